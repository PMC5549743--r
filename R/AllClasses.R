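#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Container for a plots-by-species incidence survey
#'
#' `IncidenceExperiment` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' for binary presence/absence surveys in a nested landscape design. The
#' single assay `"incidence"` holds species as rows and plots as columns
#' (0 = absent, 1 = present). Plot metadata (location, elevation, habitat,
#' optional climate covariates) lives in `colData`; species attributes
#' (an `endemic` flag) in `rowData`.
#'
#' All-zero plots (no species recorded) are legal members of the design and
#' are kept; downstream operations document how they treat empty plots.
#'
#' @slot .. see [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class].
#' @seealso [IncidenceExperiment()] for construction, [incidence()],
#'   [plotData()], [speciesData()], [designSummary()]
#' @exportClass IncidenceExperiment
setClass("IncidenceExperiment", contains = "SummarizedExperiment")

.HABITAT_LEVELS <- c("OG", "DE", "SE")

.validIncidenceExperiment <- function(object) {
  msg <- character()
  if (!"incidence" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'incidence' is required")
  else {
    m <- SummarizedExperiment::assay(object, "incidence")
    if (anyNA(m))
      msg <- c(msg, "incidence values must not be missing")
    else if (!all(m %in% c(0, 1)))
      msg <- c(msg, "incidence values must be strictly 0 or 1")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "plot identifiers (colnames) must be present and unique")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "species identifiers (rownames) must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  for (f in c("location", "elevation", "habitat"))
    if (!f %in% colnames(cd))
      msg <- c(msg, sprintf("plot metadata column '%s' is required", f))
  if ("habitat" %in% colnames(cd)) {
    h <- as.character(cd$habitat)
    bad <- setdiff(unique(h[!is.na(h)]), .HABITAT_LEVELS)
    if (length(bad))
      msg <- c(msg, sprintf("unknown habitat code(s): %s",
                            paste(bad, collapse = ", ")))
    if (anyNA(h))
      msg <- c(msg, "habitat must be known for every plot")
  }
  if ("elevation" %in% colnames(cd)) {
    e <- cd$elevation
    if (anyNA(e) || !is.numeric(e) || any(e <= 0))
      msg <- c(msg, "elevation must be positive (metres a.s.l.) for every plot")
  }
  if (length(msg)) msg else TRUE
}

setValidity("IncidenceExperiment", .validIncidenceExperiment)

#' Configuration of a synthetic landscape
#'
#' Parameters of the synthetic-community generator. The defaults describe a
#' tropical elevational transect with eight locations, three forest-use
#' habitats (old-growth `OG`, degraded `DE`, secondary `SE`) and five
#' replicate plots per habitat, a hump-shaped expected plot richness peaking
#' at mid-to-high elevation, Gaussian elevational species ranges,
#' habitat-driven compositional turnover and an endemic fraction that peaks
#' at low elevation. See [landscapeConfig()] for the user constructor and
#' the meaning, units and defaults of every slot.
#'
#' @slot n_locations integer, number of elevational locations.
#' @slot elevations numeric, one elevation (m a.s.l.) per location,
#'   strictly increasing.
#' @slot mat,map numeric, per-location mean annual temperature (degC) and
#'   precipitation (mm/a).
#' @slot habitats character, habitat codes.
#' @slot plots_per_habitat integer, replicate plots per (location, habitat).
#' @slot pool_size integer, size of the regional species pool.
#' @slot richness_peak,richness_width,richness_max numeric, Gaussian
#'   description of expected plot richness along elevation.
#' @slot niche_width numeric, SD (m) of each species' Gaussian elevational
#'   occupancy curve.
#' @slot habitat_affinity numeric matrix, species-group by habitat occurrence
#'   multipliers in `[0, 1]`.
#' @slot occupancy numeric, baseline detection probability scale; `NA` means
#'   "derive from `richness_max`".
#' @slot endemic_fraction_curve function, elevation (m) -> probability that a
#'   species centred there is endemic.
#' @slot seed integer RNG seed.
#' @exportClass LandscapeConfig
setClass("LandscapeConfig",
  representation(
    n_locations = "integer",
    elevations = "numeric",
    mat = "numeric",
    map = "numeric",
    habitats = "character",
    plots_per_habitat = "integer",
    pool_size = "integer",
    richness_peak = "numeric",
    richness_width = "numeric",
    richness_max = "numeric",
    niche_width = "numeric",
    habitat_affinity = "matrix",
    occupancy = "numeric",
    endemic_fraction_curve = "function",
    seed = "integer"
  )
)

.validLandscapeConfig <- function(object) {
  msg <- character()
  if (length(object@elevations) != object@n_locations)
    msg <- c(msg, "need one elevation per location")
  if (is.unsorted(object@elevations, strictly = TRUE))
    msg <- c(msg, "elevations must be strictly increasing")
  if (length(object@mat) != object@n_locations ||
      length(object@map) != object@n_locations)
    msg <- c(msg, "mat and map must have one value per location")
  if (!length(object@habitats) || anyDuplicated(object@habitats))
    msg <- c(msg, "habitats must be non-empty and unique")
  if (object@plots_per_habitat < 1L)
    msg <- c(msg, "plots_per_habitat must be >= 1")
  if (object@pool_size < 1L)
    msg <- c(msg, "pool_size must be >= 1")
  if (object@pool_size < object@richness_max)
    msg <- c(msg, "pool_size must be >= richness_max")
  if (object@richness_width <= 0 || object@niche_width <= 0)
    msg <- c(msg, "richness_width and niche_width must be positive")
  A <- object@habitat_affinity
  if (is.null(dimnames(A)) ||
      !identical(colnames(A), object@habitats))
    msg <- c(msg, "habitat_affinity columns must be named by the habitats")
  if (any(A < 0 | A > 1))
    msg <- c(msg, "habitat_affinity entries must lie in [0, 1]")
  occ <- object@occupancy
  if (!is.na(occ) && (occ <= 0 || occ > 1))
    msg <- c(msg, "occupancy must lie in (0, 1]")
  if (length(msg)) msg else TRUE
}

setValidity("LandscapeConfig", .validLandscapeConfig)
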