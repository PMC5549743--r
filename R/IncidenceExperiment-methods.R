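#' @include AllClasses.R AllGenerics.R
NULL

# Habitat spellings accepted on input, normalised to the canonical codes.
.HABITAT_ALIASES <- c(
  "og" = "OG", "old-growth" = "OG", "old growth" = "OG", "oldgrowth" = "OG",
  "old-growth forest" = "OG", "primary" = "OG",
  "de" = "DE", "degraded" = "DE", "degraded forest" = "DE",
  "se" = "SE", "secondary" = "SE", "secondary forest" = "SE"
)

#' Normalise habitat codes
#'
#' Maps accepted habitat spellings (e.g. `"old-growth"`, `"secondary"`,
#' lower-case codes) to the canonical codes `OG`, `DE`, `SE` and returns a
#' factor with those levels.
#'
#' @param x character vector of habitat labels.
#' @return factor with levels `OG`, `DE`, `SE`.
#' @examples
#' normalizeHabitat(c("old-growth", "DE", "secondary"))
#' @export
normalizeHabitat <- function(x) {
  x <- as.character(x)
  key <- tolower(trimws(x))
  out <- ifelse(toupper(key) %in% .HABITAT_LEVELS, toupper(key),
                unname(.HABITAT_ALIASES[key]))
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown habitat code(s): ", paste(bad, collapse = ", "))
  }
  factor(out, levels = .HABITAT_LEVELS)
}

#' Construct an IncidenceExperiment
#'
#' Assembles a validated [IncidenceExperiment-class] from a plots-by-species
#' presence/absence matrix, a plot metadata table and (optionally) a species
#' attribute table. Plot and species ordering is preserved exactly as given;
#' all downstream iteration orders derive from it.
#'
#' @param incidence numeric/integer matrix or data frame, plots as rows and
#'   species as columns, values strictly 0/1, with row and column names.
#' @param meta data frame with columns `plot_id`, `location`, `elevation`,
#'   `habitat` and optionally `mat`, `map`. Every plot in `incidence` must
#'   appear exactly once; habitat labels are normalised via
#'   [normalizeHabitat()].
#' @param species optional data frame with columns `species_id` and
#'   `endemic` (logical or 0/1). Species without a record get `NA`.
#' @return an [IncidenceExperiment-class] (species x plots internally).
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("p1", "p2"), c("a", "b")))
#' meta <- data.frame(plot_id = c("p1", "p2"), location = "L1",
#'                    elevation = 100, habitat = c("OG", "SE"))
#' ie <- IncidenceExperiment(m, meta)
#' @export
IncidenceExperiment <- function(incidence, meta, species = NULL) {
  incidence <- as.matrix(incidence)
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("incidence matrix must carry plot (row) and species (column) names")
  storage.mode(incidence) <- "integer"
  meta <- as.data.frame(meta)
  need <- c("plot_id", "location", "elevation", "habitat")
  miss <- setdiff(need, colnames(meta))
  if (length(miss))
    stop("plot metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$plot_id))
    stop("duplicate plot_id in metadata")
  absent <- setdiff(rownames(incidence), meta$plot_id)
  if (length(absent))
    stop("plot(s) in matrix missing from metadata: ",
         paste(utils::head(absent, 5), collapse = ", "))
  meta <- meta[match(rownames(incidence), meta$plot_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(
    location = factor(meta$location, levels = unique(meta$location)),
    elevation = as.numeric(meta$elevation),
    habitat = normalizeHabitat(meta$habitat),
    row.names = rownames(incidence)
  )
  cd$mat <- if ("mat" %in% colnames(meta)) as.numeric(meta$mat) else NA_real_
  cd$map <- if ("map" %in% colnames(meta)) as.numeric(meta$map) else NA_real_

  rd <- S4Vectors::DataFrame(row.names = colnames(incidence))
  rd$endemic <- NA
  if (!is.null(species)) {
    species <- as.data.frame(species)
    if (!all(c("species_id", "endemic") %in% colnames(species)))
      stop("species table needs columns species_id and endemic")
    idx <- match(colnames(incidence), species$species_id)
    rd$endemic <- as.logical(species$endemic[idx])
    extra <- setdiff(colnames(species), c("species_id", "endemic"))
    for (col in extra) rd[[col]] <- species[[col]][idx]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(incidence = t(incidence)), colData = cd, rowData = rd
  )
  methods::new("IncidenceExperiment", se)
}

#' Extract the presence/absence matrix
#'
#' Returns the binary incidence data in the site-by-species convention used
#' throughout community ecology: plots as rows, species as columns.
#'
#' @param x an [IncidenceExperiment-class].
#' @return integer matrix, plots x species.
#' @export
setMethod("incidence", "IncidenceExperiment", function(x, ...) {
  t(SummarizedExperiment::assay(x, "incidence"))
})

#' Plot metadata
#'
#' @param x an [IncidenceExperiment-class].
#' @return data.frame with one row per plot: `plot_id`, `location`,
#'   `elevation`, `habitat`, `mat`, `map`.
#' @export
setMethod("plotData", "IncidenceExperiment", function(x, ...) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(plot_id = rownames(cd), as.data.frame(cd),
             row.names = rownames(cd))
})

#' Species attributes
#'
#' @param x an [IncidenceExperiment-class].
#' @return data.frame with one row per species: `species_id`, `endemic`, and
#'   any extra attribute columns.
#' @export
setMethod("speciesData", "IncidenceExperiment", function(x, ...) {
  rd <- SummarizedExperiment::rowData(x)
  data.frame(species_id = rownames(rd), as.data.frame(rd),
             row.names = rownames(rd))
})

#' Plot identifiers, in input order
#' @param x an [IncidenceExperiment-class].
#' @export
plotIDs <- function(x) colnames(x)

#' Species identifiers, in input order
#' @param x an [IncidenceExperiment-class].
#' @export
speciesIDs <- function(x) rownames(x)

setMethod("show", "IncidenceExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("IncidenceExperiment: %d species x %d plots\n",
              nrow(object), ncol(object)))
  cat(sprintf("  locations: %d (%s)\n", nlevels(cd$location),
              paste(utils::head(levels(cd$location), 8), collapse = ", ")))
  cat(sprintf("  habitats:  %s\n",
              paste(levels(droplevels(cd$habitat)), collapse = ", ")))
  empty <- sum(colSums(SummarizedExperiment::assay(object, "incidence")) == 0)
  cat(sprintf("  presences: %d; empty plots: %d\n",
              sum(SummarizedExperiment::assay(object, "incidence")), empty))
})

#' Summarise the sampling design
#'
#' Reports the nested design of a survey: the locations with their
#' elevations, the plots per (location, habitat) cell, and any all-zero
#' (empty) plots. Empty plots are flagged, never dropped. The input is not
#' modified.
#'
#' @param x an [IncidenceExperiment-class].
#' @return a list with elements `locations` (data.frame: location, elevation,
#'   n_habitats, n_plots), `cells` (data.frame: location, habitat, n_plots),
#'   and `empty_plots` (character vector of plot ids with zero species).
#' @examples
#' ie <- simulateLandscape(landscapeConfig(seed = 1))
#' designSummary(ie)$locations
#' @export
setMethod("designSummary", "IncidenceExperiment", function(x, ...) {
  pd <- plotData(x)
  cells <- as.data.frame(table(location = pd$location, habitat = pd$habitat))
  names(cells)[3] <- "n_plots"
  cells <- cells[cells$n_plots > 0, , drop = FALSE]
  cells <- cells[order(cells$location, cells$habitat), , drop = FALSE]
  rownames(cells) <- NULL
  locs <- do.call(rbind, lapply(split(pd, pd$location), function(d) {
    data.frame(location = d$location[1], elevation = stats::median(d$elevation),
               n_habitats = length(unique(d$habitat)), n_plots = nrow(d))
  }))
  rownames(locs) <- NULL
  alpha <- colSums(SummarizedExperiment::assay(x, "incidence"))
  list(locations = locs, cells = cells,
       empty_plots = names(alpha)[alpha == 0])
})

# Plots of one (location, habitat) cell, in input order.
.cellPlots <- function(x, location, habitat) {
  pd <- plotData(x)
  pd$plot_id[pd$location == location & pd$habitat == habitat]
}
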