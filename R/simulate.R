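#' @include AllClasses.R IncidenceExperiment-methods.R
NULL

# Default transect: eight locations at the category elevations of a tropical
# volcano gradient, with per-location climate normals.
.DEFAULT_ELEV <- c(50, 650, 1000, 1500, 2100, 2500, 3100, 3500)
.DEFAULT_MAT <- c(26, 23, 21, 18, 14, 12, 10, 8)
.DEFAULT_MAP <- c(1221, 938, 1552, 1598, 3004, 1142, 821, 829)

#' Habitat affinity matrix from a single contrast
#'
#' Builds the species-group by habitat occurrence-multiplier matrix used by
#' the generator: each species group "prefers" one habitat (multiplier 1)
#' and occurs in the others with multiplier `1 - contrast`. `contrast = 0`
#' removes all habitat structure; larger contrasts increase between-habitat
#' compositional turnover.
#'
#' @param contrast numeric in `[0, 1]`.
#' @param habitats character vector of habitat codes.
#' @return square numeric matrix, groups x habitats.
#' @examples
#' habitatAffinity(0.5)
#' @export
habitatAffinity <- function(contrast, habitats = c("OG", "DE", "SE")) {
  stopifnot(contrast >= 0, contrast <= 1)
  A <- matrix(1 - contrast, length(habitats), length(habitats),
              dimnames = list(habitats, habitats))
  diag(A) <- 1
  A
}

.defaultEndemicCurve <- function(elevation) {
  0.05 + 0.30 * exp(-((elevation - 650)^2) / (2 * 800^2))
}

#' Configure a synthetic landscape
#'
#' Creates a [LandscapeConfig-class] describing the nested survey the
#' generator emulates: locations along an elevational gradient, habitats of
#' different forest-use intensity within each location, and replicate plots
#' within each habitat. Species occurrence is independent Bernoulli with
#'
#' \deqn{p_s(e, h) = \mathrm{occupancy} \cdot
#'   e^{-(e - \mathrm{peak})^2 / 2\,\mathrm{width}^2} \cdot
#'   e^{-(e - c_s)^2 / 2\,\mathrm{niche\_width}^2} \cdot
#'   A[\mathrm{group}(s), h],}
#'
#' where \eqn{c_s} is the species' elevational niche centre (uniform over the
#' gradient span), the first Gaussian shapes regional richness along
#' elevation and the second the species' own elevational range. The defaults
#' describe a 8-location x 3-habitat x 5-plot tropical transect with a
#' 264-species pool, plot richness peaking near 2500 m at about 13 species,
#' near-empty lowest-elevation plots, and an endemic fraction peaking at low
#' elevation.
#'
#' @param n_locations number of locations (default 8).
#' @param elevations per-location elevations in m a.s.l., strictly
#'   increasing (default 50, 650, 1000, 1500, 2100, 2500, 3100, 3500).
#' @param mat,map per-location mean annual temperature (degC) and
#'   precipitation (mm/a); defaults follow the default transect and are
#'   interpolated for custom elevations.
#' @param habitats habitat codes (default `OG`, `DE`, `SE`).
#' @param plots_per_habitat replicate plots per cell (default 5).
#' @param pool_size regional species pool size (default 264).
#' @param richness_peak,richness_width elevation (m) of maximal expected
#'   plot richness and Gaussian width (m) of the richness curve
#'   (defaults 2500 and 1000).
#' @param richness_max expected plot richness at the peak (default 13); used
#'   to derive `occupancy` when the latter is `NA`.
#' @param niche_width SD (m) of each species' Gaussian elevational occupancy
#'   curve (default 300).
#' @param habitat_affinity groups x habitats multiplier matrix (default
#'   `habitatAffinity(0.6)`).
#' @param occupancy baseline detection probability in `(0, 1]`, or `NA`
#'   (default) to derive it so the expected peak plot richness equals
#'   `richness_max`.
#' @param endemic_fraction_curve function elevation -> probability that a
#'   species centred there is endemic (default peaks at 650 m, ~12% of the
#'   pool endemic overall).
#' @param seed integer RNG seed (default 42).
#' @return a validated [LandscapeConfig-class].
#' @seealso [simulateLandscape()], [expectedAlpha()]
#' @export
landscapeConfig <- function(n_locations = 8L,
                            elevations = NULL,
                            mat = NULL,
                            map = NULL,
                            habitats = c("OG", "DE", "SE"),
                            plots_per_habitat = 5L,
                            pool_size = 264L,
                            richness_peak = 2500,
                            richness_width = 1000,
                            richness_max = 13,
                            niche_width = 300,
                            habitat_affinity = NULL,
                            occupancy = NA_real_,
                            endemic_fraction_curve = .defaultEndemicCurve,
                            seed = 42L) {
  n_locations <- as.integer(n_locations)
  if (is.null(elevations)) {
    elevations <- if (n_locations == 8L) .DEFAULT_ELEV else
      seq(.DEFAULT_ELEV[1], .DEFAULT_ELEV[8], length.out = n_locations)
  }
  if (is.null(mat))
    mat <- stats::approx(.DEFAULT_ELEV, .DEFAULT_MAT, xout = elevations,
                         rule = 2)$y
  if (is.null(map))
    map <- stats::approx(.DEFAULT_ELEV, .DEFAULT_MAP, xout = elevations,
                         rule = 2)$y
  if (is.null(habitat_affinity))
    habitat_affinity <- habitatAffinity(0.6, habitats)
  methods::new("LandscapeConfig",
    n_locations = n_locations,
    elevations = as.numeric(elevations),
    mat = as.numeric(mat),
    map = as.numeric(map),
    habitats = as.character(habitats),
    plots_per_habitat = as.integer(plots_per_habitat),
    pool_size = as.integer(pool_size),
    richness_peak = as.numeric(richness_peak),
    richness_width = as.numeric(richness_width),
    richness_max = as.numeric(richness_max),
    niche_width = as.numeric(niche_width),
    habitat_affinity = habitat_affinity,
    occupancy = as.numeric(occupancy),
    endemic_fraction_curve = endemic_fraction_curve,
    seed = as.integer(seed))
}

setMethod("show", "LandscapeConfig", function(object) {
  cat(sprintf(
    "LandscapeConfig: %d locations x %d habitats x %d plots; pool %d\n",
    object@n_locations, length(object@habitats), object@plots_per_habitat,
    object@pool_size))
  cat(sprintf("  richness peak %g m (width %g m, max %g); niche width %g m\n",
              object@richness_peak, object@richness_width,
              object@richness_max, object@niche_width))
  cat(sprintf("  occupancy %s; seed %d\n",
              ifelse(is.na(object@occupancy), "(derived)",
                     format(object@occupancy, digits = 3)),
              object@seed))
})

# Mean over the uniform niche-centre distribution of the species-niche
# Gaussian at elevation e (closed form via the normal CDF).
.nicheBar <- function(config, e) {
  span <- range(config@elevations)
  nw <- config@niche_width
  if (!is.finite(nw)) return(rep(1, length(e)))
  nw * sqrt(2 * pi) / diff(span) *
    (stats::pnorm((span[2] - e) / nw) - stats::pnorm((span[1] - e) / nw))
}

.richnessShape <- function(config, e) {
  if (!is.finite(config@richness_width)) return(rep(1, length(e)))
  exp(-((e - config@richness_peak)^2) / (2 * config@richness_width^2))
}

# Baseline occupancy: as given, or derived so the marginal expected plot
# richness at the richness peak equals richness_max.
.occupancyScale <- function(config) {
  if (!is.na(config@occupancy)) return(config@occupancy)
  denom <- config@pool_size * .nicheBar(config, config@richness_peak) *
    mean(config@habitat_affinity)
  occ <- config@richness_max / denom
  if (occ > 1) {
    warning("derived occupancy capped at 1; expected peak richness will ",
            "fall short of richness_max")
    occ <- 1
  }
  occ
}

# Per-species Bernoulli occurrence probabilities for one plot.
.occProbs <- function(config, centers, groups, elevation, habitat) {
  occ <- .occupancyScale(config)
  nw <- config@niche_width
  niche <- if (is.finite(nw)) exp(-((elevation - centers)^2) / (2 * nw^2))
           else rep(1, length(centers))
  p <- occ * .richnessShape(config, elevation) * niche *
    config@habitat_affinity[cbind(groups, rep(habitat, length(groups)))]
  pmin(pmax(p, 0), 1)
}

#' Expected per-plot richness under a landscape configuration
#'
#' The exact Bernoulli-sum (Poisson-binomial) expectation of plot richness
#' at a given elevation and habitat. With `centers`/`groups` from a realised
#' landscape the sum runs over the realised species pool; without them the
#' expectation is also taken over the uniform niche-centre distribution and
#' the uniform species-group assignment (closed form).
#'
#' @param config a [LandscapeConfig-class].
#' @param elevation numeric elevation(s) in m.
#' @param habitat single habitat code.
#' @param centers,groups optional realised niche centres and species groups
#'   (as stored in the `rowData` of a simulated landscape).
#' @return numeric vector of expected richness, one value per elevation.
#' @examples
#' cfg <- landscapeConfig(seed = 1)
#' expectedAlpha(cfg, 2500, "OG")
#' @export
expectedAlpha <- function(config, elevation, habitat, centers = NULL,
                          groups = NULL) {
  stopifnot(habitat %in% config@habitats)
  if (is.null(centers)) {
    occ <- .occupancyScale(config)
    abar <- mean(config@habitat_affinity[, habitat])
    return(config@pool_size * occ * .richnessShape(config, elevation) *
             .nicheBar(config, elevation) * abar)
  }
  vapply(elevation, function(e)
    sum(.occProbs(config, centers, groups, e, habitat)), numeric(1))
}

#' Generate a synthetic landscape
#'
#' Draws a species pool (uniform elevational niche centres, uniform habitat
#' groups, endemic flags from the configured elevational curve) and then
#' fills every plot by independent Bernoulli occurrence draws with the
#' probabilities described in [landscapeConfig()]. One RNG stream is seeded
#' once, so the output is fully reproducible from the seed; the caller's RNG
#' state is restored on exit.
#'
#' @param config a [LandscapeConfig-class].
#' @param seed RNG seed; defaults to `config@seed`.
#' @return an [IncidenceExperiment-class] whose `rowData` carries `endemic`,
#'   `niche_center` and `group`, and whose `metadata()$config` stores
#'   `config`.
#' @examples
#' ie <- simulateLandscape(landscapeConfig(seed = 7))
#' dim(ie)  # species x plots
#' @export
simulateLandscape <- function(config, seed = config@seed) {
  methods::validObject(config)
  config@occupancy <- .occupancyScale(config)  # resolve derived value once
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  pool <- config@pool_size
  span <- range(config@elevations)
  centers <- stats::runif(pool, span[1], span[2])
  groups <- sample(rownames(config@habitat_affinity), pool, replace = TRUE)
  pend <- pmin(pmax(config@endemic_fraction_curve(centers), 0), 1)
  endemic <- stats::rbinom(pool, 1L, pend) == 1L
  sp_ids <- sprintf("sp%03d", seq_len(pool))

  locs <- as.character(config@elevations)
  n_plots <- config@n_locations * length(config@habitats) *
    config@plots_per_habitat
  plot_id <- character(n_plots)
  meta <- data.frame(plot_id = character(n_plots), location = character(n_plots),
                     elevation = numeric(n_plots), habitat = character(n_plots),
                     mat = numeric(n_plots), map = numeric(n_plots),
                     stringsAsFactors = FALSE)
  m <- matrix(0L, n_plots, pool, dimnames = list(NULL, sp_ids))
  i <- 0L
  for (l in seq_len(config@n_locations)) {
    e <- config@elevations[l]
    for (h in config@habitats) {
      p <- .occProbs(config, centers, groups, e, h)
      for (r in seq_len(config@plots_per_habitat)) {
        i <- i + 1L
        plot_id[i] <- sprintf("p%s_%s_%d", locs[l], h, r)
        meta[i, c("plot_id", "location", "habitat")] <-
          c(plot_id[i], locs[l], h)
        meta$elevation[i] <- e
        meta$mat[i] <- config@mat[l]
        meta$map[i] <- config@map[l]
        m[i, ] <- stats::rbinom(pool, 1L, p)
      }
    }
  }
  rownames(m) <- plot_id
  species <- data.frame(species_id = sp_ids, endemic = endemic,
                        niche_center = centers, group = groups,
                        stringsAsFactors = FALSE)
  ie <- IncidenceExperiment(m, meta, species)
  S4Vectors::metadata(ie)$config <- config
  ie
}
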