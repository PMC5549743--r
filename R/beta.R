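#' @include IncidenceExperiment-methods.R utils.R
NULL

# Full plots x plots matrices of shared-species counts and 1 - Sorensen.
# beta[i, j] is NA (undefined) when both plots are empty.
.betaMatrix <- function(x) {
  a <- SummarizedExperiment::assay(x, "incidence")
  C <- crossprod(a)                       # shared species counts
  alpha <- colSums(a)
  denom <- outer(alpha, alpha, "+")
  S <- ifelse(denom > 0, 2 * C / denom, NA_real_)
  list(C = C, alpha = alpha, S = S, beta = 1 - S)
}

#' Sorensen comparison of two plots
#'
#' Computes the Sorensen similarity \eqn{S = 2C/(A+B)} and dissimilarity
#' \eqn{\beta = 1 - S} for a pair of plots, where `A` and `B` are the two
#' plot richnesses and `C` the number of shared species. When exactly one
#' plot is empty the pair is maximally dissimilar (`S = 0`, `beta = 1`);
#' when both are empty the comparison is undefined (`NA`, with a warning)
#' and is excluded from all summaries.
#'
#' @param x an [IncidenceExperiment-class].
#' @param plot_a,plot_b plot identifiers.
#' @return one-row data.frame with columns `plot_a`, `plot_b`, `location`
#'   (`NA` if the plots belong to different locations), `habitat_a`,
#'   `habitat_b`, `transition`, `A`, `B`, `C`, `S`, `beta`, `defined`.
#' @examples
#' ie <- simulateLandscape(landscapeConfig(seed = 1))
#' sorensenPair(ie, plotIDs(ie)[31], plotIDs(ie)[32])
#' @export
sorensenPair <- function(x, plot_a, plot_b) {
  stopifnot(all(c(plot_a, plot_b) %in% plotIDs(x)))
  a <- SummarizedExperiment::assay(x, "incidence")
  va <- a[, plot_a] > 0
  vb <- a[, plot_b] > 0
  A <- sum(va); B <- sum(vb); C <- sum(va & vb)
  S <- if (A + B > 0) 2 * C / (A + B) else NA_real_
  if (A + B == 0)
    warning("both plots are empty: Sorensen comparison undefined")
  pd <- plotData(x)
  ha <- as.character(pd[plot_a, "habitat"])
  hb <- as.character(pd[plot_b, "habitat"])
  la <- as.character(pd[plot_a, "location"])
  lb <- as.character(pd[plot_b, "location"])
  data.frame(plot_a = plot_a, plot_b = plot_b,
             location = if (identical(la, lb)) la else NA_character_,
             habitat_a = ha, habitat_b = hb,
             transition = .transitionCode(ha, hb),
             A = A, B = B, C = C, S = S, beta = 1 - S,
             defined = A + B > 0, stringsAsFactors = FALSE)
}

# Assemble pair rows from a beta-matrix lookup.
.pairRows <- function(x, bm, pd, ia, ib, location) {
  ha <- as.character(pd$habitat[ia])
  hb <- as.character(pd$habitat[ib])
  # orient each pair so habitat_a precedes habitat_b in canonical order
  swap <- match(ha, .HABITAT_LEVELS) > match(hb, .HABITAT_LEVELS)
  tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp
  ha <- as.character(pd$habitat[ia]); hb <- as.character(pd$habitat[ib])
  ids <- pd$plot_id
  data.frame(plot_a = ids[ia], plot_b = ids[ib],
             location = rep(location, length(ia)),
             habitat_a = ha, habitat_b = hb,
             transition = .transitionCode(ha, hb),
             A = bm$alpha[ia], B = bm$alpha[ib],
             C = bm$C[cbind(ia, ib)],
             S = bm$S[cbind(ia, ib)], beta = bm$beta[cbind(ia, ib)],
             defined = (bm$alpha[ia] + bm$alpha[ib]) > 0,
             stringsAsFactors = FALSE)
}

#' All within-location pairwise Sorensen comparisons
#'
#' Enumerates, for every location, all unordered plot pairs within each
#' habitat (the within-habitat scheme: \eqn{n(n-1)/2} pairs per cell) and
#' the full cross products between habitats (the between-habitat scheme:
#' \eqn{n_a n_b} pairs per habitat pair), labelling each pair with its
#' canonical habitat transition. Plots from different locations are never
#' compared. Pairs of two empty plots are retained with `defined = FALSE`.
#'
#' @param x an [IncidenceExperiment-class].
#' @return data.frame of pair comparisons (see [sorensenPair()] for
#'   columns).
#' @examples
#' ie <- simulateLandscape(landscapeConfig(seed = 1))
#' table(pairwiseBeta(ie)$transition)
#' @export
setMethod("pairwiseBeta", "IncidenceExperiment", function(x, ...) {
  bm <- .betaMatrix(x)
  pd <- plotData(x)
  out <- lapply(levels(pd$location), function(loc) {
    idx <- which(pd$location == loc)
    if (length(idx) < 2) return(NULL)
    cmb <- utils::combn(idx, 2)
    .pairRows(x, bm, pd, cmb[1, ], cmb[2, ], loc)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  n_undef <- sum(!res$defined)
  if (n_undef)
    warning(n_undef, " pair(s) of empty plots are undefined and excluded ",
            "from summaries")
  res
})

#' Within-habitat pair comparisons for one cell
#'
#' All unordered pairs of the plots of one (location, habitat) cell; each
#' plot is compared to the other `n - 1` plots.
#'
#' @param x an [IncidenceExperiment-class].
#' @param location location label.
#' @param habitat habitat code.
#' @return data.frame of pair comparisons.
#' @export
withinHabitatPairs <- function(x, location, habitat) {
  habitat <- as.character(normalizeHabitat(habitat))
  ids <- .cellPlots(x, location, habitat)
  if (length(ids) < 2)
    stop("within-habitat comparisons need >= 2 plots in cell (",
         location, ", ", habitat, ")")
  pd <- plotData(x)
  bm <- .betaMatrix(x)
  idx <- match(ids, pd$plot_id)
  cmb <- utils::combn(idx, 2)
  .pairRows(x, bm, pd, cmb[1, ], cmb[2, ], as.character(location))
}

#' Between-habitat pair comparisons for one location
#'
#' The full cross product of plots of two different habitats within one
#' location; each plot of one habitat is compared to every plot of the
#' other.
#'
#' @param x an [IncidenceExperiment-class].
#' @param location location label.
#' @param habitat_a,habitat_b two distinct habitat codes.
#' @return data.frame of pair comparisons.
#' @export
betweenHabitatPairs <- function(x, location, habitat_a, habitat_b) {
  habitat_a <- as.character(normalizeHabitat(habitat_a))
  habitat_b <- as.character(normalizeHabitat(habitat_b))
  if (identical(habitat_a, habitat_b))
    stop("between-habitat comparisons need two distinct habitats")
  ids_a <- .cellPlots(x, location, habitat_a)
  ids_b <- .cellPlots(x, location, habitat_b)
  if (!length(ids_a) || !length(ids_b))
    stop("empty habitat cell at location ", location)
  pd <- plotData(x)
  bm <- .betaMatrix(x)
  grid <- expand.grid(a = match(ids_a, pd$plot_id),
                      b = match(ids_b, pd$plot_id))
  .pairRows(x, bm, pd, grid$a, grid$b, as.character(location))
}

# One bootstrap pass over the cells contributing to one transition.
# cells: list of list(a = indices, b = indices or NULL for within).
.bootReplicateMean <- function(cells, beta_lookup) {
  resample <- function(v) v[sample.int(length(v), length(v), replace = TRUE)]
  vals <- unlist(lapply(cells, function(cell) {
    sa <- resample(cell$a)
    if (is.null(cell$b)) {
      if (length(sa) < 2) return(NULL)
      cmb <- utils::combn(seq_along(sa), 2)
      beta_lookup[cbind(sa[cmb[1, ]], sa[cmb[2, ]])]
    } else {
      sb <- resample(cell$b)
      grid <- expand.grid(i = sa, j = sb)
      beta_lookup[cbind(grid$i, grid$j)]
    }
  }))
  mean(vals, na.rm = TRUE)
}

#' Bootstrap standard error of a mean pairwise dissimilarity
#'
#' Resamples the observed data and recomputes the mean of the pairwise
#' `beta` values `reps` times; the SE is the standard deviation of the
#' replicate means. The default `method = "plots"` resamples plots with
#' replacement within each contributing (location, habitat) cell and
#' re-forms all scheme pairs, which respects the dependence among pairs
#' sharing a plot; `method = "values"` resamples the pair values directly.
#'
#' @param pairs data.frame of pair comparisons as produced by
#'   [pairwiseBeta()], [withinHabitatPairs()] or [betweenHabitatPairs()];
#'   typically the subset belonging to one habitat transition.
#' @param x the [IncidenceExperiment-class] the pairs came from (required
#'   for `method = "plots"`).
#' @param reps number of bootstrap replicates (>= 2; default 1000).
#' @param seed RNG seed (the caller's RNG state is restored).
#' @param method `"plots"` (default) or `"values"`.
#' @return the bootstrap standard error (numeric scalar).
#' @examples
#' ie <- simulateLandscape(landscapeConfig(seed = 1))
#' pr <- withinHabitatPairs(ie, "2500", "OG")
#' bootstrapSE(pr, ie, reps = 200, seed = 9)
#' @export
bootstrapSE <- function(pairs, x = NULL, reps = 1000, seed = 1,
                        method = c("plots", "values")) {
  method <- match.arg(method)
  if (reps < 2) stop("bootstrap needs reps >= 2")
  vals <- pairs$beta[pairs$defined]
  if (!length(vals)) stop("no defined pairs to resample")
  if (method == "values") {
    means <- .withSeed(seed, vapply(seq_len(reps), function(r)
      mean(sample(vals, length(vals), replace = TRUE)), numeric(1)))
    return(stats::sd(means))
  }
  if (is.null(x))
    stop("method = 'plots' needs the IncidenceExperiment the pairs came from")
  pd <- plotData(x)
  bm <- .betaMatrix(x)
  cells <- lapply(split(pairs, pairs$location, drop = TRUE), function(d) {
    within <- all(d$habitat_a == d$habitat_b)
    ia <- match(unique(d$plot_a), pd$plot_id)
    ib <- match(unique(d$plot_b), pd$plot_id)
    if (within) list(a = sort(unique(c(ia, ib))), b = NULL)
    else list(a = ia, b = ib)
  })
  means <- .withSeed(seed, vapply(seq_len(reps), function(r)
    .bootReplicateMean(cells, bm$beta), numeric(1)))
  stats::sd(means)
}

#' Mean dissimilarity per habitat transition, with bootstrap SEs
#'
#' For each of the six habitat transitions (`OG-OG`, `OG-DE`, `OG-SE`,
#' `DE-DE`, `DE-SE`, `SE-SE`), pools all defined pairwise `1 - Sorensen`
#' values across the non-excluded locations, averages them, and attaches a
#' bootstrap standard error. Locations whose plots should not enter the
#' comparison (e.g. a lowest-elevation belt with empty plots) can be
#' excluded.
#'
#' @param x an [IncidenceExperiment-class].
#' @param exclude_locations location labels to drop (default none).
#' @param reps bootstrap replicates (default 1000); `0` skips the SE.
#' @param seed RNG seed for the bootstrap.
#' @param method bootstrap resampling unit, see [bootstrapSE()].
#' @return data.frame with one row per transition: `transition`,
#'   `mean_beta`, `se`, `n_pairs`, `locations_used`. Transitions with no
#'   defined pairs have `NA` mean and SE.
#' @examples
#' ie <- simulateLandscape(landscapeConfig(seed = 1))
#' transitionMeans(ie, exclude_locations = "50", reps = 100, seed = 2)
#' @export
setMethod("transitionMeans", "IncidenceExperiment",
  function(x, exclude_locations = NULL, reps = 1000, seed = 1,
           method = c("plots", "values"), ...) {
  method <- match.arg(method)
  pairs <- suppressWarnings(pairwiseBeta(x))
  if (!is.null(exclude_locations))
    pairs <- pairs[!pairs$location %in% as.character(exclude_locations), ,
                   drop = FALSE]
  out <- lapply(.TRANSITION_LEVELS, function(tr) {
    d <- pairs[pairs$transition == tr & pairs$defined, , drop = FALSE]
    if (!nrow(d))
      return(data.frame(transition = tr, mean_beta = NA_real_, se = NA_real_,
                        n_pairs = 0L, locations_used = "",
                        stringsAsFactors = FALSE))
    se <- if (reps >= 2)
      bootstrapSE(d, x, reps = reps, seed = seed, method = method)
    else NA_real_
    data.frame(transition = tr, mean_beta = mean(d$beta), se = se,
               n_pairs = nrow(d),
               locations_used = paste(unique(d$location), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$transition <- factor(res$transition, levels = .TRANSITION_LEVELS)
  res
})
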