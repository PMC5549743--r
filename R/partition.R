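#' @include IncidenceExperiment-methods.R
NULL

#' Multiplicative diversity partition for one location
#'
#' Decomposes the location species pool multiplicatively,
#' \deqn{\gamma = \bar\alpha \cdot \beta_w \cdot \beta_b,}
#' where \eqn{\bar\alpha} is the mean per-plot richness over all plots of
#' the location, \eqn{\bar\alpha_2} the mean over habitats of the pooled
#' habitat richness, \eqn{\beta_w = \bar\alpha_2 / \bar\alpha} the effective
#' number of distinct plots per habitat, and
#' \eqn{\beta_b = \gamma / \bar\alpha_2} the effective number of distinct
#' habitats. Components are numbers-equivalents at diversity order 0 (raw
#' richness), without null-model standardisation. Empty plots count toward
#' \eqn{\bar\alpha} with richness 0; if every plot of the location is empty
#' the partition is undefined and all components are `NA`.
#'
#' @param x an [IncidenceExperiment-class].
#' @param location location label.
#' @return one-row data.frame: `location`, `alpha_bar`, `alpha2_bar`,
#'   `beta_w`, `beta_b`, `gamma`, `defined`.
#' @examples
#' ie <- simulateLandscape(landscapeConfig(seed = 1))
#' multiplicativePartition(ie, "2500")
#' @export
multiplicativePartition <- function(x, location) {
  pd <- plotData(x)
  location <- as.character(location)
  if (!location %in% pd$location) stop("unknown location: ", location)
  ids <- pd$plot_id[pd$location == location]
  a <- SummarizedExperiment::assay(x, "incidence")[, ids, drop = FALSE]
  alpha_bar <- mean(colSums(a))
  habs <- unique(as.character(pd[ids, "habitat"]))
  pooled <- vapply(habs, function(h) {
    cell <- ids[pd[ids, "habitat"] == h]
    sum(rowSums(a[, cell, drop = FALSE]) > 0)
  }, numeric(1))
  alpha2_bar <- mean(pooled)
  gamma <- sum(rowSums(a) > 0)
  if (alpha_bar == 0) {
    return(data.frame(location = location, alpha_bar = 0,
                      alpha2_bar = NA_real_, beta_w = NA_real_,
                      beta_b = NA_real_, gamma = gamma, defined = FALSE,
                      stringsAsFactors = FALSE))
  }
  data.frame(location = location, alpha_bar = alpha_bar,
             alpha2_bar = alpha2_bar, beta_w = alpha2_bar / alpha_bar,
             beta_b = gamma / alpha2_bar, gamma = gamma, defined = TRUE,
             stringsAsFactors = FALSE)
}

#' Multiplicative partition for every location
#'
#' Applies [multiplicativePartition()] to each location and adds the
#' relative (log-scale) contribution of each component,
#' \eqn{\log\bar\alpha / \log\gamma}, \eqn{\log\beta_w / \log\gamma} and
#' \eqn{\log\beta_b / \log\gamma}, which sum to 1 and are convenient for
#' stacked-bar displays of how plot richness, within-habitat turnover and
#' between-habitat turnover build up the location pool.
#'
#' @param x an [IncidenceExperiment-class].
#' @return data.frame with one row per location (in input order), the
#'   partition components, and columns `share_alpha`, `share_beta_w`,
#'   `share_beta_b` (`NA` when `gamma <= 1` or the partition is undefined).
#' @examples
#' ie <- simulateLandscape(landscapeConfig(seed = 1))
#' partitionAll(ie)
#' @export
setMethod("partitionAll", "IncidenceExperiment", function(x, ...) {
  pd <- plotData(x)
  res <- do.call(rbind, lapply(levels(pd$location), function(l)
    multiplicativePartition(x, l)))
  lg <- ifelse(res$defined & res$gamma > 1, log(res$gamma), NA_real_)
  res$share_alpha <- log(res$alpha_bar) / lg
  res$share_beta_w <- log(res$beta_w) / lg
  res$share_beta_b <- log(res$beta_b) / lg
  rownames(res) <- NULL
  res
})
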