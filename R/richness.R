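#' @include IncidenceExperiment-methods.R
NULL

#' Plot-level species richness (alpha diversity)
#'
#' Counts the species present in each plot. Empty plots yield 0.
#'
#' @param x an [IncidenceExperiment-class].
#' @return named integer vector, one count per plot, in plot order.
#' @examples
#' ie <- simulateLandscape(landscapeConfig(seed = 1))
#' head(alphaRichness(ie))
#' @export
setMethod("alphaRichness", "IncidenceExperiment", function(x, ...) {
  colSums(SummarizedExperiment::assay(x, "incidence"))
})

#' Pooled species richness (gamma diversity)
#'
#' Richness of the union of presences over all plots of each group:
#' per location (`level = "location"`, the location species pool across its
#' habitat x replicate plots) or per (location, habitat) cell
#' (`level = "habitat"`).
#'
#' @param x an [IncidenceExperiment-class].
#' @param level `"location"` or `"habitat"`.
#' @return for `"location"`, a named integer vector; for `"habitat"`, a
#'   data.frame with columns `location`, `habitat`, `richness`.
#' @examples
#' ie <- simulateLandscape(landscapeConfig(seed = 1))
#' gammaRichness(ie)
#' @export
setMethod("gammaRichness", "IncidenceExperiment",
  function(x, level = c("location", "habitat"), ...) {
  level <- match.arg(level)
  a <- SummarizedExperiment::assay(x, "incidence")  # species x plots
  pd <- plotData(x)
  pooledRichness <- function(ids) sum(rowSums(a[, ids, drop = FALSE]) > 0)
  if (level == "location") {
    groups <- split(pd$plot_id, pd$location)
    return(vapply(groups, pooledRichness, numeric(1)))
  }
  cells <- unique(pd[, c("location", "habitat")])
  cells <- cells[order(match(cells$location, levels(pd$location)),
                       match(cells$habitat, .HABITAT_LEVELS)), ]
  cells$richness <- mapply(function(l, h)
    pooledRichness(.cellPlots(x, l, h)), cells$location, cells$habitat)
  rownames(cells) <- NULL
  cells
})

#' Per-plot proportion of endemic species
#'
#' Fraction of each plot's species that are flagged endemic; the denominator
#' is the plot's own richness. Empty plots have an undefined (0/0)
#' proportion and are returned as `NA` with a warning, so that downstream
#' beta-family models can drop them explicitly.
#'
#' @param x an [IncidenceExperiment-class] whose `rowData$endemic` is known
#'   for every species that occurs somewhere.
#' @return named numeric vector in `[0, 1]` (or `NA`), one value per plot.
#' @examples
#' ie <- simulateLandscape(landscapeConfig(seed = 1))
#' summary(endemicProportion(ie))
#' @export
setMethod("endemicProportion", "IncidenceExperiment", function(x, ...) {
  a <- SummarizedExperiment::assay(x, "incidence")
  endemic <- SummarizedExperiment::rowData(x)$endemic
  present <- rowSums(a) > 0
  if (any(present & is.na(endemic))) {
    bad <- rownames(x)[present & is.na(endemic)]
    stop("endemic flag missing for species present in the data: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  alpha <- colSums(a)
  n_end <- colSums(a * ifelse(is.na(endemic), 0, endemic))
  out <- ifelse(alpha > 0, n_end / alpha, NA_real_)
  if (anyNA(out))
    warning(sum(is.na(out)), " empty plot(s) have undefined endemic ",
            "proportion (returned as NA)")
  names(out) <- colnames(x)
  out
})
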