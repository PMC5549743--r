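#' @include IncidenceExperiment-methods.R richness.R beta.R
NULL

# Gradient GLMs: candidate construction, ML fitting with
# response-appropriate error families, AICc ranking, pseudo-R2.
#
# Responses and families:
#   alpha   - per-plot richness, negative binomial (MASS::glm.nb)
#   endemic - per-plot endemic proportion, beta family (glmmTMB)
#   beta    - pairwise 1 - Sorensen, log-normal (Gaussian ML on log(y) with
#             the log-Jacobian included in the log-likelihood, so AICc is
#             comparable across candidates of the same response)

.GLM_FAMILY <- c(alpha = "nbinom", endemic = "beta", beta = "lognormal")

# Printed best-model term sets for each response (the published winners the
# candidate set must contain). Term labels refer to standardized covariate
# columns of the analysis table.
.BEST_TERMS <- list(
  alpha = c("elev", "elev2", "habitat", "mat", "map2",
            "elev:mat", "elev:elev2", "elev2:mat"),
  endemic = c("elev", "elev2", "habitat", "mat", "map2",
              "elev:mat", "elev:elev2", "elev2:mat", "elev:elev2:mat"),
  beta = c("elev", "elev2", "transition", "mat", "map",
           "elev:transition", "elev:mat", "elev2:transition", "elev2:mat",
           "transition:mat", "mat:map",
           "elev:transition:mat", "elev2:transition:mat")
)

#' Assemble the analysis table for one response
#'
#' Builds the modelling data for the gradient GLMs. Continuous covariates
#' (elevation, MAT, MAP) are standardized (z-scored) and their squares are
#' added as `elev2`, `mat2`, `map2`; the factor is `habitat` for the
#' plot-level responses and the six-level `transition` for the pairwise
#' dissimilarity response.
#'
#' Response-specific handling:
#' * `alpha`: per-plot richness, all plots.
#' * `endemic`: per-plot endemic proportion; empty plots (undefined 0/0)
#'   are dropped, and exact 0/1 values are squeezed to the open interval by
#'   `(y (n - 1) + 0.5) / n` as beta-family models require.
#' * `beta`: all defined within-location pair dissimilarities; plots of the
#'   lowest-elevation location are excluded by default (its empty plots make
#'   the dissimilarities there degenerate) unless `exclude_locations` says
#'   otherwise; exact zeros are nudged to half the smallest positive value
#'   so the log-normal family applies.
#'
#' @param x an [IncidenceExperiment-class].
#' @param response `"alpha"`, `"endemic"` or `"beta"`.
#' @param exclude_locations locations to drop for the `beta` response;
#'   `NULL` (default) drops the lowest-elevation location, `character(0)`
#'   keeps everything.
#' @return data.frame with column `y` and the covariate columns.
#' @export
analysisTable <- function(x, response = c("alpha", "endemic", "beta"),
                          exclude_locations = NULL) {
  response <- match.arg(response)
  z <- function(v) if (stats::sd(v) > 0) as.numeric(scale(v)) else v * 0
  if (response %in% c("alpha", "endemic")) {
    pd <- plotData(x)
    y <- if (response == "alpha") as.numeric(alphaRichness(x))
         else suppressWarnings(endemicProportion(x))
    d <- data.frame(y = y, elev = pd$elevation, mat = pd$mat, map = pd$map,
                    habitat = pd$habitat, location = pd$location)
    if (response == "endemic") {
      drop <- is.na(d$y)
      if (any(drop)) {
        message(sum(drop), " empty plot(s) dropped from the endemic table")
        d <- d[!drop, , drop = FALSE]
      }
      if (any(d$y <= 0 | d$y >= 1)) {
        n <- nrow(d)
        d$y <- (d$y * (n - 1) + 0.5) / n
      }
    }
  } else {
    pd <- plotData(x)
    if (is.null(exclude_locations)) {
      lowest <- levels(pd$location)[which.min(
        tapply(pd$elevation, pd$location, stats::median))]
      message("beta response: excluding lowest-elevation location '",
              lowest, "' (override with exclude_locations)")
      exclude_locations <- lowest
    }
    pairs <- suppressWarnings(pairwiseBeta(x))
    pairs <- pairs[!pairs$location %in% as.character(exclude_locations) &
                     pairs$defined, , drop = FALSE]
    loc <- pairs$location
    row1 <- match(loc, pd$location)  # first plot row of each location
    d <- data.frame(y = pairs$beta,
                    elev = pd$elevation[row1], mat = pd$mat[row1],
                    map = pd$map[row1],
                    transition = factor(pairs$transition,
                                        levels = .TRANSITION_LEVELS),
                    location = loc)
    if (any(d$y <= 0)) {
      eps <- min(d$y[d$y > 0]) / 2
      warning(sum(d$y <= 0), " zero dissimilarity value(s) nudged to ",
              signif(eps, 3), " for the log-normal family")
      d$y[d$y <= 0] <- eps
    }
  }
  for (v in c("elev", "mat", "map")) {
    d[[v]] <- z(d[[v]])
    d[[paste0(v, "2")]] <- d[[v]]^2
  }
  d
}

#' Construct the candidate model set for one response
#'
#' Generates exactly 31 candidate models by a deterministic scheme: the
#' intercept-only model, then hierarchical main-effect combinations of the
#' blocks \{elevation, elevation^2\}, \{habitat / transition\},
#' \{MAT, MAT^2\}, \{MAP, MAP^2\} (a squared term only together with its
#' linear term), ordered by increasing number of terms and then
#' alphabetically, truncated to 30; the published best-model term set for
#' the response (which carries the interaction structure) is appended as
#' the 31st candidate. Every model satisfies the hierarchy constraint that
#' an interaction appears only with all its main effects.
#'
#' @param response `"alpha"`, `"endemic"` or `"beta"`.
#' @return list of 31 `candidate_model` objects (lists with `response`,
#'   `terms`, `family`).
#' @examples
#' length(buildCandidateSet("alpha"))
#' @export
buildCandidateSet <- function(response = c("alpha", "endemic", "beta")) {
  response <- match.arg(response)
  fac <- if (response == "beta") "transition" else "habitat"
  blocks <- list(
    list(character(0), "elev", c("elev", "elev2")),
    list(character(0), fac),
    list(character(0), "mat", c("mat", "mat2")),
    list(character(0), "map", c("map", "map2"))
  )
  combos <- list()
  for (e in blocks[[1]]) for (h in blocks[[2]])
    for (m in blocks[[3]]) for (p in blocks[[4]])
      combos[[length(combos) + 1L]] <- c(e, h, m, p)
  key <- vapply(combos, function(t) paste(sort(t), collapse = " "), "")
  ord <- order(lengths(combos), key)
  combos <- combos[ord]
  combos <- combos[seq_len(30L)]
  combos[[31L]] <- .BEST_TERMS[[response]]
  lapply(combos, function(t)
    structure(list(response = response, terms = t,
                   family = unname(.GLM_FAMILY[response])),
              class = "candidate_model"))
}

#' Model formula of a candidate
#' @param model a `candidate_model`.
#' @return a formula with response `y`.
#' @export
candidateFormula <- function(model) {
  stats::reformulate(if (length(model$terms)) model$terms else "1",
                     response = "y")
}

# Does every interaction come with all its main effects?
.isHierarchical <- function(terms) {
  inter <- grep(":", terms, value = TRUE)
  mains <- setdiff(terms, inter)
  all(vapply(inter, function(tr)
    all(strsplit(tr, ":", fixed = TRUE)[[1]] %in% mains), logical(1)))
}

#' Maximum-likelihood fit of one candidate model
#'
#' Fits a candidate by maximum likelihood with its response's error family
#' (negative binomial via [MASS::glm.nb()], beta via [glmmTMB::glmmTMB()],
#' log-normal via Gaussian ML on `log(y)` with the Jacobian added to the
#' log-likelihood). The parameter count `k` includes the dispersion/shape
#' parameter and counts only estimable (non-aliased) coefficients.
#'
#' @param model a `candidate_model` from [buildCandidateSet()].
#' @param data analysis table from [analysisTable()] for the same response.
#' @return a `fit_result`: list with `model`, `fit`, `loglik`, `k`, `n`,
#'   `fitted`, `converged`, `warnings`.
#' @export
fitCandidate <- function(model, data) {
  stopifnot(inherits(model, "candidate_model"), "y" %in% colnames(data))
  n <- nrow(data)
  fml <- candidateFormula(model)
  warns <- character()
  res <- tryCatch(withCallingHandlers({
    if (model$family == "nbinom") {
      # no-overdispersion data can break theta estimation; the negative
      # binomial limit theta -> Inf is Poisson, so fall back to it
      f <- tryCatch(MASS::glm.nb(fml, data = data), error = function(e) {
        warns <<- c(warns, paste("theta estimation failed, using the",
                                 "Poisson limit:", conditionMessage(e)))
        stats::glm(fml, data = data, family = stats::poisson())
      })
      list(fit = f, loglik = as.numeric(stats::logLik(f)),
           k = f$rank + 1L, fitted = as.numeric(stats::fitted(f)),
           converged = isTRUE(f$converged))
    } else if (model$family == "beta") {
      if (any(data$y <= 0 | data$y >= 1)) {
        warns <- c(warns, "boundary proportions squeezed before fitting")
        data$y <- (data$y * (n - 1) + 0.5) / n
      }
      f <- glmmTMB::glmmTMB(fml, data = data,
        family = glmmTMB::beta_family(),
        control = glmmTMB::glmmTMBControl(rank_check = "adjust"))
      fe <- glmmTMB::fixef(f)$cond
      list(fit = f, loglik = as.numeric(stats::logLik(f)),
           k = sum(!is.na(fe)) + 1L, fitted = as.numeric(stats::fitted(f)),
           converged = isTRUE(f$fit$convergence == 0))
    } else {
      if (any(data$y <= 0)) stop("log-normal family needs positive response")
      data$.logy <- log(data$y)
      lf <- stats::reformulate(if (length(model$terms)) model$terms else "1",
                               response = ".logy")
      f <- stats::lm(lf, data = data)
      list(fit = f, loglik = as.numeric(stats::logLik(f)) - sum(data$.logy),
           k = f$rank + 1L, fitted = exp(as.numeric(stats::fitted(f))),
           converged = TRUE)
    }
  }, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  }), error = function(e) list(fit = NULL, loglik = NA_real_, k = NA_integer_,
                               fitted = NULL, converged = FALSE,
                               error = conditionMessage(e)))
  structure(c(res, list(model = model, n = n, warnings = warns)),
            class = "fit_result")
}

#' Small-sample corrected Akaike information criterion
#'
#' \deqn{AICc = -2\,\ell + 2k + \frac{2k(k+1)}{n-k-1}.}
#' Undefined (with a warning) when `n <= k + 1`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters (including dispersion).
#' @param n number of observations.
#' @return numeric AICc (vectorized; `NA` where undefined).
#' @examples
#' aicc(-100, 5, 120)
#' @export
aicc <- function(loglik, k, n) {
  out <- -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  bad <- n <= k + 1
  if (any(bad, na.rm = TRUE)) {
    warning("AICc undefined for n <= k + 1")
    out[bad] <- NA_real_
  }
  out
}

#' Pseudo-R2 of a fitted candidate
#'
#' Proportion of response variation explained by the model, clamped to
#' `[0, 1]`: `1 - residual deviance / null deviance` for the negative
#' binomial family, the R2 of the Gaussian fit on the log scale for the
#' log-normal family, and for the beta family the squared correlation
#' between the link-transformed response and the linear predictor (the
#' convention of beta-regression software, since a saturated beta deviance
#' is not well defined at small precision).
#'
#' @param fit a `fit_result` from [fitCandidate()].
#' @param null_fit unused for the current families; kept so callers can
#'   supply the intercept-only fit uniformly.
#' @return numeric in `[0, 1]` (or `NA` when undefined).
#' @export
pseudoR2 <- function(fit, null_fit = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  f <- fit$fit
  if (is.null(f)) return(NA_real_)
  r2 <- switch(fit$model$family,
    nbinom = {
      if (f$null.deviance <= 0) return(NA_real_)
      1 - f$deviance / f$null.deviance
    },
    lognormal = summary(f)$r.squared,
    beta = {
      y <- stats::model.frame(f)$y
      eta <- as.numeric(stats::predict(f, type = "link"))
      if (stats::sd(eta) == 0) 0
      else suppressWarnings(stats::cor(stats::qlogis(y), eta)^2)
    })
  if (!is.finite(r2)) return(NA_real_)
  min(max(r2, 0), 1)
}

#' Rank fitted candidates by AICc
#'
#' Orders converged fits by ascending AICc, attaches the AICc difference to
#' the best model, and flags the selected model. Within an AICc band of 2
#' the most parsimonious model (fewest parameters) is selected. Fits that
#' did not converge, or whose AICc is undefined, are excluded with a
#' warning.
#'
#' @param fits list of `fit_result` objects.
#' @return data.frame with columns `terms`, `family`, `k`, `n`, `loglik`,
#'   `aicc`, `delta_aicc`, `pseudo_r2`, `best`; the AICc gap to the
#'   next-best and to the worst model are attached as attributes
#'   `delta_next_best` and `delta_worst` (`NA` with a single model).
#' @export
rankModels <- function(fits) {
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!conv))
    warning(sum(!conv), " non-converged fit(s) excluded from ranking")
  fits <- fits[conv]
  if (!length(fits)) stop("no converged fits to rank")
  null_idx <- which(vapply(fits, function(f) length(f$model$terms) == 0,
                           logical(1)))
  null_fit <- if (length(null_idx)) fits[[null_idx[1]]]
  tab <- do.call(rbind, lapply(fits, function(f) data.frame(
    terms = if (length(f$model$terms))
      paste(f$model$terms, collapse = " + ") else "1",
    family = f$model$family, k = f$k, n = f$n, loglik = f$loglik,
    aicc = suppressWarnings(aicc(f$loglik, f$k, f$n)),
    pseudo_r2 = tryCatch(pseudoR2(f, null_fit), error = function(e) NA_real_),
    stringsAsFactors = FALSE)))
  if (anyNA(tab$aicc)) {
    warning(sum(is.na(tab$aicc)), " fit(s) with undefined AICc excluded")
    tab <- tab[!is.na(tab$aicc), , drop = FALSE]
  }
  tab <- tab[order(tab$aicc, tab$k), , drop = FALSE]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  cand <- which(tab$delta_aicc < 2)
  best <- cand[order(tab$k[cand], tab$aicc[cand])][1]
  tab$best <- seq_len(nrow(tab)) == best
  rownames(tab) <- NULL
  attr(tab, "delta_next_best") <- if (nrow(tab) > 1)
    tab$aicc[2] - tab$aicc[1] else NA_real_
  attr(tab, "delta_worst") <- if (nrow(tab) > 1)
    max(tab$aicc) - tab$aicc[1] else NA_real_
  tab
}

#' Candidate-set model selection for one response
#'
#' Convenience wrapper: builds the analysis table and the 31-candidate set,
#' fits every candidate by maximum likelihood, and ranks them by AICc.
#'
#' @param x an [IncidenceExperiment-class].
#' @param response `"alpha"`, `"endemic"` or `"beta"`.
#' @param exclude_locations passed to [analysisTable()] (beta response).
#' @param candidates optional list of `candidate_model`s to use instead of
#'   [buildCandidateSet()]'s.
#' @return list with `ranking` (see [rankModels()]), `fits`, and `data`.
#' @examples
#' \donttest{
#' ie <- simulateLandscape(landscapeConfig(seed = 1))
#' sel <- runModelSelection(ie, "alpha")
#' head(sel$ranking, 3)
#' }
#' @export
runModelSelection <- function(x, response = c("alpha", "endemic", "beta"),
                              exclude_locations = NULL, candidates = NULL) {
  response <- match.arg(response)
  data <- analysisTable(x, response, exclude_locations)
  if (is.null(candidates)) candidates <- buildCandidateSet(response)
  fits <- lapply(candidates, fitCandidate, data = data)
  list(ranking = rankModels(fits), fits = fits, data = data)
}
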