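#' @include IncidenceExperiment-methods.R
NULL

# Incidence-based Hill-number machinery.
#
# For a group of T sampling units (plots), each species i has incidence
# count Y_i (number of plots it occurs in), U = sum(Y), and Q_k counts the
# species with Y_i == k; Q_1/Q_2 (uniques/duplicates) drive the
# undersampling corrections. Empirical diversity uses incidence shares
# pi_i = Y_i / U (so sum(pi) = 1):
#
#   qD = (sum pi_i^q)^(1/(1-q)),  1D = exp(-sum pi_i log pi_i).
#
# Asymptotic estimators (documented here because the package implements the
# incidence-data variants of the asymptotic profile-estimator family):
#   q = 0: bias-corrected Chao2 richness,
#          S_obs + ((T-1)/T) * Q1(Q1-1) / (2(Q2+1)).
#   q = 1: exponential of the asymptotic Shannon entropy of the normalised
#          detection rates: with A = 2Q2/((T-1)Q1 + 2Q2) (standard fallbacks
#          when Q2 = 0),
#          H_pi = sum_{1<=Y_i<=T-1} (Y_i/T) sum_{k=Y_i}^{T-1} 1/k
#                 + (Q1/T)(1-A)^{1-T} (-log A - sum_{r=1}^{T-1} (1-A)^r / r)
#          estimates -sum pi_i log pi_i of the detection rates pi_i, and
#          1D = exp((T/U) H_pi + log(U/T)).
#   other q: the power sum sum(pi^q) of the detection rates is estimated by
#          the falling-factorial estimator continued to real q,
#            S_q = sum_i Gamma(Y_i+1) Gamma(T-q+1) /
#                        (Gamma(Y_i-q+1) Gamma(T+1))
#          (for integer q this is the unbiased Y(Y-1)...(Y-q+1) /
#          T(T-1)...(T-q+1) moment estimator; terms whose continuation
#          vanishes, Y_i <= q - 1, contribute 0), plus the unseen-species
#          tail term
#            B(q) = (Q1/T)(1-A)^{1-T} [A^{q-1}
#                    - sum_{r=0}^{T-1} choose(q-1, r)(A-1)^r]
#          (the remainder of the binomial series of A^{q-1}, so B >= 0 and
#          B(0) recovers the classic Chao2 correction). Then
#            qD = ((S_q + B(q)) / (U/T)^q)^(1/(1-q)),
#          which at q = 2 reduces to the familiar asymptotic inverse
#          Simpson form (U/T)^2 / sum_i [Y_i(Y_i-1) / (T(T-1))].

#' Incidence frequency counts for a set of plots
#'
#' Pools a set of plots into the sampling-unit frequencies that drive
#' incidence-based diversity estimation.
#'
#' @param x an [IncidenceExperiment-class].
#' @param plots plot identifiers to pool (default: all plots).
#' @return an object of class `incidence_freq`: a list with `T` (number of
#'   sampling units), `Y` (named incidence counts of the species present),
#'   `U` (total incidence), `Q` (frequency counts `Q_1 .. Q_T`) and `S_obs`.
#' @examples
#' ie <- simulateLandscape(landscapeConfig(seed = 1))
#' f <- incidenceFrequencies(ie, plotIDs(ie)[plotData(ie)$location == "2500"])
#' c(T = f$T, U = f$U, S_obs = f$S_obs)
#' @export
incidenceFrequencies <- function(x, plots = plotIDs(x)) {
  if (!length(plots)) stop("empty plot group")
  stopifnot(all(plots %in% plotIDs(x)))
  a <- SummarizedExperiment::assay(x, "incidence")[, plots, drop = FALSE]
  Y <- rowSums(a)
  Y <- Y[Y > 0]
  Tn <- length(plots)
  Q <- tabulate(Y, nbins = Tn)
  structure(list(T = Tn, Y = Y, U = sum(Y), Q = Q, S_obs = length(Y)),
            class = "incidence_freq")
}

#' Empirical Hill number of order q
#'
#' Effective number of species of order `q` computed from the incidence
#' shares \eqn{\pi_i = Y_i / U}: richness at `q = 0`, exponential Shannon
#' entropy at `q = 1` (the limit), inverse Simpson concentration at
#' `q = 2`.
#'
#' @param freq an `incidence_freq` object from [incidenceFrequencies()].
#' @param q numeric vector of non-negative diversity orders.
#' @return numeric vector of diversities, one per `q`.
#' @examples
#' f <- structure(list(T = 5, Y = c(a = 4, b = 1), U = 5,
#'                     Q = c(1, 0, 0, 1, 0), S_obs = 2),
#'                class = "incidence_freq")
#' empiricalHill(f, c(0, 2))  # 2 and 25/17
#' @export
empiricalHill <- function(freq, q) {
  stopifnot(inherits(freq, "incidence_freq"))
  if (any(q < 0)) stop("diversity order q must be >= 0")
  if (freq$U <= 0) stop("no incidences in group")
  pi_i <- freq$Y / freq$U
  vapply(q, function(qq) {
    if (qq == 1) exp(-sum(pi_i * log(pi_i)))
    else sum(pi_i^qq)^(1 / (1 - qq))
  }, numeric(1))
}

#' Bias-corrected Chao2 richness estimator
#'
#' Asymptotic species richness from incidence data:
#' \deqn{\hat S = S_{obs} + \frac{T-1}{T}\,\frac{Q_1 (Q_1 - 1)}{2 (Q_2 + 1)},}
#' the bias-corrected form, which is defined also when there are no
#' duplicates (`Q_2 = 0`) and never falls below the observed richness.
#'
#' @param freq an `incidence_freq` object.
#' @return estimated richness (numeric scalar).
#' @export
chao2Richness <- function(freq) {
  stopifnot(inherits(freq, "incidence_freq"))
  Tn <- freq$T
  Q1 <- freq$Q[1]
  Q2 <- if (Tn >= 2) freq$Q[2] else 0
  freq$S_obs + (Tn - 1) / Tn * Q1 * (Q1 - 1) / (2 * (Q2 + 1))
}

# Chao's A term shared by the q = 1 and continuous-q corrections.
.chaoA <- function(Tn, Q1, Q2) {
  if (Q2 > 0) 2 * Q2 / ((Tn - 1) * Q1 + 2 * Q2)
  else if (Q1 > 0) 2 / ((Tn - 1) * (Q1 - 1) + 2)
  else 1
}

.asymptoticShannon <- function(freq) {
  Tn <- freq$T; Y <- freq$Y; U <- freq$U
  Q1 <- freq$Q[1]; Q2 <- if (Tn >= 2) freq$Q[2] else 0
  A <- .chaoA(Tn, Q1, Q2)
  yi <- Y[Y >= 1 & Y <= Tn - 1]
  term1 <- if (length(yi))
    sum((yi / Tn) * vapply(yi, function(y) sum(1 / (y:(Tn - 1))), numeric(1)))
  else 0
  corr <- if (A < 1 && Q1 > 0) {
    r <- seq_len(Tn - 1)
    (Q1 / Tn) * (1 - A)^(1 - Tn) * (-log(A) - sum((1 - A)^r / r))
  } else 0
  exp((Tn / U) * (term1 + corr) + log(U / Tn))
}

.asymptoticOrderQ <- function(freq, q) {
  Tn <- freq$T; Y <- freq$Y; U <- freq$U
  Q1 <- freq$Q[1]; Q2 <- if (Tn >= 2) freq$Q[2] else 0
  A <- .chaoA(Tn, Q1, Q2)
  B <- if (A < 1 && Q1 > 0) {
    r <- 0:(Tn - 1)
    (Q1 / Tn) * (1 - A)^(1 - Tn) *
      (A^(q - 1) - sum(choose(q - 1, r) * (A - 1)^r))
  } else 0
  ok <- Y - q + 1 > 0
  terms <- numeric(length(Y))
  terms[ok] <- exp(lgamma(Y[ok] + 1) - lgamma(Y[ok] - q + 1) +
                     lgamma(Tn - q + 1) - lgamma(Tn + 1))
  Sq <- sum(terms) + max(B, 0)
  if (!is.finite(Sq) || Sq <= 0) return(empiricalHill(freq, q))
  (Sq / (U / Tn)^q)^(1 / (1 - q))
}

#' Asymptotic Hill number of order q
#'
#' Asymptotic (undersampling-corrected) effective species number for
#' incidence data; see the estimator notes in the package source. `q = 0`
#' uses the bias-corrected Chao2 estimator, `q = 1` the asymptotic Shannon
#' entropy exponentiated, other orders the coverage-adjusted continuous
#' estimator. With fewer than two sampling units no correction is possible
#' and the empirical value is returned with a warning.
#'
#' @param freq an `incidence_freq` object.
#' @param q numeric vector of non-negative diversity orders.
#' @return numeric vector of estimated diversities.
#' @export
asymptoticHill <- function(freq, q) {
  stopifnot(inherits(freq, "incidence_freq"))
  if (any(q < 0)) stop("diversity order q must be >= 0")
  if (freq$T < 2) {
    warning("fewer than two sampling units: returning empirical diversity")
    return(empiricalHill(freq, q))
  }
  vapply(q, function(qq) {
    if (qq == 0) chao2Richness(freq)
    else if (abs(qq - 1) < 1e-8) .asymptoticShannon(freq)
    else .asymptoticOrderQ(freq, qq)
  }, numeric(1))
}

#' Empirical and asymptotic diversity profile
#'
#' Evaluates both the empirical and the asymptotic Hill-number profile on a
#' grid of diversity orders (default `q = 0, 0.25, ..., 3`).
#'
#' @param freq an `incidence_freq` object.
#' @param q numeric grid of diversity orders.
#' @return data.frame with columns `q`, `empirical`, `asymptotic`.
#' @examples
#' ie <- simulateLandscape(landscapeConfig(seed = 1))
#' f <- incidenceFrequencies(ie, plotIDs(ie)[plotData(ie)$location == "2500"])
#' head(asymptoticHillProfile(f))
#' @export
asymptoticHillProfile <- function(freq, q = seq(0, 3, by = 0.25)) {
  data.frame(q = q, empirical = empiricalHill(freq, q),
             asymptotic = asymptoticHill(freq, q))
}

#' Diversity profiles for every location or habitat cell
#'
#' Pools the plots of each group (location, or (location, habitat) cell)
#' and evaluates the empirical and asymptotic diversity profiles.
#'
#' @param x an [IncidenceExperiment-class].
#' @param level `"location"` or `"habitat"`.
#' @param q numeric grid of diversity orders (default `0, 0.25, ..., 3`).
#' @return long-format data.frame: `group`, `q`, `empirical`, `asymptotic`.
#' @examples
#' ie <- simulateLandscape(landscapeConfig(seed = 1))
#' pr <- hillProfiles(ie)
#' subset(pr, q == 0 & group == "2500")
#' @export
setMethod("hillProfiles", "IncidenceExperiment",
  function(x, level = c("location", "habitat"), q = seq(0, 3, by = 0.25),
           ...) {
  level <- match.arg(level)
  pd <- plotData(x)
  groups <- if (level == "location") split(pd$plot_id, pd$location)
  else split(pd$plot_id, interaction(pd$location, pd$habitat, sep = ":",
                                     drop = TRUE, lex.order = TRUE))
  out <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    freq <- incidenceFrequencies(x, ids)
    if (freq$U == 0) return(NULL)
    cbind(group = g, asymptoticHillProfile(freq, q))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
})
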