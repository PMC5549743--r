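#' @include AllClasses.R
NULL

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Canonical habitat-transition code: OG < DE < SE, unordered pairs collapse.
.transitionCode <- function(h1, h2) {
  i <- match(h1, .HABITAT_LEVELS)
  j <- match(h2, .HABITAT_LEVELS)
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  paste(.HABITAT_LEVELS[lo], .HABITAT_LEVELS[hi], sep = "-")
}

.TRANSITION_LEVELS <- c("OG-OG", "OG-DE", "OG-SE", "DE-DE", "DE-SE", "SE-SE")
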