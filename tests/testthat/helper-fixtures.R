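# Fixture builders: small nested designs constructed in code.

# Metadata for a balanced n_loc x habitats x pph design.
design_meta <- function(n_loc = 1, habitats = c("OG", "DE", "SE"), pph = 5,
                        elevations = seq(500, by = 500, length.out = n_loc)) {
  grid <- expand.grid(rep = seq_len(pph), habitat = habitats,
                      location = seq_len(n_loc), stringsAsFactors = FALSE)
  data.frame(
    plot_id = sprintf("L%d_%s_%d", grid$location, grid$habitat, grid$rep),
    location = paste0("L", grid$location),
    elevation = elevations[grid$location],
    habitat = grid$habitat,
    mat = 26 - elevations[grid$location] * 0.005,
    map = 900 + elevations[grid$location] * 0.2,
    stringsAsFactors = FALSE)
}

# Experiment from a plots x species matrix (rows in design_meta order).
ie_from_matrix <- function(m, meta, species = NULL) {
  rownames(m) <- meta$plot_id
  if (is.null(colnames(m))) colnames(m) <- sprintf("sp%02d", seq_len(ncol(m)))
  IncidenceExperiment(m, meta, species)
}

# Random binary survey with a given Bernoulli fill probability.
rand_ie <- function(seed, n_loc = 2, pph = 3, n_sp = 12, p = 0.4,
                    habitats = c("OG", "DE", "SE")) {
  meta <- design_meta(n_loc, habitats, pph)
  m <- withr::with_seed(seed,
    matrix(rbinom(nrow(meta) * n_sp, 1, p), nrow(meta), n_sp))
  ie_from_matrix(m, meta)
}

# Landscape in which every plot holds exactly the same k species.
identical_ie <- function(k = 4, n_loc = 2, pph = 5, n_sp = 10) {
  meta <- design_meta(n_loc, pph = pph)
  row <- c(rep(1L, k), rep(0L, n_sp - k))
  ie_from_matrix(matrix(row, nrow(meta), n_sp, byrow = TRUE), meta)
}

# Brute-force Sorensen oracle on two presence vectors (set operations).
sorensen_oracle <- function(va, vb) {
  a <- which(va > 0); b <- which(vb > 0)
  A <- length(a); B <- length(b); C <- length(intersect(a, b))
  if (A + B == 0) return(NA_real_)
  1 - 2 * C / (A + B)
}
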