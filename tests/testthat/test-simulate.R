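test_that("simulation is reproducible from the seed", {
  cfg <- landscapeConfig(seed = 9, pool_size = 60L, occupancy = 0.5)
  a <- simulateLandscape(cfg)
  b <- simulateLandscape(cfg)
  expect_identical(incidence(a), incidence(b))
  expect_identical(speciesData(a), speciesData(b))
  c <- simulateLandscape(cfg, seed = 10)
  expect_false(identical(incidence(a), incidence(c)))
})

test_that("the saturating limit fills every plot and kills all turnover", {
  cfg <- landscapeConfig(n_locations = 2L, elevations = c(500, 1500),
                         pool_size = 15L, plots_per_habitat = 2L,
                         richness_width = Inf, niche_width = Inf,
                         habitat_affinity = habitatAffinity(0),
                         occupancy = 1, richness_max = 15, seed = 4)
  ie <- simulateLandscape(cfg)
  expect_true(all(incidence(ie) == 1L))
  pr <- pairwiseBeta(ie)
  expect_true(all(pr$beta == 0))
})

test_that("design shape always matches the configuration", {
  cfg <- landscapeConfig(n_locations = 3L, plots_per_habitat = 2L,
                         habitats = c("OG", "SE"), pool_size = 30L,
                         occupancy = 0.3, seed = 2)
  ie <- simulateLandscape(cfg)
  expect_equal(ncol(ie), 3 * 2 * 2)
  expect_equal(nrow(ie), 30)
  s <- designSummary(ie)
  expect_true(all(s$cells$n_plots == 2))
})

test_that("expectedAlpha is the exact Bernoulli-sum expectation", {
  # single species, flat curves: expectation equals the baseline occupancy
  cfg1 <- landscapeConfig(pool_size = 1L, occupancy = 0.5, richness_max = 1,
                          richness_width = Inf, niche_width = Inf,
                          habitat_affinity = habitatAffinity(0), seed = 1)
  expect_equal(expectedAlpha(cfg1, 2500, "OG"), 0.5)

  # habitat-constant affinities: the marginal expectation peaks at the
  # configured richness peak
  cfg <- landscapeConfig(habitat_affinity = habitatAffinity(0), seed = 1)
  grid <- seq(50, 3500, by = 50)
  ea <- expectedAlpha(cfg, grid, "OG")
  expect_equal(grid[which.max(ea)], 2500)
})

test_that("realised richness matches the analytic Poisson-binomial mean", {
  # one location at the richness peak, many replicate plots
  cfg <- landscapeConfig(n_locations = 1L, elevations = 2500,
                         plots_per_habitat = 67L, pool_size = 120L,
                         richness_peak = 2500, richness_width = 1000,
                         niche_width = 400, occupancy = 0.3,
                         seed = 21)
  ie <- simulateLandscape(cfg)
  sp <- speciesData(ie)
  pd <- plotData(ie)
  # independent oracle: per-species probabilities straight from the model
  for (h in c("OG", "DE", "SE")) {
    p <- 0.3 *
      exp(-((2500 - cfg@richness_peak)^2) / (2 * cfg@richness_width^2)) *
      exp(-((2500 - sp$niche_center)^2) / (2 * cfg@niche_width^2)) *
      cfg@habitat_affinity[cbind(sp$group, h)]
    ids <- pd$plot_id[pd$habitat == h]
    n <- length(ids)
    expect_equal(expectedAlpha(cfg, 2500, h, centers = sp$niche_center,
                               groups = sp$group), sum(p), tolerance = 1e-12)
    mc_se <- sqrt(sum(p * (1 - p)) / n)
    obs <- mean(alphaRichness(ie)[ids])
    expect_lt(abs(obs - sum(p)), 3 * mc_se)
  }
})

test_that("stronger habitat affinity contrast raises between-habitat beta", {
  mean_between <- function(contrast, seed) {
    cfg <- landscapeConfig(n_locations = 2L, elevations = c(2000, 2500),
                           pool_size = 80L, occupancy = 0.5,
                           niche_width = 500,
                           habitat_affinity = habitatAffinity(contrast),
                           seed = seed)
    ie <- simulateLandscape(cfg)
    pr <- suppressWarnings(pairwiseBeta(ie))
    mean(pr$beta[pr$habitat_a != pr$habitat_b & pr$defined])
  }
  for (seed in c(31, 32, 33)) {
    m <- vapply(c(0.15, 0.5, 0.85), mean_between, numeric(1), seed = seed)
    expect_true(all(diff(m) > 0))
  }
})

test_that("equal affinities make within- and between-habitat beta equal in expectation", {
  diffs <- vapply(c(41, 42, 43), function(seed) {
    cfg <- landscapeConfig(n_locations = 2L, elevations = c(2000, 2500),
                           pool_size = 80L, occupancy = 0.5,
                           niche_width = 500,
                           habitat_affinity = habitatAffinity(0),
                           seed = seed)
    pr <- suppressWarnings(pairwiseBeta(simulateLandscape(cfg)))
    ok <- pr$defined
    mean(pr$beta[ok & pr$habitat_a != pr$habitat_b]) -
      mean(pr$beta[ok & pr$habitat_a == pr$habitat_b])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.03)
})

test_that("invalid configurations are rejected", {
  expect_error(landscapeConfig(occupancy = 1.2), "occupancy")
  expect_error(landscapeConfig(pool_size = 5L, richness_max = 13),
               "pool_size")
  expect_error(landscapeConfig(elevations = c(100, 50), n_locations = 2L),
               "increasing")
  A <- habitatAffinity(0.5); A[1, 1] <- 2
  expect_error(landscapeConfig(habitat_affinity = A), "\\[0, 1\\]")
})
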