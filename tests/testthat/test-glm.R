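test_that("each response gets exactly 31 hierarchical candidates", {
  for (resp in c("alpha", "endemic", "beta")) {
    cs <- buildCandidateSet(resp)
    expect_length(cs, 31)
    expect_identical(cs, buildCandidateSet(resp))  # deterministic
    # intercept-only first, published best set last
    expect_length(cs[[1]]$terms, 0)
    fac <- if (resp == "beta") "transition" else "habitat"
    expect_true(fac %in% cs[[31]]$terms)
    expect_true(all(c("elev", "elev2") %in% cs[[31]]$terms))
    # hierarchy: every interaction has all its main effects
    for (m in cs) {
      inter <- grep(":", m$terms, value = TRUE)
      mains <- setdiff(m$terms, inter)
      for (tr in inter)
        expect_true(all(strsplit(tr, ":")[[1]] %in% mains))
    }
    # no duplicated candidates
    keys <- vapply(cs, function(m) paste(sort(m$terms), collapse = "+"), "")
    expect_false(anyDuplicated(keys) > 0)
  }
  expect_equal(buildCandidateSet("alpha")[[31]]$family, "nbinom")
  expect_equal(buildCandidateSet("endemic")[[31]]$family, "beta")
  expect_equal(buildCandidateSet("beta")[[31]]$family, "lognormal")
})

test_that("AICc follows the small-sample formula", {
  ll <- -250
  expect_equal(aicc(ll, 5, 120) - (-2 * ll + 2 * 5), 2 * 5 * 6 / 114)
  expect_equal(2 * 5 * 6 / 114, 0.5263, tolerance = 1e-4)
  # large n: correction vanishes, AICc -> AIC
  expect_equal(aicc(ll, 5, 1e9), -2 * ll + 10, tolerance = 1e-6)
  # equal fit, fewer parameters wins
  expect_lt(aicc(ll, 3, 120), aicc(ll, 4, 120))
  expect_warning(bad <- aicc(ll, 10, 11), "undefined")
  expect_true(is.na(bad))
})

test_that("an intercept-only negative binomial fit recovers the mean", {
  d <- data.frame(y = rep(7, 60), elev = 0, elev2 = 0, mat = 0, mat2 = 0,
                  map = 0, map2 = 0, habitat = "OG")
  cs <- buildCandidateSet("alpha")
  f <- fitCandidate(cs[[1]], d)
  expect_true(f$converged)
  expect_equal(unique(round(f$fitted, 6)), 7)
  # refits are deterministic
  f2 <- fitCandidate(cs[[1]], d)
  expect_identical(f$loglik, f2$loglik)
})

test_that("a quadratic signal is preferred over a linear one in likelihood", {
  set.seed(42)
  elev <- rep(seq(-1.5, 1.5, length.out = 24), each = 5)
  mu <- exp(2 - 1.2 * elev^2)
  d <- data.frame(y = rnbinom(length(elev), mu = mu, size = 8),
                  elev = elev, elev2 = elev^2, mat = 0, mat2 = 0,
                  map = 0, map2 = 0, habitat = "OG")
  cs <- buildCandidateSet("alpha")
  lin <- fitCandidate(cs[[which(vapply(cs, function(m)
    identical(m$terms, "elev"), logical(1)))]], d)
  quad <- fitCandidate(cs[[which(vapply(cs, function(m)
    identical(m$terms, c("elev", "elev2")), logical(1)))]], d)
  expect_gt(quad$loglik, lin$loglik)
})

test_that("ranking orders by AICc with a parsimony tie-break", {
  set.seed(7)
  elev <- rep(seq(-1.5, 1.5, length.out = 24), each = 5)
  d <- data.frame(y = rnbinom(120, mu = exp(2 - elev^2), size = 10),
                  elev = elev, elev2 = elev^2, mat = 0, mat2 = 0,
                  map = 0, map2 = 0, habitat = rep(c("OG", "DE", "SE"), 40))
  cs <- buildCandidateSet("alpha")[c(1, 2, 4, 7)]
  fits <- lapply(cs, fitCandidate, d = d)
  tab <- rankModels(fits)
  expect_equal(tab$delta_aicc[1], 0)
  expect_true(tab$best[1] || tab$k[which(tab$best)] <=
                tab$k[1])  # parsimony can promote within the 2-unit band
  expect_true(all(diff(tab$aicc) >= 0))
  expect_equal(attr(tab, "delta_worst"), max(tab$aicc) - min(tab$aicc))

  single <- rankModels(fits[1])
  expect_true(is.na(attr(single, "delta_next_best")))
  expect_equal(single$delta_aicc, 0)
})

test_that("pseudo-R2 is zero for the null model and scale-invariant", {
  set.seed(11)
  elev <- rep(seq(-1.5, 1.5, length.out = 24), each = 5)
  d <- data.frame(y = rnbinom(120, mu = exp(2 + 0.8 * elev), size = 10),
                  elev = elev, elev2 = elev^2, mat = 0, mat2 = 0,
                  map = 0, map2 = 0, habitat = "OG")
  cs <- buildCandidateSet("alpha")
  f0 <- fitCandidate(cs[[1]], d)
  expect_equal(pseudoR2(f0), 0)
  f1 <- fitCandidate(cs[[2]], d)  # elev only
  r_base <- pseudoR2(f1)
  expect_gt(r_base, 0)
  d2 <- d
  d2$elev <- d$elev * 10 + 3
  d2$elev2 <- d2$elev^2
  expect_equal(pseudoR2(fitCandidate(cs[[2]], d2)), r_base,
               tolerance = 1e-6)
})

test_that("near-perfect data drives pseudo-R2 toward one", {
  set.seed(12)
  elev <- rep(seq(-1.5, 1.5, length.out = 24), each = 5)
  mu <- exp(6 - 2 * elev^2)
  d <- data.frame(y = rnbinom(120, mu = mu, size = 1e4),
                  elev = elev, elev2 = elev^2, mat = 0, mat2 = 0,
                  map = 0, map2 = 0, habitat = "OG")
  cs <- buildCandidateSet("alpha")
  quad <- fitCandidate(cs[[which(vapply(cs, function(m)
    identical(m$terms, c("elev", "elev2")), logical(1)))]], d)
  expect_gt(pseudoR2(quad), 0.9)
})

test_that("log-normal model selection recovers a quadratic generating signal", {
  hits <- 0
  cs <- buildCandidateSet("beta")
  for (s in 1:20) {
    set.seed(400 + s)
    elev <- rep(seq(-1.5, 1.5, length.out = 20), each = 6)
    d <- data.frame(y = exp(-0.5 - 0.9 * elev^2 + rnorm(120, 0, 0.4)),
                    elev = elev, elev2 = elev^2, mat = 0, mat2 = 0,
                    map = 0, map2 = 0,
                    transition = factor(rep(c("OG-OG", "OG-DE", "OG-SE",
                                              "DE-DE", "DE-SE", "SE-SE"),
                                            20)))
    fits <- lapply(cs, fitCandidate, d = d)
    tab <- suppressWarnings(rankModels(fits))
    sel <- strsplit(tab$terms[tab$best], " \\+ ")[[1]]
    if ("elev2" %in% sel) hits <- hits + 1
  }
  expect_gte(hits, 16)
})

test_that("beta-family model selection recovers a quadratic generating signal", {
  cs_all <- buildCandidateSet("endemic")
  keep <- vapply(cs_all, function(m)
    all(m$terms %in% c("elev", "elev2", "mat", "mat2")), logical(1))
  cs <- cs_all[keep]  # elevation/temperature block subsets incl. intercept
  expect_gte(length(cs), 6)
  hits <- 0
  for (s in 1:20) {
    set.seed(600 + s)
    elev <- rep(seq(-1.5, 1.5, length.out = 20), each = 5)
    mu <- plogis(-1 + 1.5 * elev^2)
    d <- data.frame(y = rbeta(100, mu * 30, (1 - mu) * 30),
                    elev = elev, elev2 = elev^2, mat = rnorm(100),
                    habitat = "OG")
    d$mat2 <- d$mat^2
    fits <- lapply(cs, fitCandidate, d = d)
    tab <- suppressWarnings(rankModels(fits))
    sel <- strsplit(tab$terms[tab$best], " \\+ ")[[1]]
    if ("elev2" %in% sel) hits <- hits + 1
  }
  expect_gte(hits, 16)
})

test_that("the analysis tables carry standardized covariates and exclusions", {
  ie <- simulateLandscape(landscapeConfig(seed = 19))
  da <- analysisTable(ie, "alpha")
  expect_equal(nrow(da), 120)
  expect_equal(mean(da$elev), 0, tolerance = 1e-12)
  expect_equal(stats::sd(da$elev), 1, tolerance = 1e-12)
  expect_equal(da$elev2, da$elev^2)

  expect_message(de <- analysisTable(ie, "endemic"), "empty plot")
  expect_true(all(de$y > 0 & de$y < 1))

  expect_message(db <- analysisTable(ie, "beta"), "lowest-elevation")
  expect_false("50" %in% db$location)
  expect_s3_class(db$transition, "factor")
  expect_equal(nlevels(db$transition), 6)
  db2 <- analysisTable(ie, "beta", exclude_locations = character(0))
  expect_gt(nrow(db2), nrow(db))
})
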