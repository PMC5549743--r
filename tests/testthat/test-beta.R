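test_that("Sorensen pairs follow 2C/(A+B) on forced examples", {
  meta <- design_meta(1, pph = 2, habitats = c("OG", "DE"))
  m <- rbind(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),  # identical pair (4 species)
             c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
             c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0),  # A=4,B=6,C=3 with next
             c(1, 1, 1, 1, 1, 0, 1, 0, 0, 0))
  ie <- ie_from_matrix(m, meta)
  same <- sorensenPair(ie, meta$plot_id[1], meta$plot_id[2])
  expect_equal(same$S, 1); expect_equal(same$beta, 0)
  mix <- sorensenPair(ie, meta$plot_id[3], meta$plot_id[4])
  expect_equal(mix[, c("A", "B", "C")], data.frame(A = 4L, B = 6L, C = 3L))
  expect_equal(mix$S, 0.6); expect_equal(mix$beta, 0.4)

  # disjoint plots: beta = 1
  m2 <- rbind(c(1, 1, 1, 0, 0), c(0, 0, 0, 1, 1), c(1, 0, 0, 0, 0),
              c(0, 1, 0, 0, 0))
  ie2 <- ie_from_matrix(m2, design_meta(1, pph = 2, habitats = c("OG", "DE")))
  dis <- sorensenPair(ie2, "L1_OG_1", "L1_OG_2")
  expect_equal(dis$S, 0); expect_equal(dis$beta, 1)
})

test_that("Sorensen is symmetric, bounded, and matches the set oracle", {
  ie <- rand_ie(101, n_loc = 2, pph = 5, n_sp = 30, p = 0.35)
  m <- incidence(ie)
  ids <- plotIDs(ie)
  set.seed(202)
  for (k in 1:25) {  # spot symmetry on full objects
    ab <- sample(ids, 2)
    f <- sorensenPair(ie, ab[1], ab[2])
    r <- sorensenPair(ie, ab[2], ab[1])
    expect_equal(f$beta, r$beta)
    expect_equal(f$transition, r$transition)
  }
  # 1,000 random pairs against the brute-force set-intersection oracle
  set.seed(303)
  pool <- replicate(1000, sample(nrow(m), 2))
  for (k in seq_len(ncol(pool))) {
    i <- pool[1, k]; j <- pool[2, k]
    b <- sorensenPair(ie, ids[i], ids[j])$beta
    expect_identical(b >= 0 && b <= 1, TRUE)
    expect_equal(b, sorensen_oracle(m[i, ], m[j, ]))
  }
})

test_that("pairwise dissimilarities agree with vegan's binary Bray-Curtis", {
  skip_if_not_installed("vegan")
  ie <- rand_ie(55, n_loc = 1, pph = 5, n_sp = 40, p = 0.4)
  m <- incidence(ie)
  vd <- as.matrix(vegan::vegdist(m, method = "bray", binary = TRUE))
  pr <- pairwiseBeta(ie)
  for (r in seq_len(nrow(pr)))
    expect_equal(pr$beta[r], vd[pr$plot_a[r], pr$plot_b[r]],
                 tolerance = 1e-12)
})

test_that("comparison schemes produce the designed pair counts", {
  ie <- simulateLandscape(landscapeConfig(seed = 6, pool_size = 80L,
                                          occupancy = 0.5))
  w <- withinHabitatPairs(ie, "2500", "OG")
  expect_equal(nrow(w), 10)  # C(5,2)
  expect_true(all(table(c(w$plot_a, w$plot_b)) == 4))  # each vs other four
  b <- betweenHabitatPairs(ie, "2500", "OG", "SE")
  expect_equal(nrow(b), 25)  # 5 x 5
  expect_true(all(table(b$plot_a) == 5))
  pr <- pairwiseBeta(ie)
  one_loc <- pr[pr$location == "2500", ]
  expect_equal(sum(one_loc$habitat_a == one_loc$habitat_b), 30)   # 3 C(5,2)
  expect_equal(sum(one_loc$habitat_a != one_loc$habitat_b), 75)   # 3 x 25
  expect_equal(nrow(pr), 8 * 105)
})

test_that("degenerate cells and habitat arguments are rejected", {
  meta <- design_meta(1, pph = 2)
  ie <- ie_from_matrix(matrix(1L, 6, 4), meta)
  expect_equal(nrow(withinHabitatPairs(ie, "L1", "OG")), 1)  # C(2,2) = 1
  expect_error(betweenHabitatPairs(ie, "L1", "OG", "OG"), "distinct")
  meta1 <- design_meta(1, pph = 1)
  ie1 <- ie_from_matrix(matrix(1L, 3, 4), meta1)
  expect_error(withinHabitatPairs(ie1, "L1", "OG"), ">= 2 plots")
})

test_that("empty plots: one empty gives beta 1, two empty are undefined", {
  meta <- design_meta(1, pph = 3, habitats = "OG")
  m <- rbind(c(1, 1, 0, 0), rep(0, 4), rep(0, 4))
  ie <- ie_from_matrix(m, meta)
  expect_warning(pr <- pairwiseBeta(ie), "empty plots")
  one_empty <- pr[pr$plot_a == meta$plot_id[1] | pr$plot_b == meta$plot_id[1], ]
  expect_true(all(one_empty$beta == 1))
  both_empty <- pr[pr$plot_a == meta$plot_id[2] & pr$plot_b == meta$plot_id[3], ]
  expect_false(both_empty$defined)
  expect_true(is.na(both_empty$beta))
  expect_warning(sorensenPair(ie, meta$plot_id[2], meta$plot_id[3]),
                 "undefined")
})

test_that("identical landscscapes yield zero transition means everywhere", {
  ie <- identical_ie(k = 5, n_loc = 2)
  tm <- transitionMeans(ie, reps = 50, seed = 1)
  expect_equal(nrow(tm), 6)
  expect_equal(tm$mean_beta, rep(0, 6))
  expect_equal(tm$se, rep(0, 6))
  expect_equal(tm$n_pairs, c(20, 50, 50, 20, 50, 20))
})

test_that("transition summaries pool pairs and honour location exclusion", {
  ie <- simulateLandscape(landscapeConfig(seed = 8))
  tm <- transitionMeans(ie, exclude_locations = "50", reps = 0)
  expect_false(any(grepl("(^|;)50(;|$)", tm$locations_used)))
  tm_all <- transitionMeans(ie, reps = 0)
  expect_true(all(tm_all$n_pairs >= tm$n_pairs))
  expect_true(all(tm$mean_beta >= 0 & tm$mean_beta <= 1))
  # canonical transition ordering collapses unordered habitat pairs
  expect_equal(as.character(tm$transition),
               c("OG-OG", "OG-DE", "OG-SE", "DE-DE", "DE-SE", "SE-SE"))
})

test_that("the bootstrap is seeded, degenerate-safe and convergent", {
  ie <- simulateLandscape(landscapeConfig(seed = 12, pool_size = 80L,
                                          occupancy = 0.5))
  pr <- withinHabitatPairs(ie, "2100", "OG")
  expect_error(bootstrapSE(pr, ie, reps = 1), "reps")
  s1 <- bootstrapSE(pr, ie, reps = 300, seed = 5)
  s2 <- bootstrapSE(pr, ie, reps = 300, seed = 5)
  expect_identical(s1, s2)
  s3 <- bootstrapSE(pr, ie, reps = 300, seed = 6)
  expect_false(identical(s1, s3))

  # value-level resampling of constant values has zero spread
  prc <- pr; prc$beta <- rep(0.4, nrow(prc))
  expect_equal(bootstrapSE(prc, ie, reps = 100, seed = 1,
                           method = "values"), 0)

  # replicate-count convergence on a fixed cell
  a <- bootstrapSE(pr, ie, reps = 1000, seed = 7)
  b <- bootstrapSE(pr, ie, reps = 4000, seed = 7)
  expect_lt(abs(a - b) / b, 0.10)
})
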