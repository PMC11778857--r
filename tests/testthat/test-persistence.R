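test_that("persistence summaries match brute-force counting", {
  # toy: 4 communities, week 1 everyone present; week 8 three collapsed
  strains <- c(paste0("AdeOP", 1:4), paste0("LysOP", 1:4), "Cheater")
  mk <- function(week, counts) {
    m <- matrix(counts, 4, 9, byrow = TRUE,
                dimnames = list(NULL, strains))
    toyObs(m, week = week)
  }
  w1 <- mk(1, rep(100, 9))
  w8rows <- rbind(rep(0, 9), rep(0, 9), rep(0, 9),
                  c(100, 50, 0, 0, 80, 60, 0, 0, 0))
  w8 <- toyObs(matrix(w8rows, 4, 9, dimnames = list(NULL, strains)),
               week = 2)
  obs <- rbind(w1, w8)
  lay <- toyLayout(matrix(0, 4, 9, dimnames = list(NULL, strains)))
  pc <- persistenceCurve(obs, lay)
  r1 <- pc$retained[pc$retained$week == 1, ]
  expect_equal(r1$proportion[r1$k == 9], 1)
  c2 <- pc$collapse[pc$collapse$week == 2, ]
  expect_equal(c2$collapse_proportion, 0.75)
  expect_equal(c2$n_communities, 4)

  # oracle equivalence on random tables
  set.seed(14)
  for (i in 1:10) {
    counts <- matrix(rpois(45, 2) * rbinom(45, 1, 0.6), 5, 9,
                     dimnames = list(NULL, strains))
    obsR <- toyObs(counts, week = 1)
    pcR <- persistenceCurve(obsR, toyLayout(counts))
    retained <- rowSums(counts > 0)
    for (k in 0:9) {
      got <- pcR$retained$proportion[pcR$retained$k == k]
      expect_equal(got, mean(retained == k))
    }
  }
})

test_that("missing weeks are reported as gaps", {
  strains <- c("A", "B")
  o1 <- toyObs(matrix(1:4, 2, 2, dimnames = list(NULL, strains)), week = 1)
  o3 <- toyObs(matrix(1:4, 2, 2, dimnames = list(NULL, strains)), week = 3)
  lay <- toyLayout(matrix(0, 2, 2, dimnames = list(NULL, strains)))
  expect_error(persistenceCurve(rbind(o1, o3), lay), "missing week")
})

test_that("retained counts never increase in isolated communities", {
  lay <- smallLayout(seed = 16, wells = 8L)
  e <- runExperiment(lay, fastParams(weeks = 3L, sigmaEnv = 0),
                     policy = "none", seed = 16, stochastic = FALSE)
  obs <- observations(e)
  obs$key <- paste(obs$plate_id, obs$well_id)
  for (k in unique(obs$key)) {
    d <- obs[obs$key == k, ]
    ret <- tapply(d$score != "gone", d$week, sum)
    expect_true(all(diff(ret) <= 0))
  }
})

test_that("alpha comparison separates groups and respects identical ones", {
  same <- alphaComparison(rep(4, 20),
                          rep(c("dispersal_allowed", "isolated"), 10),
                          rep(c("M1", "M2"), each = 10), nPerm = 199,
                          seed = 1)
  expect_equal(same$difference, 0)
  expect_gt(same$p_perm, 0.99)

  sep <- alphaComparison(c(rep(8, 20), rep(1, 20)),
                         rep(c("dispersal_allowed", "isolated"),
                             each = 20),
                         rep(c("M1", "M2"), 20), nPerm = 1999, seed = 1)
  expect_equal(sep$difference, 7)
  expect_lte(sep$p_perm, 0.001)
  expect_true(sep$stratified)

  expect_warning(
    glob <- alphaComparison(rnorm(10, 5),
                            rep(c("dispersal_allowed", "isolated"),
                                each = 5),
                            rep(c("P1", "P2"), each = 5), nPerm = 99,
                            seed = 2),
    "single treatment")
  expect_false(glob$stratified)
})

test_that("beta trend recovers exact and noisy slopes with a valid
           permutation p-value", {
  weeks <- rep(1:7, times = 6)
  pairs <- rep(paste0("p", 1:6), each = 7)

  flat <- betaTrend(rep(0.4, 42), weeks, pairs, nPerm = 199, seed = 3)
  expect_equal(flat@slope, 0)
  expect_gt(flat@p_perm, 0.99)

  ramp <- betaTrend(0.05 * weeks, weeks, pairs, nPerm = 199, seed = 3)
  expect_equal(ramp@slope, 0.05, tolerance = 1e-12)
  expect_equal(ramp@p_perm, 1 / 200)

  # parameter recovery: slope 0.02, noise sd 0.05 (scaled-down replicate
  # count; the estimator is exactly least squares, so only noise enters)
  set.seed(15)
  est <- replicate(120, {
    b <- 0.1 + 0.02 * weeks + rnorm(42, 0, 0.05)
    betaTrend(b, weeks, pairs, nPerm = 9, seed = 1)@slope
  })
  expect_lt(abs(mean(est) - 0.02), 0.002)

  expect_error(betaTrend(1:3, c(1, 1, 1), c("a", "b", "c")), "two distinct")
})

test_that("betaByWeek produces pair-consistent long data", {
  lay <- smallLayout(seed = 17, wells = 12L)
  e <- runExperiment(lay, fastParams(weeks = 3L), policy = "none",
                     seed = 17)
  bw <- betaByWeek(e, weeks = 1:3, treatment = "isolated")
  expect_true(all(bw$beta >= 0 & bw$beta <= 1))
  expect_true(all(table(bw$pair) <= 3))
  expect_setequal(unique(bw$week), 1:3)
})

test_that("functional collapse counts communities whose AdeOPs are gone", {
  strains <- c(paste0("AdeOP", 1:4), paste0("LysOP", 1:4), "Cheater")
  counts <- rbind(c(rep(0, 4), rep(10, 4), 50),   # AdeOPs gone, rest alive
                  rep(20, 9),                      # intact
                  rep(0, 9))                       # fully collapsed
  dimnames(counts) <- list(NULL, strains)
  obs <- toyObs(counts)
  lay <- toyLayout(counts, communityType = "exploited")
  tot <- persistenceCurve(obs, lay, collapse = "total")$collapse
  fun <- persistenceCurve(obs, lay, collapse = "functional")$collapse
  expect_equal(tot$collapse_proportion, 1 / 3)
  expect_equal(fun$collapse_proportion, 2 / 3)
})
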