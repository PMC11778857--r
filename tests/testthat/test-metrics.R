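test_that("Hill diversity matches closed forms and limits", {
  expect_equal(hillDiversity(rep(3, 8), q = 1), 8)
  expect_equal(hillDiversity(c(0.5, 0.25, 0.25), q = 1), 2 * sqrt(2))
  expect_equal(hillDiversity(c(0, 7, 0), q = 0), 1)
  expect_equal(hillDiversity(c(0, 7, 0), q = 2), 1)
  expect_true(is.na(hillDiversity(c(0, 0, 0))))

  # continuity at q -> 1 and agreement with exp(Shannon) from vegan
  set.seed(3)
  for (i in 1:25) {
    x <- rexp(8) * rbinom(8, 1, 0.8)
    if (sum(x) == 0) next
    expect_lt(abs(hillDiversity(x, 0.9999) - hillDiversity(x, 1)), 1e-3)
    expect_equal(hillDiversity(x, 1),
                 exp(vegan::diversity(x, index = "shannon")),
                 tolerance = 1e-10)
  }
})

test_that("Hill diversity is bounded, permutation- and scale-invariant", {
  set.seed(4)
  for (i in 1:30) {
    x <- rpois(9, 4)
    if (sum(x) == 0) next
    for (q in c(0, 0.5, 1, 2)) {
      h <- hillDiversity(x, q)
      expect_gte(h, 1 - 1e-12)
      expect_lte(h, sum(x > 0) + 1e-12)
      expect_equal(hillDiversity(sample(x), q), h)
      expect_equal(hillDiversity(2 * x, q), h)
    }
  }
})

test_that("score-to-abundance mapping is monotone and validated", {
  map <- scoreAbundanceMap()
  expect_equal(scoreToAbundance("gone"), 0)
  vals <- scoreToAbundance(c("gone", "micro", "very_weak", "weak",
                             "strong"))
  expect_true(all(diff(vals) > 0))
  expect_gt(scoreToAbundance("strong", scoreAbundanceMap(2, 3, 4, 9)),
            scoreToAbundance("weak", scoreAbundanceMap(2, 3, 4, 9)))
  expect_error(scoreToAbundance("mega"), "unknown score")
  expect_error(scoreAbundanceMap(5, 4, 3, 2), "increasing")
})

test_that("Bray-Curtis matches hand arithmetic and its invariants", {
  expect_equal(brayCurtis(c(6, 0, 2), c(2, 2, 0)), 2 / 3)
  expect_equal(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(brayCurtis(c(5, 0), c(0, 3)), 1)
  expect_true(is.na(brayCurtis(c(0, 0), c(0, 0))))
  set.seed(5)
  for (i in 1:30) {
    x <- rpois(6, 3); y <- rpois(6, 3)
    if (sum(x) + sum(y) == 0) next
    b <- brayCurtis(x, y)
    expect_equal(brayCurtis(y, x), b)
    expect_gte(b, 0); expect_lte(b, 1)
    expect_equal(brayCurtis(2 * x, 2 * y), b)  # joint rescaling only
  }
})

test_that("pairwise beta equals the brute-force per-pair oracle and
           excludes collapsed communities", {
  set.seed(6)
  for (i in 1:10) {
    m <- matrix(rpois(40, 4), 5, 8)
    m[1, ] <- m[1, ] + 1  # ensure at least some usable rows
    d <- suppressMessages(pairwiseBeta(m))
    keep <- which(rowSums(m) > 0)
    for (a in seq_along(keep)) for (b in seq_len(a - 1)) {
      expect_equal(d[a, b], brayCurtis(m[keep[a], ], m[keep[b], ]),
                   tolerance = 1e-12)
    }
    expect_equal(diag(d), rep(0, length(keep)), ignore_attr = TRUE)
    expect_equal(d, t(d))
  }

  m <- matrix(rpois(30, 3) + 1, 5, 6,
              dimnames = list(paste0("c", 1:5), NULL))
  m[3, ] <- 0
  expect_message(d <- pairwiseBeta(m), "collapsed")
  expect_equal(dim(d), c(4, 4))
  expect_equal(attr(d, "excluded"), "c3")

  expect_error(suppressMessages(pairwiseBeta(matrix(0, 3, 2))),
               "at least two")

  # n identical communities -> all-zero matrix
  same <- matrix(rep(c(3, 1, 0, 2), each = 4), 4, 4)
  expect_true(all(suppressMessages(pairwiseBeta(same)) == 0))
})

test_that("NMDS recovers a planted planar configuration", {
  set.seed(7)
  pts <- matrix(rnorm(24), 12, 2)
  d <- dist(pts)
  fit <- runNMDS(d, k = 2, nRestarts = 20, seed = 7)
  expect_lt(fit@stress, 1e-3)
  pr <- vegan::procrustes(pts, fit@coordinates, symmetric = TRUE)
  expect_lt(pr$ss, 1e-2)

  # three points always embed exactly
  d3 <- dist(matrix(c(0, 0, 3, 0, 1, 2), 3, 2, byrow = TRUE))
  fit3 <- runNMDS(d3, k = 2, nRestarts = 10, seed = 3)
  expect_lt(fit3@stress, 1e-6)

  # same seed, same answer
  fitA <- runNMDS(d, k = 2, nRestarts = 5, seed = 11)
  fitB <- runNMDS(d, k = 2, nRestarts = 5, seed = 11)
  expect_identical(fitA@coordinates, fitB@coordinates)
  expect_identical(fitA@stress, fitB@stress)

  # degenerate all-equal dissimilarities are flagged
  dEq <- stats::as.dist(matrix(0.5, 4, 4) - diag(0.5, 4))
  fitEq <- suppressWarnings(runNMDS(dEq, k = 2, nRestarts = 3, seed = 1))
  expect_false(fitEq@converged)
})

test_that("abundance matrices pivot observations with both sources", {
  counts <- matrix(c(0, 200, 10, 60, 3, 0), 2, 3,
                   dimnames = list(NULL, c("AdeOP1", "AdeOP2", "LysOP1")))
  obs <- toyObs(counts)
  lay <- toyLayout(counts)
  mS <- abundanceMatrix(obs, lay, week = 1, source = "score")
  mC <- abundanceMatrix(obs, lay, week = 1, source = "count")
  expect_equal(unname(mC[, "AdeOP1"]), c(0, 200))
  expect_equal(unname(mS[1, "AdeOP2"]),
               unname(scoreAbundanceMap()[["very_weak"]]))
  expect_equal(unname(mS[2, "AdeOP1"]),
               unname(scoreAbundanceMap()[["strong"]]))
  expect_equal(attr(mS, "treatment"), rep("isolated", 2))
  expect_error(abundanceMatrix(obs, lay, week = 5), "no observations")
})

test_that("diversity conclusions are rank-stable across score maps", {
  lay <- smallLayout(seed = 8, wells = 12L)
  e <- runExperiment(lay, fastParams(weeks = 3L), policy = "none", seed = 8)
  sens <- suppressMessages(scoreSensitivity(e, week = 3))
  expect_true(all(sens$alpha_rank_cor > 0.5))
  expect_true(all(sens$beta_rank_cor > 0.5))
})
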