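test_that("weightedDelta combines shifts with the standard 15N scaling", {
  expect_identical(weightedDelta(0, 0), 0)
  expect_equal(weightedDelta(0.03, 0, alpha = 0.7), 0.03)
  expect_equal(weightedDelta(0.03, 0.15), 0.042426, tolerance = 1e-5)
  expect_equal(weightedDelta(0.03, 0.15, alpha = 0.2),
               sqrt(0.03^2 + (0.2 * 0.15)^2), tolerance = 1e-12)
  # vectorized
  expect_length(weightedDelta(c(0, 0.01), c(0.1, 0.2)), 2L)
})

test_that("siaScores normalizes per peak and averages across peaks", {
  free <- peakList("p1", 8.0, 120)
  bound <- lapply(c(A = 0.05, C = 0.10, G = 0.40, U = 0.20),
                  function(d) peakList("p1", 8.0 + d, 120))
  res <- siaScores(free, bound, "p1")
  expect_equal(unname(res$scores),
               c(0.125, 0.25, 1.0, 0.5), tolerance = 1e-12)
  # max normalized value per peak is exactly 1
  byPeak <- split(res$shiftRecords$normalized, res$shiftRecords$id)
  expect_true(all(vapply(byPeak, max, numeric(1)) == 1))

  # proportional shift patterns on two peaks give the same scores as one
  free2 <- peakList(c("p1", "p2"), c(8.0, 7.5), c(120, 115))
  bound2 <- lapply(c(A = 0.05, C = 0.10, G = 0.40, U = 0.20), function(d)
    peakList(c("p1", "p2"), c(8.0 + d, 7.5 + 0.3 * d), c(120, 115)))
  res2 <- siaScores(free2, bound2, c("p1", "p2"))
  expect_equal(res2$scores, res$scores, tolerance = 1e-12)

  # scale invariance: multiplying every shift by c > 0 changes nothing
  bound3 <- lapply(c(A = 0.05, C = 0.10, G = 0.40, U = 0.20),
                   function(d) peakList("p1", 8.0 + 7 * d, 120))
  expect_equal(siaScores(free, bound3, "p1")$scores, res$scores,
               tolerance = 1e-12)

  # all-zero peaks are excluded and reported
  free4 <- peakList(c("p1", "still"), c(8.0, 9.0), c(120, 125))
  bound4 <- lapply(c(A = 0.05, C = 0.10, G = 0.40, U = 0.20), function(d)
    peakList(c("p1", "still"), c(8.0 + d, 9.0), c(120, 125)))
  res4 <- siaScores(free4, bound4, c("p1", "still"))
  expect_identical(res4$excluded, "still")
  expect_equal(res4$scores, res$scores, tolerance = 1e-12)

  # id absent from a bound list names id and base
  boundBad <- bound
  boundBad$G <- peakList("other", 8.0, 120)
  expect_error(siaScores(free, boundBad, "p1"), "p1.*G")
})

test_that("noiseless simulated scores are proportional to fraction bound", {
  cfg <- smallConfig(noiseSd = 0, nPositions = 1L)
  sim <- simulateSIAExperiment(cfg)
  resp <- sim$model$responsiveIds
  res <- siaScores(sim$freePeaks, sim$boundPeaks[["1"]], resp)
  tr <- sim$truth[sim$truth$position == 1L, ]
  f <- tr$f_bound[match(names(res$scores), tr$base)]
  expect_equal(unname(res$scores), f / max(f), tolerance = 1e-9)
  expect_equal(max(res$scores), 1)
})

test_that("subsetSensitivity is zero for proportional shifts and positive under peak noise", {
  cfg <- smallConfig(noiseSd = 0, nPositions = 1L)
  sim <- simulateSIAExperiment(cfg)
  resp <- sim$model$responsiveIds
  sub1 <- resp[1:4]
  sub2 <- resp[3:6]
  dev <- subsetSensitivity(sim$freePeaks, sim$boundPeaks[["1"]],
                           list(sub1, sub1))
  expect_equal(unname(dev), rep(0, 4))
  # shared dmax + no noise: normalization removes peak identity entirely
  dev2 <- subsetSensitivity(sim$freePeaks, sim$boundPeaks[["1"]],
                            list(sub1, sub2))
  expect_lt(max(dev2), 1e-12)

  # perturb the tracked positions peak-wise (measurement noise): subsets
  # now disagree
  set.seed(31)
  noisy <- lapply(sim$boundPeaks[["1"]], function(pl) {
    pl$h_ppm <- pl$h_ppm + rnorm(nrow(pl), sd = 0.005)
    pl
  })
  dev3 <- subsetSensitivity(sim$freePeaks, noisy, list(sub1, sub2))
  # the top-ranked pool is pinned at 1 by the per-peak normalization, so at
  # least the remaining bases must disagree between subsets
  expect_gt(sum(dev3 > 0), 2L)
  expect_true(all(dev3 >= 0))
  expect_error(subsetSensitivity(sim$freePeaks, sim$boundPeaks[["1"]],
                                 list(sub1)), "two")
})

test_that("Kendall tau agrees with the stats oracle and known values", {
  tau <- siaPCA:::.kendallTau
  expect_identical(tau(c("G", "U", "C", "A"), c("G", "U", "C", "A")), 1)
  # one adjacent transposition among four items
  expect_equal(tau(c("G", "U", "C", "A"), c("G", "C", "U", "A")), 2 / 3,
               tolerance = 1e-12)
  expect_identical(tau(c("A", "C", "G", "U"), c("U", "G", "C", "A")), -1)
  set.seed(44)
  for (i in 1:25) {
    a <- sample(letters[1:6])
    b <- sample(letters[1:6])
    ra <- match(letters[1:6], a)
    rb <- match(letters[1:6], b)
    expect_equal(tau(a, b), unname(cor(ra, rb, method = "kendall")),
                 tolerance = 1e-12)
  }
})

test_that("compareMethods reports rank agreement and the component correlation pattern", {
  cfg <- smallConfig(noiseSd = 0)
  sim <- simulateSIAExperiment(cfg)
  pca <- pcaPreferenceTable(sim$stacks)
  sia <- siaPreferenceTable(sim$freePeaks, sim$boundPeaks,
                            sim$model$responsiveIds)
  cmp <- compareMethods(pca, sia)
  expect_identical(cmp$rankAgreement$tau, rep(1, cfg$nPositions))
  expect_true(all(cmp$rankAgreement$exact))
  expect_identical(nrow(cmp$componentCorrelation), 5L)
  # with dilution active, the shift signal lives on component 2
  r <- cmp$componentCorrelation$r
  expect_identical(which.max(r), 2L)

  # mismatched positions error
  sia1 <- siaPreferenceTable(sim$freePeaks, sim$boundPeaks["1"],
                             sim$model$responsiveIds)
  expect_error(compareMethods(pca, sia1), "positions")
})
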