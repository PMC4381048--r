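test_that("fractionBound solves the 1:1 binding quadratic exactly", {
  # no ligand, saturation limit, and the closed-form value at P=R=K=100
  expect_equal(fractionBound(100, 0, 5), 0)
  # stoichiometric tight-binding limit: 1 - f ~ sqrt(K/P) as K -> 0
  expect_equal(1 - fractionBound(100, 100, 1e-6), sqrt(1e-6 / 100),
               tolerance = 1e-3)
  expect_lt(abs(fractionBound(100, 100, 1e-6) -
                fractionBoundBisect(100, 100, 1e-6)), 1e-9)
  expect_equal(fractionBound(100, 100, 100), 0.381966, tolerance = 1e-6)
  expect_equal(fractionBound(100, 100, 100),
               fractionBoundBisect(100, 100, 100), tolerance = 1e-9)
  expect_error(fractionBound(0, 10, 1), "protein")
  expect_error(fractionBound(10, 10, 0), "Kd")
})

test_that("fractionBound agrees with the bisection oracle on 1000 random triples", {
  set.seed(101)
  P <- 10^runif(1000, -1, 3)
  R <- 10^runif(1000, -2, 3)
  K <- 10^runif(1000, -2, 4)
  f <- fractionBound(P, R, K)
  fb <- mapply(fractionBoundBisect, P, R, K)
  expect_lt(max(abs(f - fb)), 1e-9)
  # monotonicity: increasing in R, decreasing in K
  expect_true(all(fractionBound(50, c(1, 5, 25, 125), 10) ==
                  cummax(fractionBound(50, c(1, 5, 25, 125), 10))))
  expect_true(all(diff(fractionBound(50, 50, c(1, 10, 100, 1000))) < 0))
})

test_that("fast-exchange peak displacement equals fraction bound times the saturated shift", {
  cfg <- smallConfig(noiseSd = 0, nPositions = 1L)
  sim <- simulateSIAExperiment(cfg)
  model <- sim$model
  free <- sim$freePeaks
  for (base in c("A", "C", "G", "U")) {
    b <- simulateBoundPeakList(free, model, 1L, base)
    f <- fractionBoundBisect(model$proteinConc,
                             model$proteinConc * model$rnaRatio,
                             b$kd)
    expect_equal(b$fBound, f, tolerance = 1e-9)
    d <- model$dmaxByPeak
    idx <- match(d$id, free$id)
    expect_equal(b$peaks$h_ppm[idx] - free$h_ppm[idx], f * d$dmax_h,
                 tolerance = 1e-9)
    expect_equal(b$peaks$n_ppm[idx] - free$n_ppm[idx], f * d$dmax_n,
                 tolerance = 1e-9)
    # non-responsive peaks unchanged, intensities unchanged
    rest <- setdiff(free$id, d$id)
    ir <- match(rest, free$id)
    expect_identical(b$peaks$h_ppm[ir], free$h_ppm[ir])
    expect_identical(b$peaks$intensity, free$intensity)
  }
})

test_that("no-binding and saturation limits of the bound peak list", {
  cfg <- smallConfig(noiseSd = 0, nPositions = 1L)
  sim <- simulateSIAExperiment(cfg)
  model <- sim$model
  # kd -> infinity: output equals input
  model$kdByPool$kd[] <- 1e9
  b <- simulateBoundPeakList(sim$freePeaks, model, 1L, "A")
  expect_equal(b$peaks$h_ppm, sim$freePeaks$h_ppm, tolerance = 1e-6)
  expect_equal(b$peaks$n_ppm, sim$freePeaks$n_ppm, tolerance = 1e-6)
  # f_bound = 1: responsive peaks land exactly at free + dmax
  d <- model$dmaxByPeak
  shifted <- sim$freePeaks
  idx <- match(d$id, shifted$id)
  sat <- simulateBoundPeakList(sim$freePeaks, model, 1L, "A")
  satF <- sat$fBound
  model$kdByPool$kd[] <- 1e-9
  sat <- simulateBoundPeakList(sim$freePeaks, model, 1L, "A")
  expect_gt(sat$fBound, 1 - 1e-5)
  expect_equal(sat$peaks$h_ppm[idx],
               sim$freePeaks$h_ppm[idx] + sat$fBound * d$dmax_h,
               tolerance = 1e-12)
  # displacement ratio across two pools equals the f_bound ratio
  m2 <- sim$model
  m2$kdByPool$kd[m2$kdByPool$base == "A"] <- 10
  m2$kdByPool$kd[m2$kdByPool$base == "C"] <- 100
  m2$proteinConc <- 25; m2$rnaRatio <- 1
  bA <- simulateBoundPeakList(sim$freePeaks, m2, 1L, "A")
  bC <- simulateBoundPeakList(sim$freePeaks, m2, 1L, "C")
  fA <- fractionBoundBisect(25, 25, 10)
  fC <- fractionBoundBisect(25, 25, 100)
  dA <- bA$peaks$h_ppm[idx] - sim$freePeaks$h_ppm[idx]
  dC <- bC$peaks$h_ppm[idx] - sim$freePeaks$h_ppm[idx]
  nz <- abs(dC) > 0
  expect_equal(dA[nz] / dC[nz], rep(fA / fC, sum(nz)), tolerance = 1e-9)
})

test_that("rendering is deterministic, linear in scale, and places peaks correctly", {
  cfg <- smallConfig()
  pk <- peakList(c("p1", "p2"), c(8.0, 7.2), c(112, 124), c(1, 0.6))
  a <- renderSpectrum(pk, cfg, seed = 77L)
  b <- renderSpectrum(pk, cfg, seed = 77L)
  expect_identical(intensities(a), intensities(b))
  c <- renderSpectrum(pk, cfg, seed = 78L)
  expect_false(identical(intensities(a), intensities(c)))

  cfg0 <- smallConfig(noiseSd = 0)
  full <- renderSpectrum(pk, cfg0, intensityScale = 1)
  part <- renderSpectrum(pk, cfg0, intensityScale = 0.8)
  expect_equal(intensities(part), 0.8 * intensities(full), tolerance = 1e-12)

  # single unit peak: maximum at the nearest grid point, height ~ intensity
  one <- peakList("only", 8.0, 112, 1)
  s <- renderSpectrum(one, cfg0)
  idx <- which(intensities(s) == max(intensities(s)), arr.ind = TRUE)[1, ]
  expect_identical(unname(idx[1]), which.min(abs(ppmH(s) - 8.0)))
  expect_identical(unname(idx[2]), which.min(abs(ppmN(s) - 112)))
  expect_gt(max(intensities(s)), 0.5)
  expect_lte(max(intensities(s)), 1 + 1e-12)

  expect_error(renderSpectrum(peakList("off", 20, 112), cfg0),
               "'off'")
})

test_that("rendering is linear in peak intensity (noiseless)", {
  cfg0 <- smallConfig(noiseSd = 0)
  pk1 <- peakList(c("a", "b"), c(8.0, 7.4), c(110, 120), c(1, 1))
  pk2 <- pk1; pk2$intensity <- c(2, 3)
  s1 <- intensities(renderSpectrum(pk1, cfg0))
  s2 <- intensities(renderSpectrum(pk2, cfg0))
  sa <- intensities(renderSpectrum(pk1[1, ], cfg0))
  sb <- intensities(renderSpectrum(pk1[2, ], cfg0))
  expect_equal(s2, 2 * sa + 3 * sb, tolerance = 1e-12)
  expect_equal(s1, sa + sb, tolerance = 1e-12)
})

test_that("a simulated experiment has the expected structure and ground truth", {
  cfg <- smallConfig()
  sim <- simulateSIAExperiment(cfg)
  expect_length(sim$stacks, cfg$nPositions)
  for (st in sim$stacks) {
    expect_s4_class(st, "EnsembleStack")
    expect_identical(dim(st@reference@intensities), c(96L, 64L))
  }
  expect_identical(nrow(sim$truth), cfg$nPositions * 4L)
  # ground-truth f_bound ordering follows the Kd profile G > U > C > A
  tr <- sim$truth[sim$truth$position == 1L, ]
  expect_identical(tr$base[order(-tr$f_bound)], c("G", "U", "C", "A"))
  # determinism of the whole experiment
  sim2 <- simulateSIAExperiment(cfg)
  expect_identical(intensities(sim2$stacks[[1]]@bound$G),
                   intensities(sim$stacks[[1]]@bound$G))
})

test_that("equal affinities, no noise and no dilution give identical bound planes", {
  cfg <- smallConfig(noiseSd = 0, dilutionFactor = 1, nPositions = 1L,
                     kdByBase = c(A = 20, C = 20, G = 20, U = 20))
  sim <- simulateSIAExperiment(cfg)
  st <- sim$stacks[[1]]
  for (b in c("C", "G", "U"))
    expect_identical(intensities(st@bound[[b]]), intensities(st@bound$A))
})

test_that("the preferred pool's plane is farthest from the free plane (noiseless)", {
  cfg <- smallConfig(noiseSd = 0, dilutionFactor = 1, nPositions = 1L)
  sim <- simulateSIAExperiment(cfg)
  st <- sim$stacks[[1]]
  frob <- vapply(st@bound, function(s)
    sqrt(sum((intensities(s) - intensities(st@reference))^2)), numeric(1))
  expect_identical(names(which.max(frob)), "G")
  expect_identical(names(sort(frob)), c("A", "C", "U", "G"))
})
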