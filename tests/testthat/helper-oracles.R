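# Independent oracles and small fixtures used across the suite.

# Bisection root of the 1:1 binding quadratic P f^2 - (P+R+K) f + R = 0 on
# [0, 1]: independent of the closed form used by fractionBound().
fractionBoundBisect <- function(P, R, K, tol = 1e-12) {
  g <- function(f) P * f^2 - (P + R + K) * f + R
  lo <- 0; hi <- 1
  # g(0) = R >= 0, g(1) = -K < 0: root bracketed
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# SVD-based PCA oracle for spectra-as-rows matrices (uncentered): per
# component, projections = u_k * d_k, eigen-spectrum = v_k, variance
# fraction = d_k^2 / sum(X^2).
svdPcaOracle <- function(X, nComponents = min(dim(X))) {
  s <- svd(X, nu = nComponents, nv = nComponents)
  list(projections = sweep(s$u, 2L, s$d[seq_len(nComponents)], `*`),
       eigenSpectra = s$v,
       varianceFraction = s$d[seq_len(nComponents)]^2 / sum(X^2))
}

# Small, fast simulation settings (grid and peak count reduced; binding,
# dilution and noise parameters as in the default study conditions).
smallConfig <- function(...) {
  args <- list(n1 = 96L, n2 = 64L, nPeaks = 24L, nPositions = 2L, seed = 11L)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulationConfig, args)
}

# a tiny deterministic spectrum for I/O tests
tinySpectrum <- function(label = "free", seed = 5L) {
  set.seed(seed)
  Spectrum2D(matrix(rnorm(8 * 6), 8, 6),
             nmrAxis(8, sw = 2, first = 10, obs = 700.13),
             nmrAxis(6, sw = 10, first = 130, obs = 70.948),
             label)
}

expect_ranking <- function(scores, expected) {
  r <- rankBases(scores)
  expect_identical(as.character(r), expected)
}
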