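test_that("matrix dialect round trip is bit-exact for arbitrary spectra", {
  for (seed in c(1L, 2L, 3L)) {
    s <- tinySpectrum(label = sprintf("NN%dNN", seed), seed = seed)
    f <- withr::local_tempfile()
    writeSpectrum(s, f, "matrix")
    r <- readSpectrum(f, "matrix")
    expect_identical(intensities(r), unname(intensities(s)))
    expect_identical(axisH(r), axisH(s))
    expect_identical(axisN(r), axisN(s))
    expect_identical(specLabel(r), specLabel(s))
  }
})

test_that("nmrpipe2d round trip preserves data within float32 rounding", {
  s <- tinySpectrum(seed = 9L)
  f <- withr::local_tempfile()
  writeSpectrum(s, f, "nmrpipe2d")
  r <- readSpectrum(f, "nmrpipe2d")
  expect_identical(dim(r), dim(s))
  eps32 <- 2^-23
  expect_lt(max(abs(intensities(r) - intensities(s))),
            eps32 * max(abs(intensities(s))) * 2)
  expect_lt(abs(axisH(r)$sw - axisH(s)$sw), 1e-4)
  expect_lt(abs(axisH(r)$first - axisH(s)$first), 1e-4)
  expect_lt(abs(axisN(r)$first - axisN(s)$first), 1e-3)
})

test_that("a unit peak rendered at grid centre survives an nmrpipe round trip at the written index", {
  cfg <- smallConfig(noiseSd = 0)
  hGrid <- ppmH(renderSpectrum(peakList("x", 8, 115), cfg))
  nGrid <- ppmN(renderSpectrum(peakList("x", 8, 115), cfg))
  iH <- cfg$n1 %/% 2L
  iN <- cfg$n2 %/% 2L
  pk <- peakList("centre", hGrid[iH], nGrid[iN], 1)
  s <- renderSpectrum(pk, cfg)
  f <- withr::local_tempfile()
  writeSpectrum(s, f, "nmrpipe2d")
  r <- readSpectrum(f, "nmrpipe2d")
  expect_identical(which(intensities(r) == max(intensities(r)),
                         arr.ind = TRUE)[1, ],
                   c(row = iH, col = iN))
  expect_equal(max(intensities(r)), 1, tolerance = 1e-6)
})

test_that("pseudo-3D and malformed nmrpipe input are rejected with a named field", {
  s <- tinySpectrum()
  f <- withr::local_tempfile()
  writeSpectrum(s, f, "nmrpipe2d")
  # append two extra planes of data -> pseudo-3D
  con <- file(f, "ab")
  writeBin(rep(as.vector(intensities(s)), 2), con, size = 4L,
           endian = "little")
  close(con)
  expect_error(readSpectrum(f, "nmrpipe2d"), "pseudo-3D")

  g <- withr::local_tempfile()
  writeBin(rep(1.5, 600), g, size = 4L, endian = "little")
  expect_error(readSpectrum(g, "nmrpipe2d"), "FDMAGIC")

  h <- withr::local_tempfile()
  writeLines(c("SIAPCA-MATRIX 1", "n1: 4", "DATA"), h)
  expect_error(readSpectrum(h, "matrix"), "missing header field 'n2'")
  h2 <- withr::local_tempfile()
  writeLines("not a spectrum", h2)
  expect_error(readSpectrum(h2, "matrix"), "DATA sentinel")
})

test_that("writing a spectrum with non-finite values fails before any file is produced", {
  s <- tinySpectrum()
  s@intensities[2, 2] <- NaN
  f <- withr::local_tempfile()
  expect_error(writeSpectrum(s, f, "matrix"), "finite")
  expect_false(file.exists(f))
})

test_that("ppm axes decrease with index and match the axis metadata", {
  s <- tinySpectrum()
  h <- ppmH(s)
  expect_identical(h[1], axisH(s)$first)
  expect_true(all(diff(h) < 0))
  expect_equal(h[1] - h[length(h)],
               axisH(s)$sw * (axisH(s)$n - 1) / axisH(s)$n)
})

test_that("peak list round trip preserves ids and values; duplicates rejected", {
  set.seed(21)
  pk <- peakList(sprintf("G%02d", 1:100), runif(100, 6, 10),
                 runif(100, 105, 130), runif(100))
  f <- withr::local_tempfile(fileext = ".csv")
  writePeakList(pk, f)
  r <- readPeakList(f)
  expect_identical(r$id, pk$id)
  expect_equal(r$h_ppm, pk$h_ppm, tolerance = 1e-10)
  expect_equal(r$n_ppm, pk$n_ppm, tolerance = 1e-10)

  # tab-separated input with the same header parses too
  ft <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\th_ppm\tn_ppm\tintensity",
               "G45\t8.10\t120.5\t1.0",
               "A12\t7.95\t118.2\t0.7",
               "T03\t9.01\t125.0\t0.4"), ft)
  r2 <- readPeakList(ft)
  expect_identical(r2$id, c("G45", "A12", "T03"))

  expect_error(peakList(c("G45", "G45"), c(8, 8.1), c(120, 121)), "G45")
  fd <- withr::local_tempfile()
  writeLines(c("id,h_ppm,n_ppm,intensity", "G45,8.1,120.5,1",
               "G45,8.2,121.0,1"), fd)
  expect_error(readPeakList(fd), "G45")
  fm <- withr::local_tempfile()
  writeLines(c("id,h_ppm,intensity", "G45,8.1,1"), fm)
  expect_error(readPeakList(fm), "n_ppm")
})

test_that("pool labels place the base at the scanned position among Ns", {
  expect_identical(poolLabelName(4, "A"), "NNNAN")
  expect_identical(poolLabelName(1, "G"), "GNNNN")
  expect_identical(poolLabelName(2, "U", length = 3), "NUN")
  expect_error(poolLabelName(6, "A"), "position")
})

test_that("stackEnsemble validates grids, calibration and completeness", {
  cfg <- smallConfig(noiseSd = 0)
  pk <- peakList("p1", 8, 115)
  mk <- function(label) renderSpectrum(pk, cfg, label = label)
  bound <- list(A = mk("A"), C = mk("C"), G = mk("G"), U = mk("U"))
  st <- stackEnsemble(mk("free"), bound, 1L)
  expect_s4_class(st, "EnsembleStack")
  expect_identical(names(st@bound), c("A", "C", "G", "U"))

  # wrong dimensions on one plane, named in the error
  badCfg <- smallConfig(n1 = 95L, noiseSd = 0)
  bound$G <- renderSpectrum(pk, badCfg, label = "G")
  expect_error(stackEnsemble(mk("free"), bound, 1L), "'G'")
  bound$G <- mk("G")

  # same dims, different spectral width -> calibration error
  drift <- mk("G")
  drift@axisH$sw <- drift@axisH$sw + 1e-4
  bound$G <- drift
  expect_error(stackEnsemble(mk("free"), bound, 1L), "calibration")
  bound$G <- NULL
  expect_error(stackEnsemble(mk("free"), bound, 1L), "'G'")
})
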