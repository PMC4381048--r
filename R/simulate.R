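#' @include spectra-io.R
NULL

#' Fraction of protein bound at equilibrium
#'
#' Exact root of the 1:1 binding quadratic
#' \eqn{P f^2 - (P + R + K) f + R = 0}:
#' \deqn{f = \frac{(P + R + K) - \sqrt{(P + R + K)^2 - 4 P R}}{2 P}}
#' Monotone increasing in ligand concentration and decreasing in Kd. In fast
#' exchange, observed peak displacement equals \eqn{f} times the saturated
#' complex shift, so each pool's one effective Kd maps directly onto its
#' average shift.
#'
#' @param proteinTotal total protein concentration, uM (> 0).
#' @param rnaTotal total RNA concentration, uM (>= 0).
#' @param kd effective dissociation constant, uM (> 0).
#' @return fraction bound in [0, 1]; vectorized over all arguments.
#' @examples
#' fractionBound(100, 100, 100)  # 0.381966...
#' @export
fractionBound <- function(proteinTotal, rnaTotal, kd) {
  if (any(!is.finite(proteinTotal)) || any(proteinTotal <= 0))
    stop("protein concentration must be positive")
  if (any(!is.finite(rnaTotal)) || any(rnaTotal < 0))
    stop("RNA concentration must be non-negative")
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("Kd must be positive")
  s <- proteinTotal + rnaTotal + kd
  # discriminant expanded as a sum of non-negative terms so the tight-binding
  # corner (kd -> 0, P ~ R) does not lose precision to cancellation
  disc <- (proteinTotal - rnaTotal)^2 +
    2 * kd * (proteinTotal + rnaTotal) + kd^2
  f <- 2 * rnaTotal / (s + sqrt(disc))
  pmin(pmax(f, 0), 1)
}

#' Binding model for a simulated SIA experiment
#'
#' One effective Kd per (position, base) pool stands in for the pool's
#' quasi-degenerate mixture: a single fast-exchange species with the pool's
#' average fraction bound reproduces the observable average shift. The
#' saturated-complex shifts (dmax) are shared across the four pools of a
#' position, so pools differ only in fraction bound.
#'
#' @param proteinConc total protein concentration, uM.
#' @param rnaRatio RNA:protein concentration ratio (1, 2 or 4 are typical).
#' @param kdByPool data.frame with columns \code{position}, \code{base},
#'   \code{kd} (uM), covering every pool to be simulated.
#' @param dmaxByPeak data.frame with columns \code{id}, \code{dmax_h},
#'   \code{dmax_n}: the saturated shift of each interface-responsive peak,
#'   in ppm.
#' @param responsiveIds character vector of responsive peak ids; every one
#'   must have a dmax entry.
#' @return a \code{BindingModel} list.
#' @export
bindingModel <- function(proteinConc, rnaRatio, kdByPool, dmaxByPeak,
                         responsiveIds = dmaxByPeak$id) {
  if (!is.finite(proteinConc) || proteinConc <= 0)
    stop("protein concentration must be positive")
  if (!is.finite(rnaRatio) || rnaRatio < 0)
    stop("RNA:protein ratio must be non-negative")
  need <- c("position", "base", "kd")
  if (!all(need %in% names(kdByPool)))
    stop("kdByPool must have columns position, base, kd")
  if (any(kdByPool$kd <= 0)) stop("all Kd values must be positive")
  if (!all(c("id", "dmax_h", "dmax_n") %in% names(dmaxByPeak)))
    stop("dmaxByPeak must have columns id, dmax_h, dmax_n")
  orphan <- setdiff(responsiveIds, dmaxByPeak$id)
  if (length(orphan))
    stop("responsive peak '", orphan[1], "' has no dmax entry")
  structure(list(proteinConc = proteinConc, rnaRatio = rnaRatio,
                 kdByPool = kdByPool, dmaxByPeak = dmaxByPeak,
                 responsiveIds = as.character(responsiveIds)),
            class = "BindingModel")
}

.poolKd <- function(model, position, base) {
  k <- model$kdByPool
  hit <- k$kd[k$position == position & k$base == base]
  if (length(hit) != 1L)
    stop(sprintf("no Kd defined for pool position %d base %s", position, base))
  hit
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: a 290 x 256 point amide-region
#' grid, 100 backbone amide peaks of which 30\% respond to RNA binding,
#' per-pool effective Kds of 2/10/50/250 uM (preference order G > U > C > A)
#' at 25 uM protein with a 1:1 RNA:protein ratio, 10\% dilution of the bound
#' samples and Gaussian noise at 0.5\% of the maximum free-spectrum
#' intensity. Saturated shifts are drawn once per responsive peak (sd 0.05
#' ppm 1H, 0.25 ppm 15N) and shared across the four pools of each position.
#'
#' @param n1,n2 grid points in the direct 1H and indirect 15N dimension.
#' @param axisH,axisN axis calibration ([nmrAxis()]); defaults cover the
#'   amide region (1H 5.5-11.5 ppm at 700.13 MHz, 15N 95-135 ppm).
#' @param nPeaks number of amide peaks.
#' @param responsiveFraction fraction of peaks that shift on binding.
#' @param linewidthH,linewidthN Lorentzian half-width at half-maximum, ppm.
#' @param dilutionFactor intensity scale applied to every bound spectrum
#'   (RNA addition dilutes the sample).
#' @param noiseSd additive Gaussian noise sd as a fraction of the maximum
#'   noiseless free-spectrum intensity.
#' @param dmaxSdH,dmaxSdN sd of the saturated-shift draws, ppm.
#' @param proteinConc protein concentration, uM.
#' @param rnaRatio RNA:protein ratio.
#' @param kdByBase named numeric, effective Kd (uM) per base, applied at
#'   every position.
#' @param nPositions number of scanned RNA positions.
#' @param rnaLength RNA length (for pool display names).
#' @param seed master seed; all per-plane noise seeds derive from it.
#' @return a \code{SimulationConfig} list.
#' @export
simulationConfig <- function(n1 = 290L, n2 = 256L,
                             axisH = nmrAxis(n1, sw = 6, first = 11.5,
                                             obs = 700.13),
                             axisN = nmrAxis(n2, sw = 40, first = 135,
                                             obs = 70.948),
                             nPeaks = 100L, responsiveFraction = 0.3,
                             linewidthH = 0.02, linewidthN = 0.15,
                             dilutionFactor = 0.9, noiseSd = 0.005,
                             dmaxSdH = 0.05, dmaxSdN = 0.25,
                             proteinConc = 25, rnaRatio = 1,
                             kdByBase = c(A = 250, C = 50, G = 2, U = 10),
                             nPositions = 5L, rnaLength = 5L, seed = 42L) {
  if (axisH$n != n1 || axisN$n != n2)
    stop("axis point counts must match n1/n2")
  if (linewidthH <= 0 || linewidthN <= 0) stop("linewidths must be positive")
  if (noiseSd < 0) stop("noise sd must be non-negative")
  if (dilutionFactor < 0 || dilutionFactor > 1)
    stop("dilution factor must lie in [0, 1]")
  if (responsiveFraction < 0 || responsiveFraction > 1)
    stop("responsive fraction must lie in [0, 1]")
  if (!setequal(names(kdByBase), BASES))
    stop("kdByBase must name all of A, C, G, U")
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 axisH = axisH, axisN = axisN,
                 nPeaks = as.integer(nPeaks),
                 responsiveFraction = responsiveFraction,
                 linewidthH = linewidthH, linewidthN = linewidthN,
                 dilutionFactor = dilutionFactor, noiseSd = noiseSd,
                 dmaxSdH = dmaxSdH, dmaxSdN = dmaxSdN,
                 proteinConc = proteinConc, rnaRatio = rnaRatio,
                 kdByBase = kdByBase[BASES],
                 nPositions = as.integer(nPositions),
                 rnaLength = as.integer(rnaLength),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat(sprintf("SimulationConfig: %d x %d grid, %d peaks (%.0f%% responsive), %d positions\n",
              x$n1, x$n2, x$nPeaks, 100 * x$responsiveFraction, x$nPositions))
  cat(sprintf("  P = %g uM, R:P = %g, Kd (uM): %s\n", x$proteinConc,
              x$rnaRatio,
              paste(sprintf("%s=%g", names(x$kdByBase), x$kdByBase),
                    collapse = " ")))
  cat(sprintf("  dilution %.2f, noise sd %.3f, seed %d\n",
              x$dilutionFactor, x$noiseSd, x$seed))
  invisible(x)
}

# run expr with a private RNG stream; the caller's RNG state is untouched
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# deterministic per-plane child seed, kept under 2^31
.planeSeed <- function(seed, position, plane) {
  as.integer(((seed %% 1000003) * 2053 + position * 97 + plane * 13) %%
               2147483647) + 1L
}

# Peaks are placed away from the grid edges so lineshape tails and binding
# shifts stay on-grid.
.simulateFreePeaks <- function(config) {
  marginH <- 0.3
  marginN <- 2.5
  hRange <- c(config$axisH$first - config$axisH$sw + marginH,
              config$axisH$first - marginH)
  nRange <- c(config$axisN$first - config$axisN$sw + marginN,
              config$axisN$first - marginN)
  n <- config$nPeaks
  peakList(id = sprintf("R%03d", seq_len(n)),
           h_ppm = stats::runif(n, hRange[1], hRange[2]),
           n_ppm = stats::runif(n, nRange[1], nRange[2]),
           intensity = stats::runif(n, 0.5, 1.0))
}

.defaultModel <- function(config, peaks) {
  nResp <- round(config$nPeaks * config$responsiveFraction)
  responsive <- peaks$id[seq_len(nResp)]
  dmax <- data.frame(id = responsive,
                     dmax_h = stats::rnorm(nResp, 0, config$dmaxSdH),
                     dmax_n = stats::rnorm(nResp, 0, config$dmaxSdN),
                     stringsAsFactors = FALSE)
  kd <- expand.grid(position = seq_len(config$nPositions), base = BASES,
                    stringsAsFactors = FALSE)
  kd$kd <- config$kdByBase[kd$base]
  bindingModel(config$proteinConc, config$rnaRatio, kd, dmax, responsive)
}

#' Peak list of a pool-bound sample under fast exchange
#'
#' Each responsive peak moves by \code{fractionBound * dmax} in both
#' dimensions (the population-weighted average position); non-responsive
#' peaks and all intensities are unchanged at this stage.
#'
#' @param freePeaks free-protein peak list.
#' @param model a [bindingModel()].
#' @param position,base the pool (scanned position and fixed base).
#' @return list with the shifted peak list (\code{peaks}) and the pool's
#'   fraction bound (\code{fBound}).
#' @export
simulateBoundPeakList <- function(freePeaks, model, position, base) {
  kd <- .poolKd(model, position, base)
  f <- fractionBound(model$proteinConc,
                     model$proteinConc * model$rnaRatio, kd)
  peaks <- freePeaks
  idx <- match(model$responsiveIds, peaks$id)
  if (anyNA(idx))
    stop("responsive peak '", model$responsiveIds[which(is.na(idx))[1]],
         "' absent from free peak list")
  d <- model$dmaxByPeak[match(model$responsiveIds, model$dmaxByPeak$id), ]
  peaks$h_ppm[idx] <- peaks$h_ppm[idx] + f * d$dmax_h
  peaks$n_ppm[idx] <- peaks$n_ppm[idx] + f * d$dmax_n
  list(peaks = peaks, fBound = f, kd = kd)
}

#' Render a peak list into a 2D spectrum
#'
#' Sums separable 2D Lorentzian lineshapes (product of 1D Lorentzians with
#' the configured half-widths at half-maximum), scales by
#' \code{intensityScale}, and adds i.i.d. Gaussian noise with sd =
#' \code{config$noiseSd} times the maximum noiseless intensity of the
#' reference (by default this spectrum's own noiseless maximum; pass
#' \code{noiseRef} to tie noise amplitude to the free plane across an
#' ensemble). Deterministic given \code{seed}.
#'
#' @param peaks a peak-list data.frame; every peak must lie inside the grid
#'   ppm ranges.
#' @param config a [simulationConfig()].
#' @param intensityScale multiplicative scale (1 for the free sample,
#'   \code{dilutionFactor} for bound samples).
#' @param seed RNG seed for the noise draw.
#' @param label label for the returned spectrum.
#' @param noiseRef optional reference amplitude for the noise sd.
#' @return a [Spectrum2D-class].
#' @export
renderSpectrum <- function(peaks, config, intensityScale = 1, seed = 1L,
                           label = "", noiseRef = NULL) {
  .validatePeakList(peaks)
  hGrid <- .axisPpm(config$axisH)
  nGrid <- .axisPpm(config$axisN)
  hOut <- peaks$h_ppm > max(hGrid) | peaks$h_ppm < min(hGrid)
  nOut <- peaks$n_ppm > max(nGrid) | peaks$n_ppm < min(nGrid)
  if (any(hOut | nOut))
    stop("peak '", peaks$id[which(hOut | nOut)[1]],
         "' falls outside the grid ppm range")
  m <- matrix(0, config$n1, config$n2)
  for (i in seq_len(nrow(peaks))) {
    lh <- 1 / (1 + ((hGrid - peaks$h_ppm[i]) / config$linewidthH)^2)
    ln <- 1 / (1 + ((nGrid - peaks$n_ppm[i]) / config$linewidthN)^2)
    m <- m + peaks$intensity[i] * tcrossprod(lh, ln)
  }
  ref <- if (is.null(noiseRef)) max(abs(m)) else noiseRef
  m <- m * intensityScale
  if (config$noiseSd > 0 && ref > 0) {
    noise <- .withSeed(seed,
      stats::rnorm(length(m), sd = config$noiseSd * ref))
    m <- m + noise
  }
  Spectrum2D(m, config$axisH, config$axisN, label)
}

#' Simulate a complete SIA experiment
#'
#' For every scanned position, renders the free-protein spectrum
#' (intensity scale 1) and the four pool-bound spectra (intensity scale =
#' \code{dilutionFactor}) on a common grid, with per-plane noise seeds
#' derived deterministically from \code{config$seed}. Ground truth (per-pool
#' fraction bound and the noiseless bound peak lists) is returned alongside
#' for validation.
#'
#' @param config a [simulationConfig()].
#' @param model optional [bindingModel()]; by default one is drawn from the
#'   config (Kd profile from \code{kdByBase}, saturated shifts drawn once
#'   and shared across pools).
#' @return list with \code{stacks} (named list of [EnsembleStack-class],
#'   one per position), \code{truth} (data.frame position/base/kd/f_bound),
#'   \code{freePeaks}, \code{boundPeaks} (nested by position then base) and
#'   \code{model}.
#' @examples
#' cfg <- simulationConfig(n1 = 64, n2 = 48, nPeaks = 10, nPositions = 1)
#' sim <- simulateSIAExperiment(cfg)
#' sim$stacks[[1]]
#' @export
simulateSIAExperiment <- function(config, model = NULL) {
  freePeaks <- .withSeed(config$seed, .simulateFreePeaks(config))
  if (is.null(model))
    model <- .withSeed(config$seed + 1L, .defaultModel(config, freePeaks))
  stacks <- list()
  truth <- NULL
  boundPeaks <- list()
  # shared noise amplitude: the free plane's noiseless maximum
  freeNoiseless <- {
    cfg0 <- config; cfg0$noiseSd <- 0
    max(abs(intensities(renderSpectrum(freePeaks, cfg0))))
  }
  for (pos in seq_len(config$nPositions)) {
    free <- renderSpectrum(freePeaks, config, intensityScale = 1,
                           seed = .planeSeed(config$seed, pos, 0L),
                           label = "free", noiseRef = freeNoiseless)
    bound <- list()
    boundPeaks[[as.character(pos)]] <- list()
    for (bi in seq_along(BASES)) {
      base <- BASES[bi]
      sim <- simulateBoundPeakList(freePeaks, model, pos, base)
      bound[[base]] <- renderSpectrum(
        sim$peaks, config, intensityScale = config$dilutionFactor,
        seed = .planeSeed(config$seed, pos, bi),
        label = poolLabelName(pos, base, config$rnaLength),
        noiseRef = freeNoiseless)
      boundPeaks[[as.character(pos)]][[base]] <- sim$peaks
      truth <- rbind(truth, data.frame(position = pos, base = base,
                                       kd = sim$kd, f_bound = sim$fBound,
                                       stringsAsFactors = FALSE))
    }
    stacks[[as.character(pos)]] <- stackEnsemble(free, bound, pos)
  }
  list(stacks = stacks, truth = truth, freePeaks = freePeaks,
       boundPeaks = boundPeaks, model = model)
}
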