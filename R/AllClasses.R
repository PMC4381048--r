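#' @import methods
NULL

BASES <- c("A", "C", "G", "U")
PLANE_LABELS <- c("free", BASES)

#' Construct an NMR axis descriptor
#'
#' Describes one frequency-domain axis of a processed 2D spectrum. Grid
#' indexing is 0-based in the formulas below; the ppm of grid point \eqn{i}
#' is \code{first - i * sw / n}, so ppm decreases with increasing index
#' (standard NMR convention) and the spacing follows the usual
#' frequency-domain convention of \code{sw / n} per point.
#'
#' @param n number of grid points (>= 2).
#' @param sw spectral width in ppm.
#' @param first ppm value of the first grid point (the downfield edge).
#' @param obs observe (carrier) frequency in MHz; used only to convert
#'   between ppm and Hz when reading or writing NMRPipe files.
#' @return a named list with elements \code{n}, \code{sw}, \code{first},
#'   \code{obs}.
#' @examples
#' nmrAxis(290, sw = 6, first = 11.5, obs = 700.13)
#' @export
nmrAxis <- function(n, sw, first, obs = 1) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L)
    stop("axis must have at least 2 points")
  if (!is.finite(sw) || sw <= 0) stop("spectral width must be positive")
  if (!is.finite(first)) stop("first-point ppm must be finite")
  if (!is.finite(obs) || obs <= 0) stop("observe frequency must be positive")
  list(n = n, sw = as.numeric(sw), first = as.numeric(first),
       obs = as.numeric(obs))
}

.checkAxis <- function(axis, nExpected, what) {
  if (!is.list(axis) || !all(c("n", "sw", "first", "obs") %in% names(axis)))
    return(sprintf("%s axis must be a list with n, sw, first, obs", what))
  if (axis$n != nExpected)
    return(sprintf("%s axis has %d points but matrix dimension is %d",
                   what, axis$n, nExpected))
  if (!is.finite(axis$sw) || axis$sw <= 0)
    return(sprintf("%s axis spectral width must be positive", what))
  if (!is.finite(axis$first))
    return(sprintf("%s axis first-point ppm must be finite", what))
  NULL
}

#' Spectrum2D: a calibrated 2D frequency-domain NMR spectrum
#'
#' Holds the real-valued intensity matrix of a processed 2D 1H-15N
#' correlation spectrum together with the ppm calibration of both axes and a
#' free-form label (e.g. \code{"free"} or an RNA pool name such as
#' \code{"NNNAN"}). Rows index the direct 1H dimension, columns the indirect
#' 15N dimension.
#'
#' @slot intensities numeric matrix, n1 x n2, all values finite.
#' @slot axisH,axisN axis descriptors as built by [nmrAxis()]; point counts
#'   must match the matrix dimensions.
#' @slot label character scalar tag.
#' @seealso [readSpectrum()], [writeSpectrum()], [stackEnsemble()]
#' @export
setClass("Spectrum2D",
  representation(intensities = "matrix", axisH = "list", axisN = "list",
                 label = "character"))

setValidity("Spectrum2D", function(object) {
  m <- object@intensities
  if (!is.numeric(m)) return("intensities must be numeric")
  if (any(!is.finite(m))) return("intensities contain non-finite values")
  if (nrow(m) < 2L || ncol(m) < 2L)
    return("spectrum must have at least 2 points in each dimension")
  msg <- .checkAxis(object@axisH, nrow(m), "1H")
  if (!is.null(msg)) return(msg)
  msg <- .checkAxis(object@axisN, ncol(m), "15N")
  if (!is.null(msg)) return(msg)
  if (length(object@label) != 1L) return("label must be a single string")
  TRUE
})

#' Create a Spectrum2D
#'
#' @param intensities numeric matrix (direct 1H dimension in rows, indirect
#'   15N dimension in columns).
#' @param axisH,axisN axis descriptors from [nmrAxis()].
#' @param label free-form tag, e.g. \code{"free"} or \code{"NNNAN"}.
#' @return a [Spectrum2D-class] object.
#' @examples
#' s <- Spectrum2D(matrix(0, 4, 3),
#'                 nmrAxis(4, 2, 10), nmrAxis(3, 10, 130), "free")
#' dim(s)
#' @export
Spectrum2D <- function(intensities, axisH, axisN, label = "") {
  new("Spectrum2D", intensities = intensities, axisH = axisH,
      axisN = axisN, label = as.character(label))
}

#' EnsembleStack: one free plus four pool-bound spectra
#'
#' The PCA input unit: the free-protein reference spectrum and the four
#' spectra of complexes with the A/C/G/U RNA pools for one scanned sequence
#' position, all on an identical grid. Plane order is fixed as
#' \code{[free, A, C, G, U]}.
#'
#' @slot reference the free-protein [Spectrum2D-class].
#' @slot bound named list of four [Spectrum2D-class] objects, names
#'   \code{A, C, G, U} in that order.
#' @slot position integer, the scanned RNA position.
#' @seealso [stackEnsemble()]
#' @export
setClass("EnsembleStack",
  representation(reference = "Spectrum2D", bound = "list",
                 position = "integer"))

.calibrationEqual <- function(a, b, tol = 1e-6) {
  a$n == b$n && abs(a$sw - b$sw) <= tol && abs(a$first - b$first) <= tol
}

setValidity("EnsembleStack", function(object) {
  if (!identical(names(object@bound), BASES))
    return("bound spectra must be named A, C, G, U in that order")
  if (!all(vapply(object@bound, is, logical(1), "Spectrum2D")))
    return("bound entries must be Spectrum2D objects")
  ref <- object@reference
  for (b in BASES) {
    s <- object@bound[[b]]
    if (!identical(dim(s@intensities), dim(ref@intensities)))
      return(sprintf("grid mismatch: spectrum '%s' has %d x %d points, reference has %d x %d",
                     b, nrow(s@intensities), ncol(s@intensities),
                     nrow(ref@intensities), ncol(ref@intensities)))
    if (!.calibrationEqual(s@axisH, ref@axisH) ||
        !.calibrationEqual(s@axisN, ref@axisN))
      return(sprintf("calibration mismatch: spectrum '%s' axes differ from reference", b))
  }
  if (length(object@position) != 1L || is.na(object@position) ||
      object@position < 1L)
    return("position must be a positive integer")
  TRUE
})

#' PCAResult: principal components of a spectrum ensemble
#'
#' Result of NIPALS PCA on a flattened ensemble of spectra. Each component
#' has a unit-norm eigen-spectrum (a pattern over grid points), one
#' projection per input spectrum, and a variance fraction. The per-spectrum
#' projections are what the source field often calls per-spectrum "loadings";
#' in the spectra-as-rows convention used here they are scores, so the
#' neutral name "projections" is used throughout.
#'
#' @slot eigenSpectra numeric matrix, (n1*n2) x k, orthonormal columns.
#' @slot projections numeric matrix, nInput x k; rownames are the plane
#'   labels (\code{free, A, C, G, U} for an ensemble).
#' @slot varianceFraction numeric vector, length k, non-increasing.
#' @slot centering one of \code{"none"}, \code{"mean"}, \code{"reference"}.
#' @slot nInput number of input spectra.
#' @slot converged logical per component; \code{FALSE} means the NIPALS
#'   iteration hit \code{maxIter} (recorded, not an error).
#' @slot totalSS total sum of squares of the (centered) data matrix.
#' @seealso [nipalsPca()], [pcaEnsemble()], [varianceTable()]
#' @export
setClass("PCAResult",
  representation(eigenSpectra = "matrix", projections = "matrix",
                 varianceFraction = "numeric", centering = "character",
                 nInput = "integer", converged = "logical",
                 totalSS = "numeric"))

setValidity("PCAResult", function(object) {
  k <- ncol(object@eigenSpectra)
  if (ncol(object@projections) != k || length(object@varianceFraction) != k ||
      length(object@converged) != k)
    return("component count mismatch across slots")
  if (k > 0) {
    g <- crossprod(object@eigenSpectra)
    if (max(abs(diag(g) - 1)) > 1e-8)
      return("eigen-spectra are not unit norm")
    if (k > 1 && max(abs(g[upper.tri(g)])) > 1e-7)
      return("eigen-spectra are not mutually orthogonal")
    vf <- object@varianceFraction
    if (any(diff(vf) > 1e-10)) return("variance fractions must be non-increasing")
    if (sum(vf) > 1 + 1e-8) return("variance fractions sum above 1")
  }
  if (!object@centering %in% c("none", "mean", "reference"))
    return("unknown centering mode")
  TRUE
})

#' PreferenceTable: per-position nucleobase preference scores
#'
#' Scores for every (position, base) pool, from either the PCA route or the
#' manual chemical-shift-perturbation (SIA) route, with derived rankings and
#' per-position diagnostics.
#'
#' @slot method \code{"pca"} or \code{"sia_manual"}.
#' @slot scores data.frame with columns \code{position}, \code{base},
#'   \code{score} (signed for PCA, in [0,1] for manual SIA),
#'   \code{abs_score}, \code{rank}, \code{tie}.
#' @slot componentUsed integer, the principal component used (PCA only;
#'   \code{NA} for manual SIA).
#' @slot diagnostics named list, one entry per position (variance tables,
#'   reliability flags, per-component scores, mean weighted shifts ...).
#' @seealso [pcaPreferenceTable()], [siaPreferenceTable()], [compareMethods()]
#' @export
setClass("PreferenceTable",
  representation(method = "character", scores = "data.frame",
                 componentUsed = "integer", diagnostics = "list"))

setValidity("PreferenceTable", function(object) {
  if (!object@method %in% c("pca", "sia_manual"))
    return("method must be 'pca' or 'sia_manual'")
  need <- c("position", "base", "score", "abs_score", "rank", "tie")
  if (!all(need %in% names(object@scores)))
    return(sprintf("scores must have columns %s", paste(need, collapse = ", ")))
  sp <- split(object@scores$base, object@scores$position)
  if (!all(vapply(sp, function(b) setequal(b, BASES), logical(1))))
    return("each position must have scores for all four bases")
  if (object@method == "sia_manual" &&
      (any(object@scores$score < -1e-12) || any(object@scores$score > 1 + 1e-12)))
    return("manual SIA scores must lie in [0, 1]")
  TRUE
})
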