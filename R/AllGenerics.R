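#' @include AllClasses.R
NULL

#' Accessors for spectrum and result objects
#'
#' @param object a [Spectrum2D-class], [EnsembleStack-class],
#'   [PCAResult-class] or [PreferenceTable-class] object.
#' @return \code{intensities}: the numeric matrix; \code{specLabel}: the
#'   label tag; \code{axisH}/\code{axisN}: the axis descriptor lists;
#'   \code{ppmH}/\code{ppmN}: the ppm coordinate of every grid point along
#'   the 1H / 15N axis; \code{projections}: the per-spectrum projection
#'   matrix; \code{eigenSpectra}: the orthonormal eigen-spectrum matrix;
#'   \code{varianceFractions}: per-component variance fractions;
#'   \code{scoresTable}: the (position, base) score data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("specLabel", function(object) standardGeneric("specLabel"))
#' @rdname accessors
#' @export
setGeneric("axisH", function(object) standardGeneric("axisH"))
#' @rdname accessors
#' @export
setGeneric("axisN", function(object) standardGeneric("axisN"))
#' @rdname accessors
#' @export
setGeneric("ppmH", function(object) standardGeneric("ppmH"))
#' @rdname accessors
#' @export
setGeneric("ppmN", function(object) standardGeneric("ppmN"))
#' @rdname accessors
#' @export
setGeneric("projections", function(object) standardGeneric("projections"))
#' @rdname accessors
#' @export
setGeneric("eigenSpectra", function(object) standardGeneric("eigenSpectra"))
#' @rdname accessors
#' @export
setGeneric("varianceFractions",
           function(object) standardGeneric("varianceFractions"))
#' @rdname accessors
#' @export
setGeneric("scoresTable", function(object) standardGeneric("scoresTable"))

#' Per-component variance table
#'
#' @param result a [PCAResult-class].
#' @return data.frame with columns \code{component} and \code{variance_pct}
#'   (100 x variance fraction), in component order.
#' @export
setGeneric("varianceTable", function(result) standardGeneric("varianceTable"))

.axisPpm <- function(axis) axis$first - (seq_len(axis$n) - 1L) * axis$sw / axis$n

#' @rdname accessors
setMethod("intensities", "Spectrum2D", function(object) object@intensities)
#' @rdname accessors
setMethod("specLabel", "Spectrum2D", function(object) object@label)
#' @rdname accessors
setMethod("axisH", "Spectrum2D", function(object) object@axisH)
#' @rdname accessors
setMethod("axisN", "Spectrum2D", function(object) object@axisN)
#' @rdname accessors
setMethod("ppmH", "Spectrum2D", function(object) .axisPpm(object@axisH))
#' @rdname accessors
setMethod("ppmN", "Spectrum2D", function(object) .axisPpm(object@axisN))

#' @describeIn Spectrum2D grid dimensions (1H points, 15N points).
#' @param x a \code{Spectrum2D}.
#' @export
setMethod("dim", "Spectrum2D", function(x) dim(x@intensities))

#' @rdname accessors
setMethod("projections", "PCAResult", function(object) object@projections)
#' @rdname accessors
setMethod("eigenSpectra", "PCAResult", function(object) object@eigenSpectra)
#' @rdname accessors
setMethod("varianceFractions", "PCAResult",
          function(object) object@varianceFraction)
#' @rdname accessors
setMethod("scoresTable", "PreferenceTable", function(object) object@scores)

setMethod("show", "Spectrum2D", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("Spectrum2D '%s': %d x %d points\n", object@label, d[1], d[2]))
  cat(sprintf("  1H:  %.3f .. %.3f ppm (sw %.3f, %d pts)\n",
              object@axisH$first, min(.axisPpm(object@axisH)),
              object@axisH$sw, object@axisH$n))
  cat(sprintf("  15N: %.2f .. %.2f ppm (sw %.2f, %d pts)\n",
              object@axisN$first, min(.axisPpm(object@axisN)),
              object@axisN$sw, object@axisN$n))
})

setMethod("show", "EnsembleStack", function(object) {
  d <- dim(object@reference@intensities)
  cat(sprintf("EnsembleStack position %d: 5 planes [free, A, C, G, U], %d x %d points\n",
              object@position, d[1], d[2]))
})

setMethod("show", "PCAResult", function(object) {
  k <- length(object@varianceFraction)
  cat(sprintf("PCAResult: %d components from %d spectra (centering = %s)\n",
              k, object@nInput, object@centering))
  cat("  variance %:", paste(sprintf("%.2f", 100 * object@varianceFraction),
                             collapse = ", "), "\n")
  if (!all(object@converged))
    cat("  note: components", paste(which(!object@converged), collapse = ", "),
        "did not converge within maxIter\n")
})

setMethod("show", "PreferenceTable", function(object) {
  cat(sprintf("PreferenceTable (%s%s): %d positions\n", object@method,
              if (object@method == "pca")
                sprintf(", component %d", object@componentUsed) else "",
              length(unique(object@scores$position))))
  top <- object@scores[object@scores$rank == 1L, c("position", "base")]
  cat("  top-ranked base per position:",
      paste(sprintf("%d:%s", top$position, top$base), collapse = "  "), "\n")
})
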