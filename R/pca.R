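#' @include AllGenerics.R
NULL

#' Flatten an ensemble into a PCA data matrix
#'
#' Each plane is flattened row-major into one row of a 5 x (n1*n2) matrix in
#' the fixed order \code{[free, A, C, G, U]}. Centering \code{"none"} leaves
#' the rows untouched (the default for the downstream analysis: with five
#' uncentered spectra all five principal components carry signal, and the
#' first is dominated by overall intensity); \code{"mean"} subtracts the
#' across-spectra mean vector; \code{"reference"} subtracts the free-protein
#' row from every row, making the first row identically zero.
#'
#' @param stack an [EnsembleStack-class].
#' @param centering \code{"none"}, \code{"mean"} or \code{"reference"}.
#' @return numeric matrix with rownames \code{free, A, C, G, U} and
#'   attribute \code{centering}.
#' @export
buildDataMatrix <- function(stack,
                            centering = c("none", "mean", "reference")) {
  centering <- match.arg(centering)
  validObject(stack)
  planes <- c(list(free = stack@reference), stack@bound)
  X <- do.call(rbind, lapply(planes, function(s) as.vector(t(s@intensities))))
  rownames(X) <- PLANE_LABELS
  X <- switch(centering,
              none = X,
              mean = sweep(X, 2L, colMeans(X)),
              reference = sweep(X, 2L, X[1L, ]))
  attr(X, "centering") <- centering
  X
}

# orthonormal filler direction for zero-variance components: a canonical
# basis vector orthogonalized against the loadings found so far
.fillerDirection <- function(P, k) {
  p <- ncol(P) %||% 0
  for (j in seq_len(nrow(P))) {
    e <- numeric(nrow(P)); e[j] <- 1
    if (k > 0) e <- e - P[, seq_len(k), drop = FALSE] %*%
        crossprod(P[, seq_len(k), drop = FALSE], e)
    nrm <- sqrt(sum(e^2))
    if (nrm > 1e-6) return(as.vector(e) / nrm)
  }
  stop("could not construct an orthonormal filler direction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' NIPALS principal component analysis
#'
#' Computes principal components of a spectra-as-rows data matrix by the
#' NIPALS algorithm: components are extracted one at a time by alternating
#' updates of the projection vector (one value per spectrum) and the
#' eigen-spectrum (a unit-norm pattern over grid points), followed by
#' deflation. For the five-spectrum ensembles this converges in a handful of
#' iterations and yields all five components in well under a second.
#'
#' The sign of each component is fixed so the first (reference) spectrum's
#' projection is non-negative (falling back to the first nonzero projection
#' when the reference projects to zero), making results deterministic across
#' runs and platforms. Variance fractions are sums of squared projections
#' divided by the total sum of squares of the input matrix, so they match
#' the usual "\% variance" reading.
#'
#' @param X numeric matrix, spectra in rows (rownames become the projection
#'   labels).
#' @param nComponents number of components to extract (default: all,
#'   \code{min(dim(X))}).
#' @param tol relative residual tolerance: the iteration stops when the
#'   projection vector satisfies its eigen-equation to within
#'   \code{tol} times the leading eigenvalue of the residual.
#' @param maxIter iteration cap per component; hitting it is recorded in the
#'   result's \code{converged} slot (and a warning), not an error.
#' @param centering centering already applied to \code{X}, recorded in the
#'   result (taken from \code{attr(X, "centering")} when present).
#' @return a [PCAResult-class].
#' @examples
#' X <- matrix(rnorm(50), 5, 10)
#' res <- nipalsPca(X)
#' varianceTable(res)
#' @export
nipalsPca <- function(X, nComponents = min(dim(X)), tol = 1e-12,
                      maxIter = 10000L,
                      centering = attr(X, "centering") %||% "none") {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (nComponents > min(n, p))
    stop("nComponents exceeds min(rows, columns)")
  if (tol <= 0) stop("tol must be positive")
  labels <- rownames(X) %||% paste0("s", seq_len(n))
  totSS <- sum(X^2)
  if (totSS == 0) stop("degenerate input: data matrix is all zero")

  scores <- matrix(0, n, nComponents, dimnames = list(labels, NULL))
  loads <- matrix(0, p, nComponents)
  vf <- numeric(nComponents)
  converged <- rep(TRUE, nComponents)
  R <- X
  for (k in seq_len(nComponents)) {
    resSS <- sum(R^2)
    if (resSS <= 1e-24 * totSS) {
      # residual exhausted: zero-variance component with a filler direction
      loads[, k] <- .fillerDirection(loads, k - 1L)
      next
    }
    # The alternation t <- R (R' t / ||R' t||) is one multiplication by the
    # small Gram matrix G = R R'; iterating on G gives the same fixed point
    # at O(n^2) per step instead of O(n p), so near-degenerate eigenvalue
    # pairs can be iterated to machine precision cheaply.
    G <- tcrossprod(R)
    t <- R[, which.max(colSums(R^2))]
    u <- t / sqrt(sum(t^2))
    ok <- FALSE
    for (iter in seq_len(maxIter)) {
      gu <- as.vector(G %*% u)
      lambda <- sum(u * gu)
      # residual bound: ||G u - lambda u|| small means u solves the
      # eigen-equation of this deflation level
      if (sqrt(sum((gu - lambda * u)^2)) <= tol * lambda) {
        ok <- TRUE
        break
      }
      u <- gu / sqrt(sum(gu^2))
    }
    if (!ok) {
      converged[k] <- FALSE
      warning(sprintf("component %d did not converge in %d iterations",
                      k, maxIter))
    }
    pv <- as.vector(crossprod(R, u))
    pv <- pv / sqrt(sum(pv^2))
    t <- as.vector(R %*% pv)
    # deterministic sign: reference (first) projection >= 0
    anchor <- t[1L]
    if (abs(anchor) < 1e-12 * max(abs(t))) {
      nz <- which(abs(t) >= 1e-12 * max(abs(t)))
      anchor <- if (length(nz)) t[nz[1L]] else 1
    }
    if (anchor < 0) { t <- -t; pv <- -pv }
    scores[, k] <- t
    loads[, k] <- pv
    vf[k] <- sum(t^2) / totSS
    R <- R - tcrossprod(t, pv)
  }
  new("PCAResult", eigenSpectra = loads, projections = scores,
      varianceFraction = vf, centering = centering, nInput = as.integer(n),
      converged = converged, totalSS = totSS)
}

#' PCA of one position's spectrum ensemble
#'
#' Convenience wrapper: flattens the stack with [buildDataMatrix()] and runs
#' [nipalsPca()], requesting all available components (five for an
#' uncentered ensemble).
#'
#' @param stack an [EnsembleStack-class].
#' @param centering see [buildDataMatrix()].
#' @param nComponents number of components; default all.
#' @param ... passed on to [nipalsPca()] (\code{tol}, \code{maxIter}).
#' @return a [PCAResult-class] with projections labelled
#'   \code{free, A, C, G, U}.
#' @export
pcaEnsemble <- function(stack, centering = "none", nComponents = NULL, ...) {
  X <- buildDataMatrix(stack, centering)
  if (is.null(nComponents)) nComponents <- min(dim(X))
  nipalsPca(X, nComponents = nComponents, ...)
}

#' @rdname varianceTable
#' @export
setMethod("varianceTable", "PCAResult", function(result) {
  data.frame(component = seq_along(result@varianceFraction),
             variance_pct = 100 * result@varianceFraction)
})
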