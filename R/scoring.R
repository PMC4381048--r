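#' @include pca.R
NULL

#' Per-pool PCA preference score
#'
#' The score of a pool measures how far its bound spectrum sits from the
#' free-protein reference along one principal component. The second
#' component is the default, being the one whose projections track
#' RNA-dependent chemical shift changes; scores on any component can be
#' requested for diagnostics.
#'
#' Two read-outs are provided. \code{"distance"} (the default used for
#' ranking) is the distance between the two projections,
#' \eqn{|t_{free} - t_{pool}|}. \code{"difference"} is the subtraction of
#' absolute projections, \eqn{|t_{free}| - |t_{pool}|}; the two coincide
#' (up to sign) when the reference projection is extremal and all
#' projections share a sign, but on an uncentered ensemble the component-2
#' projections must straddle zero (they are orthogonal to the all-positive
#' component-1 projections), so only the distance form is a faithful
#' separation in general. The difference form is kept because it is the
#' arithmetic conventionally reported.
#'
#' @param result a [PCAResult-class] from [pcaEnsemble()] (projections
#'   labelled \code{free, A, C, G, U}).
#' @param component principal component to use (default 2).
#' @param type \code{"distance"} or \code{"difference"} (see Details).
#' @return named numeric vector (A, C, G, U); non-negative for
#'   \code{"distance"}, signed for \code{"difference"}. Ranking uses
#'   magnitude either way (see [rankBases()]).
#' @export
pcaPoolScore <- function(result, component = 2L,
                         type = c("distance", "difference")) {
  type <- match.arg(type)
  k <- ncol(result@projections)
  if (component < 1L || component > k)
    stop(sprintf("component %d out of range (result has %d)", component, k))
  pr <- result@projections[, component]
  if (!all(PLANE_LABELS %in% names(pr)))
    stop("result projections must be labelled free, A, C, G, U")
  switch(type,
         distance = abs(pr["free"] - pr[BASES]),
         difference = abs(pr["free"]) - abs(pr[BASES]))
}

#' Rank bases by score magnitude
#'
#' Orders the four bases by decreasing absolute score (larger separation
#' from the free spectrum indicates greater average affinity). Ties are
#' broken by fixed alphabetical order A < C < G < U and flagged.
#'
#' @param scores named numeric vector with entries A, C, G, U.
#' @return character vector of bases, best first, with attribute
#'   \code{tie} (logical: any tie among the magnitudes).
#' @examples
#' rankBases(c(A = 0.01, C = 0.02, G = 0.4, U = 0.2))  # G U C A
#' @export
rankBases <- function(scores) {
  if (!setequal(names(scores), BASES))
    stop("scores must name all of A, C, G, U")
  s <- abs(scores[BASES])
  ord <- order(-s, BASES)
  ranking <- BASES[ord]
  attr(ranking, "tie") <- anyDuplicated(s) > 0L
  ranking
}

#' Flag ensembles where the PCA read-out is unreliable
#'
#' When few resonances shift on binding (small domains, sparse interfaces)
#' the variance spreads more evenly over the components and the link
#' between the second component and chemical-shift changes breaks down. The
#' heuristic implemented here flags an ensemble as unreliable when the
#' second component's variance fraction falls below \code{ratioThreshold}
#' times the third's.
#'
#' @param result a [PCAResult-class] with at least 3 components.
#' @param ratioThreshold required ratio of component-2 to component-3
#'   variance (default 1.5).
#' @return list with \code{reliable} (logical), \code{ratio} and
#'   \code{message}.
#' @export
reliabilityCheck <- function(result, ratioThreshold = 1.5) {
  vf <- result@varianceFraction
  if (length(vf) < 3L) stop("reliability check needs at least 3 components")
  ratio <- if (vf[3] > 0) vf[2] / vf[3] else Inf
  reliable <- vf[2] >= ratioThreshold * vf[3]
  list(reliable = reliable, ratio = ratio,
       message = if (reliable)
         sprintf("variance ratio PC2/PC3 = %.2f (>= %.2f): PCA scoring reliable",
                 ratio, ratioThreshold)
       else
         sprintf(paste("variance ratio PC2/PC3 = %.2f (< %.2f): variance spread",
                       "evenly over components; prefer manual scoring"),
                 ratio, ratioThreshold))
}

.rankColumns <- function(scores) {
  ranking <- rankBases(scores)
  data.frame(base = BASES,
             rank = match(BASES, ranking),
             tie = attr(ranking, "tie"),
             stringsAsFactors = FALSE)
}

#' PCA preference table for a set of ensembles
#'
#' Runs one PCA per position ensemble and assembles the per-pool scores,
#' rankings, variance tables and reliability flags into a
#' [PreferenceTable-class]. Per-component scores (components 1..5) are kept
#' in the diagnostics for method comparison.
#'
#' @param stacks list of [EnsembleStack-class] objects (one per position),
#'   or the \code{stacks} element of [simulateSIAExperiment()] output.
#' @param component component used for the reported scores (default 2).
#' @param centering see [buildDataMatrix()].
#' @param ratioThreshold see [reliabilityCheck()].
#' @param ... passed to [nipalsPca()].
#' @return a [PreferenceTable-class] with method \code{"pca"}.
#' @export
pcaPreferenceTable <- function(stacks, component = 2L, centering = "none",
                               ratioThreshold = 1.5, ...) {
  rows <- list()
  diags <- list()
  for (stack in stacks) {
    pos <- stack@position
    res <- pcaEnsemble(stack, centering = centering, ...)
    k <- ncol(res@projections)
    perComp <- vapply(seq_len(k), function(cc) pcaPoolScore(res, cc),
                      numeric(4L))
    dimnames(perComp) <- list(BASES, paste0("PC", seq_len(k)))
    sc <- pcaPoolScore(res, component)
    diffScore <- pcaPoolScore(res, component, type = "difference")
    rk <- .rankColumns(sc)
    rows[[length(rows) + 1L]] <- data.frame(
      position = pos, base = BASES, score = as.numeric(sc),
      abs_score = abs(as.numeric(sc)),
      signed_difference = as.numeric(diffScore),
      rank = rk$rank, tie = rk$tie,
      stringsAsFactors = FALSE)
    diags[[as.character(pos)]] <- list(
      varianceTable = varianceTable(res),
      reliability = reliabilityCheck(res, ratioThreshold),
      perComponentScores = perComp,
      projections = res@projections)
  }
  new("PreferenceTable", method = "pca", scores = do.call(rbind, rows),
      componentUsed = as.integer(component), diagnostics = diags)
}
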