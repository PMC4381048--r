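#' @include scoring.R
NULL

#' Weighted amide chemical-shift perturbation
#'
#' Combines per-dimension shifts into the community-standard amide CSP:
#' \deqn{\Delta\delta = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2}}
#' with \eqn{\alpha = 0.2} by default, scaling the 15N ppm range onto the
#' 1H one.
#'
#' @param deltaH,deltaN per-dimension shift differences, ppm (vectorized).
#' @param alpha 15N weighting factor.
#' @return weighted shift in ppm.
#' @examples
#' weightedDelta(0.03, 0.15)  # 0.042426...
#' @export
weightedDelta <- function(deltaH, deltaN, alpha = 0.2) {
  sqrt(deltaH^2 + (alpha * deltaN)^2)
}

# weighted shifts of selected peaks between a free and one bound list
.pairedDeltas <- function(free, bound, ids, alpha, base = "?") {
  iF <- match(ids, free$id)
  if (anyNA(iF))
    stop("peak '", ids[which(is.na(iF))[1]], "' absent from free peak list")
  iB <- match(ids, bound$id)
  if (anyNA(iB))
    stop("peak '", ids[which(is.na(iB))[1]],
         "' absent from bound peak list for base ", base)
  weightedDelta(bound$h_ppm[iB] - free$h_ppm[iF],
                bound$n_ppm[iB] - free$n_ppm[iF], alpha)
}

#' Manual SIA scores from tracked peak lists
#'
#' For each selected peak the weighted shift is measured against each of
#' the four pool-bound peak lists and normalized by the largest of the four
#' (so per peak, the pool with the largest shift gets 1). The per-base score
#' is the mean of the normalized values over the selected peaks; peaks that
#' do not shift in any pool are excluded from the mean and reported.
#'
#' @param free free-protein peak list.
#' @param boundByBase named list (A, C, G, U) of bound peak lists.
#' @param selectedIds assignment ids to evaluate (the manually chosen,
#'   accurately measurable peaks); must be present in all five lists.
#' @param alpha 15N weighting, see [weightedDelta()].
#' @return list with \code{scores} (named numeric A/C/G/U in [0,1]),
#'   \code{shiftRecords} (data.frame id, base, delta, normalized),
#'   \code{meanDelta} (named numeric: mean weighted shift per base over the
#'   selected peaks, the quantity PCA projections are correlated against)
#'   and \code{excluded} (ids with zero shift in every pool).
#' @examples
#' free <- peakList("p1", 8.0, 120)
#' bound <- lapply(c(A = .05, C = .10, G = .40, U = .20),
#'                 function(d) peakList("p1", 8.0 + d, 120))
#' siaScores(free, bound, "p1")$scores  # A .125, C .25, G 1, U .5
#' @export
siaScores <- function(free, boundByBase, selectedIds, alpha = 0.2) {
  missing <- setdiff(BASES, names(boundByBase))
  if (length(missing))
    stop("missing bound peak list for base '", missing[1], "'")
  if (length(selectedIds) < 1L) stop("at least one peak id is required")
  deltas <- vapply(BASES, function(b)
    .pairedDeltas(free, boundByBase[[b]], selectedIds, alpha, b),
    numeric(length(selectedIds)))
  deltas <- matrix(deltas, nrow = length(selectedIds),
                   dimnames = list(selectedIds, BASES))
  peakMax <- apply(deltas, 1L, max)
  keep <- peakMax > 0
  norm <- deltas
  norm[keep, ] <- deltas[keep, , drop = FALSE] / peakMax[keep]
  norm[!keep, ] <- NA_real_
  scores <- if (any(keep))
    colMeans(norm[keep, , drop = FALSE]) else
    stats::setNames(rep(NA_real_, 4L), BASES)
  records <- data.frame(
    id = rep(selectedIds, times = 4L),
    base = rep(BASES, each = length(selectedIds)),
    delta = as.vector(deltas),
    normalized = as.vector(norm),
    stringsAsFactors = FALSE)
  list(scores = scores, shiftRecords = records,
       meanDelta = colMeans(deltas),
       excluded = selectedIds[!keep])
}

#' Sensitivity of SIA scores to peak selection
#'
#' Recomputes [siaScores()] for each provided id subset and reports, per
#' base, the maximum absolute score difference across subsets — the
#' peak-selection bias that whole-spectrum PCA scoring removes.
#'
#' @inheritParams siaScores
#' @param idSubsets list (length >= 2) of id vectors.
#' @return named numeric (A, C, G, U): max pairwise score deviation.
#' @export
subsetSensitivity <- function(free, boundByBase, idSubsets, alpha = 0.2) {
  if (length(idSubsets) < 2L) stop("at least two id subsets are required")
  sc <- vapply(idSubsets, function(ids)
    siaScores(free, boundByBase, ids, alpha)$scores, numeric(4L))
  apply(sc, 1L, function(v) max(v) - min(v))
}

#' Manual SIA preference table
#'
#' Applies [siaScores()] at every position and assembles a
#' [PreferenceTable-class] (method \code{"sia_manual"}), keeping the mean
#' weighted shifts and shift records in the diagnostics.
#'
#' @param freePeaks free-protein peak list (shared across positions).
#' @param boundPeaksByPosition list over positions, each a named list
#'   (A, C, G, U) of bound peak lists — the \code{boundPeaks} element of
#'   [simulateSIAExperiment()] output has this shape.
#' @param selectedIds ids to score (default: all ids in \code{freePeaks}).
#' @param alpha 15N weighting.
#' @return a [PreferenceTable-class].
#' @export
siaPreferenceTable <- function(freePeaks, boundPeaksByPosition,
                               selectedIds = freePeaks$id, alpha = 0.2) {
  rows <- list()
  diags <- list()
  positions <- names(boundPeaksByPosition)
  if (is.null(positions)) positions <- as.character(seq_along(boundPeaksByPosition))
  for (i in seq_along(boundPeaksByPosition)) {
    pos <- as.integer(positions[i])
    res <- siaScores(freePeaks, boundPeaksByPosition[[i]], selectedIds, alpha)
    rk <- .rankColumns(res$scores)
    rows[[i]] <- data.frame(position = pos, base = BASES,
                            score = as.numeric(res$scores),
                            abs_score = abs(as.numeric(res$scores)),
                            rank = rk$rank, tie = rk$tie,
                            stringsAsFactors = FALSE)
    diags[[positions[i]]] <- list(meanDelta = res$meanDelta,
                                  shiftRecords = res$shiftRecords,
                                  excluded = res$excluded)
  }
  new("PreferenceTable", method = "sia_manual",
      scores = do.call(rbind, rows), componentUsed = NA_integer_,
      diagnostics = diags)
}

# Kendall tau between two strict orderings of the same items, by explicit
# concordant/discordant pair counting (n is tiny here)
.kendallTau <- function(orderA, orderB) {
  items <- sort(orderA)
  if (!setequal(orderA, orderB)) stop("orderings must contain the same items")
  ra <- match(items, orderA)
  rb <- match(items, orderB)
  n <- length(items)
  conc <- 0L; disc <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- sign(ra[i] - ra[j]) * sign(rb[i] - rb[j])
    if (s > 0) conc <- conc + 1L else if (s < 0) disc <- disc + 1L
  }
  (conc - disc) / (n * (n - 1L) / 2)
}

#' Compare PCA and manual SIA preference calls
#'
#' Two read-outs: (i) per position, the Kendall tau between the PCA and
#' manual-SIA base rankings (1 = identical order) plus an exact-match flag;
#' (ii) per principal component, the Pearson correlation between the PCA
#' projection distance |score| of each pool and the pool's mean weighted
#' chemical shift — computed per position (four pools) and pooled across
#' positions. In a well-behaved ensemble only the second component
#' correlates with the shifts; the first tracks overall intensity
#' (dilution).
#'
#' @param pcaTable [PreferenceTable-class] from [pcaPreferenceTable()].
#' @param siaTable [PreferenceTable-class] from [siaPreferenceTable()].
#' @return list with \code{rankAgreement} (data.frame position, tau,
#'   exact), \code{componentCorrelation} (data.frame component, r: pooled
#'   across positions) and \code{perPositionCorrelation} (matrix component x
#'   position).
#' @export
compareMethods <- function(pcaTable, siaTable) {
  if (pcaTable@method != "pca" || siaTable@method != "sia_manual")
    stop("expected one PCA table and one manual SIA table")
  posP <- sort(unique(pcaTable@scores$position))
  posS <- sort(unique(siaTable@scores$position))
  if (!identical(posP, posS))
    stop("tables cover different positions")

  rankRow <- function(pos) {
    a <- pcaTable@scores[pcaTable@scores$position == pos, ]
    b <- siaTable@scores[siaTable@scores$position == pos, ]
    oa <- a$base[order(a$rank)]
    ob <- b$base[order(b$rank)]
    data.frame(position = pos, tau = .kendallTau(oa, ob),
               exact = identical(oa, ob))
  }
  rankAgreement <- do.call(rbind, lapply(posP, rankRow))

  nComp <- ncol(pcaTable@diagnostics[[1]]$perComponentScores)
  dist <- lapply(as.character(posP), function(p)
    abs(pcaTable@diagnostics[[p]]$perComponentScores))
  meanDelta <- lapply(as.character(posP), function(p)
    siaTable@diagnostics[[p]]$meanDelta[BASES])
  perPos <- vapply(seq_along(posP), function(i)
    vapply(seq_len(nComp), function(k)
      stats::cor(dist[[i]][, k], meanDelta[[i]]), numeric(1)),
    numeric(nComp))
  dimnames(perPos) <- list(paste0("PC", seq_len(nComp)), posP)
  pooled <- vapply(seq_len(nComp), function(k)
    stats::cor(unlist(lapply(dist, function(d) d[, k])),
               unlist(meanDelta)), numeric(1))
  list(rankAgreement = rankAgreement,
       componentCorrelation = data.frame(component = seq_len(nComp),
                                         r = pooled),
       perPositionCorrelation = perPos)
}
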