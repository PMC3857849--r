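#' Binarise a smoothed ground-truth matrix
#'
#' Converts the Gaussian-smoothed truth into the positive set for TPR/FPR
#' counting: entries at or above `truthCut` are positives.  The default cut
#' of 0.5 keeps the pairs inside the nodes' half-maximum envelope.
#'
#' @param truth a [ConnectivityMatrix-class] with values in `[0, 1]`, or a
#'   numeric matrix.
#' @param truthCut threshold in `[0, 1]` (default 0.5).
#' @return Logical matrix (`NA` where the truth is undefined).
#' @export
binariseTruth <- function(truth, truthCut = 0.5) {
  v <- if (is(truth, "ConnectivityMatrix")) connValues(truth) else truth
  v >= truthCut
}

#' Log-ROC curve of a reconstruction against a binarised truth
#'
#' Thresholds the reconstruction at `nThresholds` equally spaced values
#' from the lowest to the highest value in the matrix and counts true- and
#' false-positive rates over the off-diagonal upper triangle (sentinel
#' `NaN` pairs excluded).  False-positive rates are clamped to `fprFloor`
#' (default one count: `1 / n_scored_pairs`) before taking base-10 logs, so
#' a perfect ranking has a finite, grid-size-aware area.
#'
#' @param recon a [ConnectivityMatrix-class] or numeric matrix.
#' @param truthPos logical matrix from [binariseTruth()].
#' @param nThresholds number of thresholds (default 120).
#' @param fprFloor clamp for zero FPRs; default `1/n_scored`.
#' @return An [ROCResult-class].
#' @export
logRoc <- function(recon, truthPos, nThresholds = 120L, fprFloor = NULL) {
  v <- if (is(recon, "ConnectivityMatrix")) connValues(recon) else recon
  if (!all(dim(v) == dim(truthPos)))
    stop("reconstruction and truth dimensions disagree")
  ut <- upper.tri(v)
  val <- v[ut]; pos <- truthPos[ut]
  ok <- is.finite(val) & !is.na(pos)
  val <- val[ok]; pos <- pos[ok]
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L) stop("truth has no positive pairs among scored entries")
  if (nn == 0L) stop("truth has no negative pairs among scored entries")
  if (is.null(fprFloor)) fprFloor <- 1 / length(val)
  thr <- seq(min(val), max(val), length.out = nThresholds)
  posSorted <- sort(val[pos]); negSorted <- sort(val[!pos])
  tpr <- vapply(thr, function(th) mean(posSorted >= th), 0)
  fpr <- vapply(thr, function(th) mean(negSorted >= th), 0)
  new("ROCResult", thresholds = thr, tpr = tpr, fpr = fpr,
      logFpr = log10(pmax(fpr, fprFloor)), fprFloor = fprFloor,
      nPositive = as.integer(np), nNegative = as.integer(nn))
}

#' Area under the log-ROC curve
#'
#' Trapezium-rule integral of the TPR over the base-10 log of the clamped
#' FPR, from `log10(fprFloor)` to 0.  At each distinct log-FPR the best
#' (largest) TPR is used, so a perfect ranking attains
#' `-log10(fprFloor)` and the chance curve (TPR = FPR) attains
#' `(1 - fprFloor)/ln 10` (about 0.434).
#'
#' @param roc an [ROCResult-class].
#' @return Scalar AUC (>= 0).
#' @export
logRocAuc <- function(roc) {
  stopifnot(is(roc, "ROCResult"))
  u <- roc@logFpr; t <- roc@tpr
  agg <- tapply(t, u, max)
  uu <- as.numeric(names(agg)); tt <- as.numeric(agg)
  o <- order(uu)
  uu <- uu[o]; tt <- tt[o]
  if (length(uu) < 2L)
    stop("degenerate log-ROC curve: fewer than two distinct log-FPR points")
  sum(diff(uu) * (head(tt, -1L) + tail(tt, -1L)) / 2)
}

#' Critical log-ROC AUC benchmark
#'
#' The log-ROC AUC at which the score distributions generating the true-
#' and false-positive rates, modelled as equal-variance Gaussians, overlap
#' with probability `pOverlap`.  The separation solves
#' `overlap coefficient = pOverlap` (area under the minimum of the two unit
#' variance densities, `2*pnorm(-d/2)`); the implied ROC is traced at
#' `nThresholds` equally spaced thresholds spanning `marginSd` standard
#' deviations beyond the two means and integrated exactly like [logRocAuc()].
#' With the defaults the benchmark evaluates to about 3.84; reconstructions
#' whose AUC exceeds it separate truth from noise beyond the 5% overlap
#' level.  The alternative `"midpoint-error"` convention (misclassification
#' probability at the optimal midpoint equal to `pOverlap`) is selectable.
#'
#' @param pOverlap overlap probability (default 0.05).
#' @param nThresholds number of thresholds (default 120).
#' @param fprFloor clamp for the FPR before the log (default `1e-5`).
#' @param marginSd how far beyond the two means the thresholds extend, in
#'   standard deviations (default 0.5).
#' @param overlap `"coefficient"` (default) or `"midpoint-error"`.
#' @return Scalar critical AUC.
#' @export
criticalAuc <- function(pOverlap = 0.05, nThresholds = 120L,
                        fprFloor = 1e-5, marginSd = 0.5,
                        overlap = c("coefficient", "midpoint-error")) {
  overlap <- match.arg(overlap)
  stopifnot(pOverlap > 0, pOverlap < 1)
  d <- if (overlap == "coefficient") 2 * qnorm(1 - pOverlap / 2)
       else 2 * qnorm(1 - pOverlap)
  thr <- seq(-marginSd, d + marginSd, length.out = nThresholds)
  fpr <- 1 - pnorm(thr)
  tpr <- 1 - pnorm(thr - d)
  roc <- new("ROCResult", thresholds = thr, tpr = tpr, fpr = fpr,
             logFpr = log10(pmax(fpr, fprFloor)), fprFloor = fprFloor,
             nPositive = 1L, nNegative = 1L)
  logRocAuc(roc)
}

#' t-tests on AUC collections
#'
#' One-tailed one-sample t-tests of each condition's AUCs against the
#' critical AUC, a one-tailed paired t-test between the two conditions, and
#' Bonferroni-adjusted significance flags.  Degenerate inputs (zero
#' variance) report `NA` statistics and are not significant.
#'
#' @param aucsA,aucsB numeric vectors of per-run AUCs (same length for the
#'   paired test).
#' @param critical critical AUC from [criticalAuc()].
#' @param alpha significance level before correction (default 0.05).
#' @param nComparisons Bonferroni divisor (default: the 3 tests performed).
#' @return Data frame with test, statistic, df, p, and significance flag.
#' @export
aucTests <- function(aucsA, aucsB, critical, alpha = 0.05,
                     nComparisons = 3L) {
  stopifnot(length(aucsA) >= 2L, length(aucsB) >= 2L)
  if (length(aucsA) != length(aucsB))
    stop("paired test needs equal-length AUC vectors")
  safeT <- function(expr) {
    tryCatch(expr, error = function(e) list(statistic = NA_real_,
                                            parameter = NA_real_,
                                            p.value = NA_real_))
  }
  tA <- safeT(t.test(aucsA, mu = critical, alternative = "greater"))
  tB <- safeT(t.test(aucsB, mu = critical, alternative = "greater"))
  tP <- safeT(t.test(aucsA, aucsB, paired = TRUE, alternative = "greater"))
  out <- data.frame(
    test = c("A > critical", "B > critical", "A > B (paired)"),
    statistic = c(tA$statistic, tB$statistic, tP$statistic),
    df = c(tA$parameter, tB$parameter, tP$parameter),
    p = c(tA$p.value, tB$p.value, tP$p.value))
  out$significant <- !is.na(out$p) & out$p < alpha / nComparisons
  out
}
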