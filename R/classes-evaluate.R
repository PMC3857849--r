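#' Log-ROC curve of a network reconstruction
#'
#' True- and false-positive rates of a reconstructed connectivity matrix
#' against a binarised ground truth, evaluated at thresholds equally spaced
#' over the reconstruction's value range, with the false-positive rate
#' clamped to a floor before taking base-10 logarithms.  Scored over the
#' off-diagonal upper triangle only; sentinel (`NaN`) pairs are excluded.
#'
#' @slot thresholds numeric vector of thresholds (descending coverage of the
#'   value range).
#' @slot tpr true-positive rate at each threshold.
#' @slot fpr false-positive rate at each threshold (unclamped).
#' @slot logFpr base-10 log of the floor-clamped FPR.
#' @slot fprFloor the clamp applied before the logarithm.
#' @slot nPositive,nNegative number of positive / negative scored pairs.
#'
#' @seealso [logRoc()], [logRocAuc()], [criticalAuc()]
#' @export
setClass("ROCResult",
  representation(
    thresholds = "numeric",
    tpr        = "numeric",
    fpr        = "numeric",
    logFpr     = "numeric",
    fprFloor   = "numeric",
    nPositive  = "integer",
    nNegative  = "integer"
  )
)

setValidity("ROCResult", function(object) {
  msg <- character()
  n <- length(object@thresholds)
  if (length(object@tpr) != n || length(object@fpr) != n ||
      length(object@logFpr) != n)
    msg <- c(msg, "tpr, fpr, logFpr must match thresholds in length")
  if (any(object@tpr < -1e-12 | object@tpr > 1 + 1e-12))
    msg <- c(msg, "tpr must lie in [0, 1]")
  if (any(object@fpr < -1e-12 | object@fpr > 1 + 1e-12))
    msg <- c(msg, "fpr must lie in [0, 1]")
  if (object@fprFloor <= 0 || object@fprFloor > 1)
    msg <- c(msg, "fprFloor must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf(
    "ROCResult: %d thresholds, %d positive / %d negative pairs, FPR floor %g\n",
    length(object@thresholds), object@nPositive, object@nNegative,
    object@fprFloor))
  cat(sprintf("  log-ROC AUC = %.4f\n", logRocAuc(object)))
})
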