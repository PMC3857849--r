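#' Set of DICS spatial filters
#'
#' One `3 x n_sensors` complex weight matrix per source, computed from a
#' (regularised) sensor CSD, plus the regularisation metadata.  The filters
#' satisfy the unit-gain constraint `W_k L_k = I` for every source.
#'
#' @slot weights complex array `3 x n_sensors x n_src` (free orientation) or
#'   `1 x n_sensors x n_src` (fixed orientation along the grid normals).
#' @slot alpha relative regularisation (gamma = alpha * ||C||).
#' @slot gamma absolute Tikhonov regularisation actually applied.
#' @slot csdKind `"full"` or `"nzpl"`: which CSD the filter was built from.
#' @slot orientation `"free"` or `"fixed"`.
#' @slot condition condition number of the regularised CSD.
#'
#' @seealso [makeFilters()], [sourceCoherenceMap()]
#' @export
setClass("SpatialFilterSet",
  representation(
    weights     = "array",
    alpha       = "numeric",
    gamma       = "numeric",
    csdKind     = "character",
    orientation = "character",
    condition   = "numeric"
  )
)

setValidity("SpatialFilterSet", function(object) {
  msg <- character()
  d <- dim(object@weights)
  if (length(d) != 3L || !d[1L] %in% c(1L, 3L))
    msg <- c(msg, "weights must be a {1|3} x n_sensors x n_src array")
  if (!object@orientation %in% c("free", "fixed"))
    msg <- c(msg, "orientation must be 'free' or 'fixed'")
  if (object@orientation == "free" && d[1L] != 3L)
    msg <- c(msg, "free-orientation filters must have 3 weight rows")
  if (!is.complex(object@weights))
    msg <- c(msg, "weights must be complex")
  if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
  if (!object@csdKind %in% c("full", "nzpl"))
    msg <- c(msg, "csdKind must be 'full' or 'nzpl'")
  if (length(msg)) msg else TRUE
})

setMethod("nSensors", "SpatialFilterSet", function(x) dim(x@weights)[2L])
setMethod("nSources", "SpatialFilterSet", function(x) dim(x@weights)[3L])
setMethod("filterWeights", "SpatialFilterSet", function(x, k) {
  w <- x@weights[, , k, drop = FALSE]
  matrix(w, dim(x@weights)[1L], dim(x@weights)[2L])
})

setMethod("show", "SpatialFilterSet", function(object) {
  d <- dim(object@weights)
  cat(sprintf(
    "SpatialFilterSet (%s CSD, %s orientation): %d sources x (%d x %d), alpha=%g, cond=%.3g\n",
    object@csdKind, object@orientation, d[3L], d[1L], d[2L],
    object@alpha, object@condition))
})

#' Source-by-source connectivity matrix
#'
#' Symmetric `n_src x n_src` real matrix of reconstructed source coherences
#' (or a contrast of two such matrices), together with the source grid it was
#' computed on.  Undefined entries (zero reconstructed power) are `NaN`
#' sentinels so that downstream thresholding can exclude them.
#'
#' @slot values numeric matrix `n_src x n_src`.
#' @slot grid the [SourceGrid-class] the values refer to.
#' @slot kind `"coherence"`, `"noise-contrast"` or `"fisher-contrast"`.
#'
#' @seealso [sourceCoherenceMap()], [noiseContrast()], [fisherContrast()],
#'   [logRoc()]
#' @export
setClass("ConnectivityMatrix",
  representation(
    values = "matrix",
    grid   = "SourceGrid",
    kind   = "character"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (nrow(v) != nSources(object@grid))
    msg <- c(msg, "values dimension must match grid size")
  if (!object@kind %in% c("coherence", "noise-contrast", "fisher-contrast"))
    msg <- c(msg, "invalid kind")
  ok <- is.finite(v)
  if (any(abs(v - t(v)) > 1e-8, na.rm = TRUE))
    msg <- c(msg, "values must be symmetric")
  # coherence values are non-negative; values above 1 are possible for maps
  # reconstructed from an (indefinite) NZPL rCSD, whose phase-lagged
  # interactions are deliberately overestimated
  if (object@kind == "coherence" && any(v[ok] < -1e-8))
    msg <- c(msg, "coherence values must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("connValues", "ConnectivityMatrix", function(x, ...) x@values)
setMethod("kindOf", "ConnectivityMatrix", function(x) x@kind)
setMethod("nSources", "ConnectivityMatrix", function(x) nrow(x@values))

setMethod("show", "ConnectivityMatrix", function(object) {
  v <- object@values[upper.tri(object@values)]
  cat(sprintf(
    "ConnectivityMatrix (%s): %d x %d sources, %d undefined pairs\n",
    object@kind, nrow(object@values), ncol(object@values),
    sum(!is.finite(v))))
  if (any(is.finite(v)))
    cat(sprintf("  off-diagonal range %.4g .. %.4g\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})
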