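# collapse a 3-orientation gain array onto fixed normals -> n_sens x n_src
collapseGains <- function(lead, grid) {
  nn <- gridNormals(grid)
  if (is.null(nn))
    stop("grid has free orientations; supply n_src x 3 x time activity")
  g <- lfGains(lead)
  if (dim(g)[2L] != nrow(nn))
    stop("lead field and grid disagree on the number of sources")
  g[, , 1L] * rep(nn[, 1L], each = dim(g)[1L]) +
  g[, , 2L] * rep(nn[, 2L], each = dim(g)[1L]) +
  g[, , 3L] * rep(nn[, 3L], each = dim(g)[1L])
}

#' Project source activity to the sensors
#'
#' Linear forward projection: the sensor data are the superposition of every
#' source's gain times its moment time-series, plus optional additive sensor
#' noise.  Activity can be a `n_src x time` matrix of scalar moments (the
#' grid's fixed normals supply the orientation) or a `n_src x 3 x time`
#' array of free moment vectors.
#'
#' @param lead a [LeadField-class].
#' @param activity `n_src x time` matrix or `n_src x 3 x time` array
#'   (nA mm).
#' @param grid the [SourceGrid-class] (required for fixed-normal scalar
#'   activity).
#' @param sensorNoiseSd standard deviation of white sensor noise to add
#'   (same units as the lead field output; default 0).
#' @return Numeric `n_sensors x time` matrix.
#' @export
projectSources <- function(lead, activity, grid = NULL, sensorNoiseSd = 0) {
  stopifnot(is(lead, "LeadField"))
  g <- lfGains(lead)
  if (is.matrix(activity)) {
    if (is.null(grid))
      stop("scalar activity needs the source grid for its fixed normals")
    if (nrow(activity) != dim(g)[2L])
      stop("activity has ", nrow(activity), " sources; lead field expects ",
           dim(g)[2L])
    out <- collapseGains(lead, grid) %*% activity
  } else if (length(dim(activity)) == 3L) {
    if (dim(activity)[1L] != dim(g)[2L] || dim(activity)[2L] != 3L)
      stop("activity must be n_src x 3 x time")
    nt <- dim(activity)[3L]
    out <- matrix(0, dim(g)[1L], nt)
    for (o in 1:3)
      out <- out + g[, , o] %*% activity[, o, ]
  } else stop("activity must be a matrix or a 3-d array")
  if (sensorNoiseSd > 0)
    out <- out + matrix(rnorm(length(out), sd = sensorNoiseSd),
                        nrow(out), ncol(out))
  out
}
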