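#' Source grid inside the head model
#'
#' Dipole positions (mm, right-handed head frame, origin at the sphere
#' centre) with either fixed per-source normals or free 3-d orientation.
#'
#' @slot positions numeric matrix `n_src x 3` (mm).
#' @slot orientationMode `"fixed-normal"` or `"free-3D"`.
#' @slot normals numeric matrix `n_src x 3` of unit vectors
#'   (`fixed-normal` mode), otherwise a 0-row matrix.
#' @slot spacing grid spacing in mm (informative).
#'
#' @seealso [sourceGridSphere()], [sphericalEegLeadfield()]
#' @export
setClass("SourceGrid",
  representation(
    positions       = "matrix",
    orientationMode = "character",
    normals         = "matrix",
    spacing         = "numeric"
  )
)

setValidity("SourceGrid", function(object) {
  msg <- character()
  if (ncol(object@positions) != 3L)
    msg <- c(msg, "positions must be n x 3")
  if (!object@orientationMode %in% c("fixed-normal", "free-3D"))
    msg <- c(msg, "orientationMode must be 'fixed-normal' or 'free-3D'")
  if (object@orientationMode == "fixed-normal") {
    if (!all(dim(object@normals) == dim(object@positions)))
      msg <- c(msg, "normals must match positions in shape")
    else {
      nrm <- sqrt(rowSums(object@normals^2))
      if (any(abs(nrm - 1) > 1e-8))
        msg <- c(msg, "normals must be unit length")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("nSources", "SourceGrid", function(x) nrow(x@positions))
setMethod("gridPositions", "SourceGrid", function(x) x@positions)
setMethod("gridNormals", "SourceGrid", function(x) {
  if (x@orientationMode == "fixed-normal") x@normals else NULL
})

setMethod("show", "SourceGrid", function(object) {
  cat(sprintf("SourceGrid: %d sources (%s), spacing %g mm\n",
              nrow(object@positions), object@orientationMode, object@spacing))
  r <- sqrt(rowSums(object@positions^2))
  cat(sprintf("  radial extent %.1f - %.1f mm\n", min(r), max(r)))
})

#' Lead field: linear forward operator from dipoles to sensors
#'
#' Per-source `n_sensors x 3` gains: the sensor output of unit dipole moments
#' along x, y, z at each source.  EEG gains are in microvolts per nA mm with
#' average reference; MEG gains in fT per nA mm (units documented, not
#' enforced).
#'
#' @slot gains numeric array `n_sensors x n_src x 3`.
#' @slot sensorPositions numeric matrix `n_sensors x 3` (mm).
#' @slot sensorOrientations numeric matrix `n_sensors x 3` (unit vectors;
#'   MEG coil orientations, 0-row for EEG).
#' @slot modality `"EEG"` or `"MEG"`.
#' @slot reference character; for EEG, the reference convention
#'   (`"average"`), `"none"` for MEG.
#'
#' @seealso [sphericalEegLeadfield()], [singleSphereMegLeadfield()],
#'   [projectSources()], [saveLeadField()]
#' @export
setClass("LeadField",
  representation(
    gains              = "array",
    sensorPositions    = "matrix",
    sensorOrientations = "matrix",
    modality           = "character",
    reference          = "character"
  )
)

setValidity("LeadField", function(object) {
  msg <- character()
  d <- dim(object@gains)
  if (length(d) != 3L || d[3L] != 3L)
    msg <- c(msg, "gains must be an n_sensors x n_src x 3 array")
  if (!all(is.finite(object@gains)))
    msg <- c(msg, "gains must be finite")
  if (length(d) == 3L && d[1L] != nrow(object@sensorPositions))
    msg <- c(msg, "sensorPositions must have one row per sensor")
  if (!object@modality %in% c("EEG", "MEG"))
    msg <- c(msg, "modality must be 'EEG' or 'MEG'")
  if (length(d) == 3L && d[1L] > 0 && d[2L] > 0) {
    rowmax <- apply(abs(object@gains), 1L, max)
    if (any(rowmax == 0))
      msg <- c(msg, "lead field has an all-zero sensor row")
  }
  if (length(msg)) msg else TRUE
})

setMethod("nSensors", "LeadField", function(x) dim(x@gains)[1L])
setMethod("nSources", "LeadField", function(x) dim(x@gains)[2L])
setMethod("lfGains", "LeadField", function(x) x@gains)

setMethod("show", "LeadField", function(object) {
  d <- dim(object@gains)
  cat(sprintf("LeadField (%s): %d sensors x %d sources x 3, reference '%s'\n",
              object@modality, d[1L], d[2L], object@reference))
})
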