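#' @import methods
#' @importFrom stats fft rnorm runif qnorm pnorm t.test p.adjust sd mad quantile
#' @importFrom utils head tail read.csv write.csv
NULL

#' Matrix of values held by a container
#'
#' Accessor for the numeric or complex matrix stored inside the package's
#' matrix-like S4 containers ([CSDMatrix-class], [ConnectivityMatrix-class]).
#'
#' @param x an object.
#' @param ... additional arguments for methods.
#' @return A matrix.
#' @export
setGeneric("csdValues", function(x, ...) standardGeneric("csdValues"))

#' @rdname csdValues
#' @export
setGeneric("connValues", function(x, ...) standardGeneric("connValues"))

#' Kind of a CSD or connectivity container
#'
#' @param x an object.
#' @return A character scalar (`"full"`, `"imaginary"`, `"nzpl"` for CSDs;
#'   `"coherence"`, `"noise-contrast"`, `"fisher-contrast"` for connectivity).
#' @export
setGeneric("kindOf", function(x) standardGeneric("kindOf"))

#' Frequency band of a spectral object
#'
#' @param x an object.
#' @return Numeric length-2 vector `c(f_lo, f_hi)` in Hz.
#' @export
setGeneric("bandOf", function(x) standardGeneric("bandOf"))

#' Number of epochs that entered an estimate
#'
#' @param x an object.
#' @return Integer scalar.
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' Number of sensors
#'
#' @param x an object.
#' @return Integer scalar.
#' @export
setGeneric("nSensors", function(x) standardGeneric("nSensors"))

#' Number of sources
#'
#' @param x an object.
#' @return Integer scalar.
#' @export
setGeneric("nSources", function(x) standardGeneric("nSources"))

#' Gain array of a lead field
#'
#' @param x a [LeadField-class].
#' @return Numeric array `n_sensors x n_sources x 3`.
#' @export
setGeneric("lfGains", function(x) standardGeneric("lfGains"))

#' Source positions of a grid
#'
#' @param x a [SourceGrid-class].
#' @return Numeric matrix `n_sources x 3` (mm, head frame).
#' @export
setGeneric("gridPositions", function(x) standardGeneric("gridPositions"))

#' Source orientations of a grid
#'
#' @param x a [SourceGrid-class].
#' @return Numeric matrix `n_sources x 3` of unit normals, or `NULL` for
#'   free-orientation grids.
#' @export
setGeneric("gridNormals", function(x) standardGeneric("gridNormals"))

#' Spatial-filter weights for one source
#'
#' @param x a [SpatialFilterSet-class].
#' @param k source index.
#' @return Complex matrix `3 x n_sensors`.
#' @export
setGeneric("filterWeights", function(x, k) standardGeneric("filterWeights"))
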