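#' Per-epoch Fourier coefficients of a multichannel recording
#'
#' Holds the one-sided Fourier coefficients of every epoch of an epoched
#' multichannel time-series: one complex vector over sensors per epoch and
#' frequency bin (the "sample" whose outer product is a rank-1 cross-spectral
#' density).  Produced by [fftEpochs()].
#'
#' @slot coefficients complex array `n_epochs x n_sensors x n_freqs`.
#' @slot frequencies numeric vector of bin frequencies in Hz (0 .. Nyquist).
#' @slot samplingRate sampling rate in Hz.
#'
#' @seealso [fftEpochs()], [csdFromSamples()], [nzplCsd()]
#' @export
setClass("SpectralSamples",
  representation(
    coefficients = "array",
    frequencies  = "numeric",
    samplingRate = "numeric"
  )
)

setValidity("SpectralSamples", function(object) {
  msg <- character()
  if (length(dim(object@coefficients)) != 3L)
    msg <- c(msg, "coefficients must be a 3-d array (epochs x sensors x freqs)")
  if (!is.complex(object@coefficients))
    msg <- c(msg, "coefficients must be complex")
  if (length(dim(object@coefficients)) == 3L &&
      dim(object@coefficients)[3L] != length(object@frequencies))
    msg <- c(msg, "third dimension must match length(frequencies)")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(msg)) msg else TRUE
})

setMethod("nEpochs", "SpectralSamples", function(x) dim(x@coefficients)[1L])
setMethod("nSensors", "SpectralSamples", function(x) dim(x@coefficients)[2L])

setMethod("show", "SpectralSamples", function(object) {
  d <- dim(object@coefficients)
  cat("SpectralSamples:", d[1L], "epochs x", d[2L], "sensors x",
      d[3L], "frequency bins\n")
  cat("  sampling rate:", object@samplingRate, "Hz; bins",
      format(min(object@frequencies)), "-",
      format(max(object@frequencies)), "Hz\n")
})

#' Sensor-level cross-spectral density matrix
#'
#' A Hermitian complex sensors-by-sensors cross-spectral density (CSD),
#' averaged over epochs and over the frequency bins of a band.  Three kinds
#' are distinguished:
#' \describe{
#'   \item{`full`}{the ordinary CSD; Hermitian, real non-negative diagonal.}
#'   \item{`imaginary`}{\eqn{\iota\,\mathrm{Im}\,C}: off-diagonals keep only
#'     the phase-lagged part, diagonal is zero.}
#'   \item{`nzpl`}{off-diagonals are \eqn{\iota\,\mathrm{Im}\,C} and the
#'     diagonal holds the non-zero-phase-lagged (NZPL) power obtained from the
#'     eigendecomposition of the per-sample imaginary CSD (see [nzplCsd()]).}
#' }
#'
#' @slot values complex matrix `n_sensors x n_sensors`.
#' @slot band numeric `c(f_lo, f_hi)` in Hz.
#' @slot nEpochs number of epochs averaged.
#' @slot kind one of `"full"`, `"imaginary"`, `"nzpl"`.
#'
#' @seealso [csdFromSamples()], [nzplCsd()], [coherency()], [nzplCoherence()]
#' @export
setClass("CSDMatrix",
  representation(
    values  = "matrix",
    band    = "numeric",
    nEpochs = "integer",
    kind    = "character"
  )
)

setValidity("CSDMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.complex(v) || nrow(v) != ncol(v))
    msg <- c(msg, "values must be a square complex matrix")
  if (!object@kind %in% c("full", "imaginary", "nzpl"))
    msg <- c(msg, "kind must be 'full', 'imaginary' or 'nzpl'")
  if (length(object@band) != 2L || object@band[1L] > object@band[2L])
    msg <- c(msg, "band must be c(f_lo, f_hi) with f_lo <= f_hi")
  tol <- 1e-8 * max(1, max(Mod(v)))
  if (object@kind %in% c("full", "nzpl")) {
    if (max(Mod(v - Conj(t(v)))) > tol)
      msg <- c(msg, "full/nzpl CSD must be Hermitian")
    if (max(abs(Im(diag(v)))) > tol || any(Re(diag(v)) < -tol))
      msg <- c(msg, "diagonal must be real and non-negative")
  }
  if (object@kind == "imaginary" && max(Mod(diag(v))) > tol)
    msg <- c(msg, "imaginary CSD must have zero diagonal")
  if (length(msg)) msg else TRUE
})

setMethod("csdValues", "CSDMatrix", function(x, ...) x@values)
setMethod("kindOf", "CSDMatrix", function(x) x@kind)
setMethod("bandOf", "CSDMatrix", function(x) x@band)
setMethod("nEpochs", "CSDMatrix", function(x) x@nEpochs)
setMethod("nSensors", "CSDMatrix", function(x) nrow(x@values))

setMethod("show", "CSDMatrix", function(object) {
  cat(sprintf("CSDMatrix (%s): %d x %d sensors, band %g-%g Hz, %d epochs\n",
              object@kind, nrow(object@values), ncol(object@values),
              object@band[1L], object@band[2L], object@nEpochs))
})

#' Eigendecomposition of a (part of a) sample CSD
#'
#' Column eigenvectors and eigenvalues of the full sample CSD, of its real
#' (symmetric) part, or of its imaginary (anti-symmetric) part.  For a rank-1
#' sample CSD the imaginary part has exactly two non-zero eigenvalues forming
#' a conjugate pair \eqn{\pm\iota\sigma}; their eigenvectors carry the
#' non-zero-phase-lagged power (see [nzplPower()]).
#'
#' @slot vectors complex matrix of column eigenvectors (unit norm).
#' @slot values complex vector of eigenvalues.
#' @slot sourceKind one of `"full"`, `"real-part"`, `"imaginary-part"`.
#'
#' @seealso [imagEigendecompose()], [nzplPower()]
#' @export
setClass("EigenPair",
  representation(
    vectors    = "matrix",
    values     = "complex",
    sourceKind = "character"
  )
)

setValidity("EigenPair", function(object) {
  msg <- character()
  if (ncol(object@vectors) != length(object@values))
    msg <- c(msg, "one eigenvalue per eigenvector column required")
  if (!object@sourceKind %in% c("full", "real-part", "imaginary-part"))
    msg <- c(msg, "sourceKind must be 'full', 'real-part' or 'imaginary-part'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EigenPair", function(object) {
  cat(sprintf("EigenPair (%s part): %d eigenvalues, largest |lambda| = %g\n",
              object@sourceKind, length(object@values),
              max(Mod(object@values))))
})
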