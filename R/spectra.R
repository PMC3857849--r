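#' Fourier transform every epoch of a multichannel recording
#'
#' Applies one discrete Fourier transform to the full length of each epoch
#' (no padding, no segmentation) and keeps the one-sided spectrum from 0 Hz
#' to the Nyquist frequency.  Coefficients are scaled by `1/n_time`, so a
#' unit-amplitude sinusoid at an exact bin frequency yields a coefficient of
#' modulus 0.5 at that bin.  An optional Hann taper is available; the default
#' is the plain rectangular window.
#'
#' @param epochs numeric array `n_epochs x n_sensors x n_time` of epoched
#'   sensor data (all epochs the same length).
#' @param samplingRate sampling rate in Hz (> 0).
#' @param window `"none"` (default) or `"hann"`.
#' @return A [SpectralSamples-class] object.
#'
#' @examples
#' t <- seq(0, 1 - 1/200, by = 1/200)
#' x <- array(0, c(1, 2, 200))
#' x[1, 1, ] <- cos(2 * pi * 33 * t)
#' x[1, 2, ] <- cos(2 * pi * 33 * t - pi / 2)
#' sp <- fftEpochs(x, 200)
#' Arg(sp@coefficients[1, 1, 34] / sp@coefficients[1, 2, 34])  # pi/2
#' @export
fftEpochs <- function(epochs, samplingRate, window = c("none", "hann")) {
  window <- match.arg(window)
  if (is.matrix(epochs))  # single epoch convenience: sensors x time
    epochs <- array(epochs, c(1L, nrow(epochs), ncol(epochs)))
  d <- dim(epochs)
  if (length(d) != 3L)
    stop("epochs must be an n_epochs x n_sensors x n_time array")
  if (any(d == 0L)) stop("empty input: no epochs, sensors or samples")
  if (!is.numeric(samplingRate) || length(samplingRate) != 1L ||
      samplingRate <= 0)
    stop("samplingRate must be a single positive number")
  nt <- d[3L]
  taper <- if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nt) / (nt + 1))
    w / sqrt(mean(w^2))  # preserve power scale
  } else rep(1, nt)
  nf <- nt %/% 2L + 1L
  coef <- array(0i, c(d[1L], d[2L], nf))
  for (e in seq_len(d[1L])) {
    # mvfft transforms columns: time x sensors
    x <- t(epochs[e, , , drop = FALSE][1L, , ]) * taper
    if (d[2L] == 1L) x <- matrix(x, ncol = 1L)
    f <- stats::mvfft(x) / nt
    coef[e, , ] <- t(f[seq_len(nf), , drop = FALSE])
  }
  freqs <- (seq_len(nf) - 1L) * samplingRate / nt
  new("SpectralSamples", coefficients = coef, frequencies = freqs,
      samplingRate = samplingRate)
}

# indices of frequency bins inside a band (endpoints inclusive)
bandBins <- function(samples, band) {
  if (length(band) == 1L) band <- c(band, band)
  which(samples@frequencies >= band[1L] - 1e-9 &
        samples@frequencies <= band[2L] + 1e-9)
}

#' Full cross-spectral density from Fourier samples
#'
#' Averages the rank-1 outer products \eqn{p p^{H}} of the per-epoch,
#' per-bin coefficient vectors over all epochs and over the frequency bins
#' inside `band` (endpoints inclusive).  The result is Hermitian with a real
#' non-negative diagonal (the auto-spectra).
#'
#' @param samples a [SpectralSamples-class] object.
#' @param band numeric `c(f_lo, f_hi)` in Hz (a single frequency selects one
#'   bin).
#' @return A [CSDMatrix-class] of kind `"full"`.
#' @export
csdFromSamples <- function(samples, band) {
  stopifnot(is(samples, "SpectralSamples"))
  bins <- bandBins(samples, band)
  if (length(bins) == 0L)
    stop(sprintf("no frequency bins inside band [%g, %g] Hz",
                 band[1L], band[length(band)]))
  ns <- nSensors(samples)
  ne <- nEpochs(samples)
  acc <- matrix(0i, ns, ns)
  for (b in bins) {
    P <- samples@coefficients[, , b, drop = FALSE][, , 1L]
    if (ne == 1L) P <- matrix(P, nrow = 1L)
    # sum_e p_e p_e^H  ==  t(P) %*% Conj(P)
    acc <- acc + t(P) %*% Conj(P)
  }
  vals <- hermitianise(acc / (ne * length(bins)))
  new("CSDMatrix", values = vals,
      band = c(samples@frequencies[bins[1L]],
               samples@frequencies[bins[length(bins)]]),
      nEpochs = as.integer(ne), kind = "full")
}

#' Complex coherency of a CSD
#'
#' The ratio of the cross-spectra to the auto-spectra,
#' \eqn{\kappa_{ij} = C_{ij} / \sqrt{C_{ii} C_{jj}}}: a frequency-domain
#' correlation coefficient.  Its modulus is the coherence; its imaginary
#' part is the imaginary coherency, which vanishes for purely instantaneous
#' (volume-conducted) interactions.  Entries whose auto-spectra are not
#' strictly positive are set to `NaN` with a warning.
#'
#' @param csd a [CSDMatrix-class] (any kind with a meaningful diagonal).
#' @return A complex matrix with unit diagonal where defined.
#' @export
coherency <- function(csd) {
  stopifnot(is(csd, "CSDMatrix"))
  v <- csd@values
  d <- Re(diag(v))
  bad <- d <= 0 | !is.finite(d)
  if (any(bad))
    warning(sum(bad), " sensor(s) with zero auto-spectrum; entries set to NaN")
  d[bad] <- NaN
  den <- sqrt(outer(d, d))
  coh <- v / den
  diag(coh) <- ifelse(bad, NaN_complex_(), 1 + 0i)
  coh
}

NaN_complex_ <- function() complex(real = NaN, imaginary = 0)

#' Eigendecomposition of a sample CSD (or one of its parts)
#'
#' Decomposes the full complex sample CSD, its real (symmetric) part, or its
#' imaginary (anti-symmetric) part into eigenvectors and eigenvalues.  A
#' rank-1 sample CSD \eqn{p p^{H}} has a single non-zero eigenvalue
#' \eqn{\sum_i |p_i|^2}; its anti-symmetric imaginary part has exactly two
#' non-zero eigenvalues forming a conjugate pair \eqn{\pm\iota\sigma} whose
#' (purely imaginary-paired) eigenvectors carry the phase-lagged power.
#'
#' @param sampleCsd square complex (or real) matrix: the CSD of one sample
#'   (one epoch at one frequency bin), or any Hermitian CSD.
#' @param part `"imaginary"` (default), `"real"` or `"full"`.
#' @return An [EigenPair-class].
#' @export
csdEigendecompose <- function(sampleCsd,
                              part = c("imaginary", "real", "full")) {
  part <- match.arg(part)
  if (!is.matrix(sampleCsd) || nrow(sampleCsd) != ncol(sampleCsd))
    stop("sampleCsd must be a square matrix")
  m <- switch(part,
    imaginary = Im(sampleCsd),
    real      = Re(sampleCsd),
    full      = sampleCsd)
  e <- eigen(m, symmetric = (part == "real"))
  vec <- e$vectors
  val <- e$values
  if (!is.complex(vec)) vec <- vec + 0i
  if (!is.complex(val)) val <- val + 0i
  new("EigenPair", vectors = vec, values = val,
      sourceKind = switch(part, imaginary = "imaginary-part",
                          real = "real-part", full = "full"))
}

#' @rdname csdEigendecompose
#' @export
imagEigendecompose <- function(sampleCsd)
  csdEigendecompose(sampleCsd, part = "imaginary")

#' Non-zero-phase-lagged power from an imaginary-part eigendecomposition
#'
#' The per-sensor power attributable to phase-lagged interactions within one
#' sample: the element-wise squared moduli of the non-zero eigenvectors of
#' the anti-symmetric imaginary CSD, weighted by the moduli of their
#' eigenvalues and summed over the conjugate pair(s).  For the real rank-1
#' case this reduces to the Hadamard-square relation between the single
#' non-zero eigenpair and the per-channel power; for a zero-lag sample (zero
#' imaginary part) it is the zero vector.
#'
#' Eigenvalues below `tol` times the largest modulus are treated as zero.
#'
#' @param eig an [EigenPair-class] with `sourceKind = "imaginary-part"`.
#' @param tol relative threshold for non-zero eigenvalues (default 1e-12).
#' @return Real non-negative vector over sensors.
#' @export
nzplPower <- function(eig, tol = 1e-12) {
  stopifnot(is(eig, "EigenPair"))
  if (eig@sourceKind != "imaginary-part")
    stop("nzplPower expects an imaginary-part eigendecomposition")
  lam <- Mod(eig@values)
  mx <- max(lam)
  if (mx == 0) return(numeric(nrow(eig@vectors)))
  keep <- which(lam > tol * mx)
  pw <- numeric(nrow(eig@vectors))
  for (j in keep) {
    q <- eig@vectors[, j]
    pw <- pw + lam[j] * Mod(q)^2 / sum(Mod(q)^2)
  }
  pw
}

# Fast closed-form NZPL power of one rank-1 sample p (complex vector):
# Im(p p^H) = b a^T - a b^T with a = Re(p), b = Im(p); its two non-zero
# eigenvalues are +-i*s with s = sqrt(|a|^2 |b|^2 - (a.b)^2) and the summed
# |lambda|-weighted squared-modulus eigenvector power reduces to the form
# below. Cross-checked against the eigen() route in the test suite.
nzplPowerSample <- function(p, tol = 1e-12) {
  a <- Re(p); b <- Im(p)
  A2 <- sum(a^2); B2 <- sum(b^2); cc <- sum(a * b)
  # s^2 as a sum of squared 2x2 minors: exactly 0 for zero-lag samples
  M <- b %o% a - a %o% b
  s2 <- sum(M^2) / 2
  scale <- (A2 + B2)^2  # s2 is quadratic in total power
  if (scale == 0 || s2 <= tol^2 * scale) return(numeric(length(p)))
  s <- sqrt(s2)
  if (B2 >= A2) {
    # q = a + ((i s - c)/B2) b  (unnormalised eigenvector for +i s)
    q2 <- a^2 - 2 * (cc / B2) * a * b + ((s2 + cc^2) / B2^2) * b^2
  } else {
    q2 <- b^2 - 2 * (cc / A2) * a * b + ((s2 + cc^2) / A2^2) * a^2
  }
  2 * s * q2 / sum(q2)
}

#' Non-zero-phase-lagged CSD
#'
#' Builds the NZPL CSD: for every sample (one epoch at one frequency bin)
#' the off-diagonal is the imaginary CSD \eqn{\iota\,\mathrm{Im}(p p^{H})}
#' and the diagonal is replaced by the eigen-derived per-sensor power that
#' contributes only to phase-lagged interactions ([nzplPower()]); samples
#' are then averaged over epochs and in-band bins.  The result is Hermitian
#' with a real non-negative diagonal.  For a dataset in which all channels
#' share one phase per sample, the NZPL CSD is the zero matrix.
#'
#' @inheritParams csdFromSamples
#' @return A [CSDMatrix-class] of kind `"nzpl"`.
#' @export
nzplCsd <- function(samples, band) {
  stopifnot(is(samples, "SpectralSamples"))
  bins <- bandBins(samples, band)
  if (length(bins) == 0L)
    stop(sprintf("no frequency bins inside band [%g, %g] Hz",
                 band[1L], band[length(band)]))
  ns <- nSensors(samples)
  ne <- nEpochs(samples)
  off <- matrix(0, ns, ns)   # accumulates Im(p p^H)
  dg <- numeric(ns)
  for (b in bins) {
    for (e in seq_len(ne)) {
      p <- samples@coefficients[e, , b]
      a <- Re(p); bb <- Im(p)
      off <- off + (bb %o% a - a %o% bb)  # Im(p_j conj(p_k))
      dg <- dg + nzplPowerSample(p)
    }
  }
  nsmp <- ne * length(bins)
  vals <- 1i * off / nsmp
  diag(vals) <- dg / nsmp
  new("CSDMatrix", values = hermitianise(vals),
      band = c(samples@frequencies[bins[1L]],
               samples@frequencies[bins[length(bins)]]),
      nEpochs = as.integer(ne), kind = "nzpl")
}

#' Imaginary CSD
#'
#' The anti-Hermitian matrix \eqn{\iota\,\mathrm{Im}\,C} with zero diagonal:
#' the phase-lagged off-diagonal part of a full CSD without the NZPL
#' diagonal replacement.
#'
#' @param csd a [CSDMatrix-class] of kind `"full"`.
#' @return A [CSDMatrix-class] of kind `"imaginary"`.
#' @export
imaginaryCsd <- function(csd) {
  stopifnot(is(csd, "CSDMatrix"))
  v <- 1i * Im(csd@values)
  diag(v) <- 0i
  new("CSDMatrix", values = v, band = csd@band, nEpochs = csd@nEpochs,
      kind = "imaginary")
}

#' NZPL coherence
#'
#' Coherence computed from an NZPL CSD in the same way as standard
#' coherence: the modulus of the off-diagonal divided by the geometric mean
#' of the NZPL diagonal powers.  Because both the numerator and the
#' denominator contain only phase-lagged components, a noiseless pair of
#' sinusoids with any fixed lag in (0, pi) attains coherence 1, whereas the
#' magnitude of the imaginary coherency would be |sin(lag)|.  Entries with
#' (numerically) zero NZPL power are `NaN` sentinels with a warning.
#'
#' @param nzpl a [CSDMatrix-class] of kind `"nzpl"`.
#' @param tol relative threshold below which a diagonal power counts as zero.
#' @return Symmetric real matrix with values in `[0, 1]`.
#' @export
nzplCoherence <- function(nzpl, tol = 1e-12) {
  stopifnot(is(nzpl, "CSDMatrix"))
  if (nzpl@kind != "nzpl")
    stop("nzplCoherence expects a CSD of kind 'nzpl'")
  v <- nzpl@values
  d <- Re(diag(v))
  mx <- max(d, 0)
  bad <- !(d > tol * mx) | !is.finite(d)
  if (mx == 0) bad <- rep(TRUE, length(d))
  if (any(bad))
    warning(sum(bad),
            " sensor(s) with zero NZPL power; entries set to NaN")
  d[bad] <- NaN
  coh <- Mod(v) / sqrt(outer(d, d))
  coh <- pmin(coh, 1)  # guard tiny numerical overshoot
  diag(coh) <- ifelse(bad, NaN, 1)
  coh
}
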