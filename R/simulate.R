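#' Construct a simulation configuration
#'
#' Builds a [SimulationConfig-class] with the coherent two-node network
#' protocol's study conditions as defaults; any field can be overridden.
#' See the class documentation for the meaning of every field.
#'
#' @param nodeCentres 2 x 3 matrix of node centres (mm).
#' @param nodeFwhm node smoothing FWHM (mm).
#' @param gridSpacing grid spacing (mm).
#' @param nSourcesTarget target source count.
#' @param freq oscillation frequency (Hz).
#' @param lagMean mean inter-node phase lag (radians).
#' @param lagFwhm von Mises jitter FWHM (radians); 0 for a fixed lag.
#' @param snp signal-to-noise proportion in `[0, 1]`.
#' @param amplitude total source amplitude at the node centres (nA).
#' @param backgroundAmplitude amplitude of the background (non-node)
#'   dipoles' white noise (nA).
#' @param nEpochs number of epochs.
#' @param epochMs epoch duration (ms) for each of pre and post.
#' @param samplingRate sampling rate (Hz).
#' @param headCentre origin of the spherical head frame in node
#'   coordinates (mm).
#' @param seed integer seed.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(nodeCentres = rbind(c(-40.5, -72.5, 17),
                                                 c(42, -72.5, 17)),
                             nodeFwhm = 5,
                             gridSpacing = 7.5,
                             nSourcesTarget = 1454,
                             freq = 33,
                             lagMean = 0.5 * pi,
                             lagFwhm = 0.25 * pi,
                             snp = 0.9,
                             amplitude = 1,
                             backgroundAmplitude = 0.1,
                             nEpochs = 100L,
                             epochMs = 1000,
                             samplingRate = 1000,
                             headCentre = c(0, -20, 15),
                             seed = 1L) {
  new("SimulationConfig",
      nodeCentres = nodeCentres, nodeFwhm = nodeFwhm,
      gridSpacing = gridSpacing, nSourcesTarget = nSourcesTarget,
      freq = freq, lagMean = lagMean, lagFwhm = lagFwhm, snp = snp,
      amplitude = amplitude, backgroundAmplitude = backgroundAmplitude,
      nEpochs = as.integer(nEpochs),
      epochMs = epochMs, samplingRate = samplingRate,
      headCentre = headCentre, seed = as.integer(seed))
}

#' von Mises concentration from a full width at half maximum
#'
#' Solves `density(mean +- fwhm/2) = density(mean) / 2` for the
#' concentration of a von Mises distribution (a Gaussian wrapped on the
#' circle): \eqn{\kappa = \ln 2 / (1 - \cos(\mathrm{fwhm}/2))}.
#' Monotone decreasing in the FWHM; `fwhm = 0` is the degenerate point-mass
#' limit and returns `Inf`.
#'
#' @param fwhm full width at half maximum in radians, in `(0, 2*pi]`
#'   (0 allowed, giving `Inf`).
#' @return Concentration parameter kappa.
#' @export
vonMisesKappa <- function(fwhm) {
  stopifnot(all(fwhm >= 0), all(fwhm <= 2 * pi))
  ifelse(fwhm == 0, Inf, log(2) / (1 - cos(fwhm / 2)))
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution,
# vectorised over rejection batches
rvonmises <- function(n, mu, kappa) {
  if (!is.finite(kappa)) return(rep(mu, n))
  if (kappa < 1e-8) return(runif(n, -pi, pi) + mu)
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  rr <- (1 + rho^2) / (2 * rho)
  out <- numeric(0L)
  while (length(out) < n) {
    m <- max(64L, ceiling(1.3 * (n - length(out))))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + rr * z) / (rr + z)
    cdens <- kappa * (rr - f)
    ok <- (cdens * (2 - cdens) - u2 > 0) |
          (log(cdens / u2) + 1 - cdens >= 0)
    out <- c(out, (mu + sign(u3 - 0.5) * acos(f))[ok])
  }
  out[seq_len(n)]
}

#' Sample per-epoch phase lags
#'
#' Draws one phase lag per epoch from a von Mises distribution with the
#' given circular mean and FWHM, from the degenerate (fixed-lag) limit when
#' `fwhm = 0`, or from the uniform circular distribution when
#' `fwhm = "uniform"` (the pre-stimulus protocol).
#'
#' @param mean circular mean (radians).
#' @param fwhm FWHM in radians, 0 for a point mass, or `"uniform"`.
#' @param nEpochs number of draws.
#' @param seed optional integer seed (the caller's RNG stream is restored).
#' @return Numeric vector of `nEpochs` lags (radians).
#' @export
samplePhaseLags <- function(mean, fwhm, nEpochs, seed = NULL) {
  withSeed(seed, {
    if (identical(fwhm, "uniform")) runif(nEpochs, 0, 2 * pi)
    else rvonmises(nEpochs, mean, vonMisesKappa(fwhm))
  })
}

#' SNP signal-and-noise mixing
#'
#' Mixes a signal and a noise series so that the signal carries the
#' fraction `snp` of the output power: both series are normalised to unit
#' mean-square power and combined as
#' `sqrt(snp) * s + sqrt(1 - snp) * n`, then scaled to `amplitude`.  The
#' implied signal-to-noise ratio is `10 log10(snp / (1 - snp))` dB
#' (9.54 dB at `snp = 0.9`).
#'
#' @param signal,noise numeric series of equal length.
#' @param snp signal-to-noise proportion in `[0, 1]`.
#' @param amplitude root-mean-square amplitude of the output (default 1).
#' @return Numeric series of the same length.
#' @seealso [snpToDb()]
#' @export
mixSnp <- function(signal, noise, snp, amplitude = 1) {
  stopifnot(length(signal) == length(noise), snp >= 0, snp <= 1)
  sp <- seriesPower(signal); np <- seriesPower(noise)
  if (snp > 0 && sp == 0)
    stop("signal has zero power but snp = ", snp)
  if (snp < 1 && np == 0)
    stop("noise has zero power but snp = ", snp)
  s <- if (snp > 0) signal / sqrt(sp) else 0 * signal
  n <- if (snp < 1) noise / sqrt(np) else 0 * noise
  amplitude * (sqrt(snp) * s + sqrt(1 - snp) * n)
}

#' @describeIn mixSnp implied SNR in dB for a signal-to-noise proportion.
#' @export
snpToDb <- function(snp) 10 * log10(snp / (1 - snp))

#' Gaussian node weights on a source grid
#'
#' Evaluates an isotropic Gaussian of the given FWHM, centred on the grid
#' point nearest to `centre` (peak weight 1 there), at every grid position:
#' the spatial smoothing that turns a seed voxel into an extended node.
#'
#' @param grid a [SourceGrid-class].
#' @param centre numeric length-3 position (mm, same frame as the grid).
#' @param fwhmMm Gaussian FWHM in mm.
#' @return List with `weights` (per-source vector, peak 1) and `index`
#'   (grid index of the snapped centre).
#' @export
gaussianNodeWeights <- function(grid, centre, fwhmMm) {
  stopifnot(is(grid, "SourceGrid"), length(centre) == 3L, fwhmMm >= 0)
  pos <- gridPositions(grid)
  d2c <- colSums((t(pos) - centre)^2)
  idx <- which.min(d2c)
  if (sqrt(d2c[idx]) > 1.5 * grid@spacing + 1e-9)
    stop(sprintf(
      "node centre (%.1f, %.1f, %.1f) lies %.1f mm from the nearest grid point (> 1.5 spacings): outside the grid hull",
      centre[1L], centre[2L], centre[3L], sqrt(d2c[idx])))
  d2 <- colSums((t(pos) - pos[idx, ])^2)
  w <- if (fwhmMm == 0) as.numeric(d2 == 0)
       else exp(-4 * log(2) * d2 / fwhmMm^2)
  list(weights = w, index = idx)
}

#' Simulate the coherent two-node network dataset
#'
#' Implements the full synthetic protocol: two Gaussian-smoothed nodes carry
#' a common sinusoidal oscillation whose inter-node phase lag is drawn per
#' epoch from a von Mises distribution (post-stimulus) or from the uniform
#' circular distribution (pre-stimulus, same band power); every source
#' additionally carries independent Gaussian white noise; node sources mix
#' signal and noise under the SNP rule with constant total amplitude; the
#' sensor data are the linear forward projection.
#'
#' Per source `v` with node weight `w_v` the moment series is
#' `amplitude * (sqrt(snp) * w_v * s + sqrt(1 - snp * w_v^2) * n_v)` with
#' `s` the unit-power node oscillation and `n_v` unit-power white noise, so
#' total power is `amplitude^2` at every source and the node centre attains
#' exactly the configured SNP.
#'
#' @param config a [SimulationConfig-class]; node centres are interpreted
#'   relative to `config@headCentre`.
#' @param lead a [LeadField-class] for the grid.
#' @param grid the [SourceGrid-class] (fixed normals required).
#' @return A [SimulatedDataset-class].
#' @export
simulateDataset <- function(config, lead, grid) {
  stopifnot(is(config, "SimulationConfig"), is(lead, "LeadField"),
            is(grid, "SourceGrid"))
  if (nSources(lead) != nSources(grid))
    stop("lead field and grid disagree on the number of sources")
  fs <- config@samplingRate
  nt <- round(config@epochMs / 1000 * fs)
  ne <- config@nEpochs
  nsrc <- nSources(grid)
  tt <- (seq_len(nt) - 1L) / fs
  n1 <- gaussianNodeWeights(grid,
          config@nodeCentres[1L, ] - config@headCentre, config@nodeFwhm)
  n2 <- gaussianNodeWeights(grid,
          config@nodeCentres[2L, ] - config@headCentre, config@nodeFwhm)
  G <- collapseGains(lead, grid)
  nsens <- nrow(G)
  withSeed(config@seed, {
    lagsPost <- samplePhaseLags(config@lagMean, config@lagFwhm, ne)
    lagsPre <- samplePhaseLags(0, "uniform", ne)
    makePeriod <- function(lags) {
      out <- array(0, c(ne, nsens, nt))
      for (e in seq_len(ne)) {
        phase <- runif(1L, 0, 2 * pi)
        s1 <- sin(2 * pi * config@freq * tt + phase)
        s2 <- sin(2 * pi * config@freq * tt + phase + lags[e])
        s1 <- s1 / sqrt(seriesPower(s1))
        s2 <- s2 / sqrt(seriesPower(s2))
        noise <- matrix(rnorm(nsrc * nt), nsrc, nt)
        noise <- noise / sqrt(rowMeans(noise^2))
        w <- sqrt(config@snp) * (n1$weights %o% s1 + n2$weights %o% s2)
        wmax <- pmax(n1$weights, n2$weights)
        amp <- wmax * config@amplitude +
          (1 - wmax) * config@backgroundAmplitude
        wn <- sqrt(pmax(0, 1 - config@snp * (n1$weights^2 + n2$weights^2)))
        S <- amp * (w + wn * noise)
        out[e, , ] <- G %*% S
      }
      out
    }
    post <- makePeriod(lagsPost)
    pre <- makePeriod(lagsPre)
  })
  new("SimulatedDataset", pre = pre, post = post, samplingRate = fs,
      nodeWeights = cbind(n1$weights, n2$weights),
      nodeIndex = c(n1$index, n2$index), config = config)
}

#' Ground-truth connection matrix
#'
#' The true connection space of the simulated network: the outer product of
#' the two nodes' Gaussian weight profiles, symmetrised, with peak 1 at the
#' true node pair.  This smoothed truth penalises reconstruction error
#' progressively with distance from the true connection.
#'
#' @param grid a [SourceGrid-class].
#' @param w1,w2 per-source node weights (peak 1), e.g. from
#'   [gaussianNodeWeights()] or a [SimulatedDataset-class]'s `nodeWeights`.
#' @return A [ConnectivityMatrix-class] of kind `"coherence"` holding the
#'   truth values in `[0, 1]`.
#' @export
trueConnectionMatrix <- function(grid, w1, w2) {
  stopifnot(is(grid, "SourceGrid"),
            length(w1) == nSources(grid), length(w2) == nSources(grid))
  m <- pmax(w1 %o% w2, w2 %o% w1)
  diag(m) <- 0
  new("ConnectivityMatrix", values = m, grid = grid, kind = "coherence")
}
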