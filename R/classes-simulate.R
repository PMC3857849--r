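#' Configuration of the coherent two-node network simulation
#'
#' Holds every tunable of the synthetic coherent-network protocol: two
#' Gaussian-smoothed cortical nodes oscillating at a common frequency with a
#' von Mises-jittered phase lag in the post-stimulus period and a uniformly
#' random lag in the pre-stimulus period, embedded in white background
#' activity under a signal-to-noise-proportion (SNP) mixing rule.
#'
#' Defaults are the simulated study conditions: node centres
#' `[-40.5 -72.5 17]` and `[42 -72.5 17]` mm (82.5 mm apart), 5 mm node
#' FWHM, a 7.5 mm grid, 33 Hz oscillation, mean lag 0.5*pi with jitter FWHM
#' 0.25*pi, SNP 0.9 (9.54 dB), 1 nA total amplitude, 100 epochs of 1000 ms
#' pre- and post-stimulus each.  The sampling rate (1000 Hz) and the head
#' centre used to map the MNI-style node coordinates into the spherical head
#' frame are package choices, documented in the methods vignette.
#'
#' @slot nodeCentres numeric `2 x 3` matrix (mm, MNI-style coordinates).
#' @slot nodeFwhm Gaussian node smoothing FWHM in mm.
#' @slot gridSpacing source grid spacing in mm.
#' @slot nSourcesTarget target number of grid sources.
#' @slot freq oscillation frequency in Hz.
#' @slot lagMean mean phase lag (radians) between the two nodes.
#' @slot lagFwhm FWHM of the von Mises phase-lag jitter (radians); 0 means a
#'   fixed lag.
#' @slot snp signal-to-noise proportion in `[0, 1]` (fraction of power
#'   carried by the oscillation at a node centre).
#' @slot amplitude total source amplitude at the node centres (nA).
#' @slot backgroundAmplitude amplitude of the background (non-node) white
#'   noise dipoles (nA).
#' @slot nEpochs number of epochs.
#' @slot epochMs duration of each of the pre and post periods (ms).
#' @slot samplingRate sampling rate in Hz.
#' @slot headCentre head-frame origin expressed in the node coordinate
#'   system (mm); node positions are used relative to this point.
#' @slot seed integer seed for every stochastic stage.
#'
#' @seealso [simulationConfig()], [simulateDataset()]
#' @export
setClass("SimulationConfig",
  representation(
    nodeCentres    = "matrix",
    nodeFwhm       = "numeric",
    gridSpacing    = "numeric",
    nSourcesTarget = "numeric",
    freq           = "numeric",
    lagMean        = "numeric",
    lagFwhm        = "numeric",
    snp            = "numeric",
    amplitude      = "numeric",
    backgroundAmplitude = "numeric",
    nEpochs        = "integer",
    epochMs        = "numeric",
    samplingRate   = "numeric",
    headCentre     = "numeric",
    seed           = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (!all(dim(object@nodeCentres) == c(2L, 3L)))
    msg <- c(msg, "nodeCentres must be a 2 x 3 matrix")
  if (object@snp < 0 || object@snp > 1)
    msg <- c(msg, "snp must lie in [0, 1]")
  if (object@nodeFwhm < 0 || object@lagFwhm < 0)
    msg <- c(msg, "fwhm values must be >= 0")
  if (object@nEpochs < 1L) msg <- c(msg, "nEpochs must be >= 1")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("nEpochs", "SimulationConfig", function(x) x@nEpochs)

setMethod("show", "SimulationConfig", function(object) {
  d <- sqrt(sum((object@nodeCentres[1L, ] - object@nodeCentres[2L, ])^2))
  cat("SimulationConfig:\n")
  cat(sprintf("  nodes %.1f mm apart, FWHM %g mm, grid %g mm (target %d src)\n",
              d, object@nodeFwhm, object@gridSpacing,
              as.integer(object@nSourcesTarget)))
  cat(sprintf("  %g Hz, lag %.3g rad (jitter FWHM %.3g), SNP %g, %d x %g ms, fs %g Hz, seed %d\n",
              object@freq, object@lagMean, object@lagFwhm, object@snp,
              object@nEpochs, object@epochMs, object@samplingRate,
              object@seed))
})

#' Simulated epoched sensor dataset with ground truth
#'
#' Pre- and post-stimulus epoched sensor data from [simulateDataset()],
#' together with the per-source Gaussian node weights that define the true
#' coherent pair.
#'
#' @slot pre numeric array `n_epochs x n_sensors x n_time`.
#' @slot post numeric array `n_epochs x n_sensors x n_time`.
#' @slot samplingRate sampling rate in Hz.
#' @slot nodeWeights numeric matrix `n_src x 2`: Gaussian weight of every
#'   source for node 1 and node 2.
#' @slot nodeIndex integer length-2: grid index of the two node centres.
#' @slot config the [SimulationConfig-class] used.
#'
#' @export
setClass("SimulatedDataset",
  representation(
    pre          = "array",
    post         = "array",
    samplingRate = "numeric",
    nodeWeights  = "matrix",
    nodeIndex    = "integer",
    config       = "SimulationConfig"
  )
)

setMethod("nEpochs", "SimulatedDataset", function(x) dim(x@post)[1L])
setMethod("nSensors", "SimulatedDataset", function(x) dim(x@post)[2L])

setMethod("show", "SimulatedDataset", function(object) {
  d <- dim(object@post)
  cat(sprintf(
    "SimulatedDataset: %d epochs x %d sensors x %d samples (pre & post), fs %g Hz\n",
    d[1L], d[2L], d[3L], object@samplingRate))
  cat(sprintf("  node centres at grid indices %d and %d\n",
              object@nodeIndex[1L], object@nodeIndex[2L]))
})
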