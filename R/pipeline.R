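# polynomial rolling hash of a character string (provenance fingerprints
# without external dependencies; exact in double arithmetic)
strHash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

configHash <- function(config) {
  fields <- slotNames(class(config))
  s <- paste(vapply(fields, function(f)
    paste(f, paste(format(slot(config, f), digits = 17), collapse = ","),
          sep = "="), ""), collapse = ";")
  strHash(s)
}

#' Save / load a simulated dataset container
#'
#' Writes the epoched arrays as an RDS payload plus a JSON provenance file
#' (configuration hash, seed, sampling rate, dimensions, package version),
#' so a dataset can be regenerated or verified later.
#'
#' @param dataset a [SimulatedDataset-class].
#' @param path directory to write.
#' @return `saveDataset` returns `path` invisibly; `loadDataset` the
#'   [SimulatedDataset-class].
#' @export
saveDataset <- function(dataset, path) {
  stopifnot(is(dataset, "SimulatedDataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  prov <- list(container = "dataset", version = 1L,
               config_hash = configHash(dataset@config),
               seed = dataset@config@seed,
               sampling_rate = dataset@samplingRate,
               n_epochs = dim(dataset@post)[1L],
               n_sensors = dim(dataset@post)[2L],
               n_time = dim(dataset@post)[3L],
               package_version = as.character(utils::packageVersion("nzplDICS")))
  jsonlite::write_json(prov, file.path(path, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(dataset, file.path(path, "dataset.rds"))
  invisible(path)
}

#' @rdname saveDataset
#' @export
loadDataset <- function(path) {
  f <- file.path(path, "dataset.rds")
  if (!file.exists(f)) stop("no dataset.rds in ", path)
  ds <- readRDS(f)
  stopifnot(is(ds, "SimulatedDataset"))
  ds
}

#' Per-period sensor CSDs of an epoched dataset
#'
#' Fourier-transforms the pre- and post-stimulus epochs and estimates the
#' requested CSD kind over the band of interest.
#'
#' @param dataset a [SimulatedDataset-class] (or any object with `pre`,
#'   `post` arrays and `samplingRate`).
#' @param band numeric `c(f_lo, f_hi)` Hz (default `c(25, 40)`).
#' @param kind `"full"`, `"nzpl"` or `"imaginary"`.
#' @return List with elements `pre` and `post` ([CSDMatrix-class]).
#' @export
datasetCsds <- function(dataset, band = c(25, 40),
                        kind = c("full", "nzpl", "imaginary")) {
  kind <- match.arg(kind)
  fs <- dataset@samplingRate
  if (band[length(band)] > fs / 2)
    stop("band upper edge ", band[length(band)],
         " Hz exceeds the Nyquist frequency ", fs / 2, " Hz")
  one <- function(x) {
    sp <- fftEpochs(x, fs)
    switch(kind,
      full = csdFromSamples(sp, band),
      nzpl = nzplCsd(sp, band),
      imaginary = imaginaryCsd(csdFromSamples(sp, band)))
  }
  list(pre = one(dataset@pre), post = one(dataset@post))
}

#' DICS noise-contrasted coherence map
#'
#' Builds spatial filters from the post-stimulus CSD (by default; filters
#' per period from each period's own CSD are selectable), reconstructs the
#' source coherence maps of both periods, and subtracts the pre-stimulus
#' map from the post-stimulus map.  The shared post-stimulus filter makes
#' the contrast sensitive to the correlated-source cancellation that
#' penalises the full-CSD method, which is the behaviour the method is
#' designed to expose.
#'
#' @param csds list with `pre` and `post` [CSDMatrix-class] objects (from
#'   [datasetCsds()]).
#' @param lead a [LeadField-class].
#' @param grid the [SourceGrid-class].
#' @param alpha relative regularisation (default `1e-6`).
#' @param ratioThreshold singular-value dominance ratio for [scalarise()].
#' @param orientation `"fixed"` (scalar filters along the grid normals, the
#'   simulation protocol) or `"free"` (3-component filters).
#' @param filterPeriod `"post"` (one filter from the post-stimulus CSD,
#'   default) or `"per-period"` (each period filtered with its own CSD).
#' @return List with `post`, `pre` and `contrast`
#'   ([ConnectivityMatrix-class]).
#' @export
dicsContrast <- function(csds, lead, grid, alpha = 1e-6,
                         ratioThreshold = 2,
                         orientation = c("fixed", "free"),
                         filterPeriod = c("post", "per-period")) {
  orientation <- match.arg(orientation)
  filterPeriod <- match.arg(filterPeriod)
  fPost <- makeFilters(lead, csds$post, alpha, orientation = orientation,
                       grid = grid)
  fPre <- if (filterPeriod == "post") fPost
          else makeFilters(lead, csds$pre, alpha, orientation = orientation,
                           grid = grid)
  post <- sourceCoherenceMap(fPost, csds$post, grid, ratioThreshold)
  pre <- sourceCoherenceMap(fPre, csds$pre, grid, ratioThreshold)
  list(post = post, pre = pre, contrast = noiseContrast(post, pre))
}

#' End-to-end network reconstruction and scoring
#'
#' Runs the full analysis on a simulated dataset: CSD estimation of the
#' requested kind, DICS filtering and pairwise coherence reconstruction,
#' pre/post noise contrast, and log-ROC scoring against the Gaussian truth.
#'
#' @param dataset a [SimulatedDataset-class].
#' @param lead,grid forward model of the dataset's grid.
#' @param kind `"full"` or `"nzpl"`.
#' @param band frequency band in Hz.
#' @param alpha relative regularisation.
#' @param ratioThreshold scalarisation dominance ratio.
#' @param truthCut binarisation cut for the smoothed truth.
#' @param nThresholds ROC thresholds.
#' @param fprFloor FPR clamp (default `1/n_scored`).
#' @param orientation filter orientation mode (see [dicsContrast()]).
#' @param filterPeriod filter period convention (see [dicsContrast()]).
#' @return List with `auc`, `roc`, `contrast`, `truth`.
#' @export
reconstructNetwork <- function(dataset, lead, grid,
                               kind = c("nzpl", "full"),
                               band = c(25, 40), alpha = 1e-6,
                               ratioThreshold = 2, truthCut = 0.5,
                               nThresholds = 120L, fprFloor = NULL,
                               orientation = c("fixed", "free"),
                               filterPeriod = c("post", "per-period")) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  filterPeriod <- match.arg(filterPeriod)
  csds <- datasetCsds(dataset, band, kind)
  maps <- dicsContrast(csds, lead, grid, alpha, ratioThreshold, orientation,
                       filterPeriod)
  truth <- trueConnectionMatrix(grid, dataset@nodeWeights[, 1L],
                                dataset@nodeWeights[, 2L])
  roc <- logRoc(maps$contrast, binariseTruth(truth, truthCut),
                nThresholds, fprFloor)
  list(auc = logRocAuc(roc), roc = roc, contrast = maps$contrast,
       truth = truth)
}

#' Sensor-level phase-lag tolerance sweep
#'
#' Quantifies how much coherence the NZPL estimator retains as the phase
#' lag and the SNP shrink: two equal-amplitude sinusoids with the given
#' (fixed by default) lag are mixed with independent white noise under the
#' SNP rule over the epoch protocol, and the coherence between the two
#' channels is estimated at the oscillation frequency from the NZPL CSD or
#' as the magnitude of the imaginary coherency.  Since the full coherence
#' of the noiseless pair is 1, the estimate measures the retained fraction.
#'
#' @param snpValues,lagValues numeric grids (SNP in `[0, 1]`, lags in
#'   radians).
#' @param estimator `"nzpl"` or `"imaginary"`.
#' @param nEpochs epochs per cell (default 100).
#' @param freq oscillation frequency Hz (default 33).
#' @param samplingRate Hz (default 1000).
#' @param epochMs epoch length ms (default 1000).
#' @param lagFwhm von Mises jitter FWHM of the per-epoch lags (default 0:
#'   the lag is the manipulated variable).
#' @param seed integer seed.
#' @return Data frame with columns `snp`, `lag`, `coherence`.
#' @export
phaseSweep <- function(snpValues, lagValues,
                       estimator = c("nzpl", "imaginary"),
                       nEpochs = 100L, freq = 33, samplingRate = 1000,
                       epochMs = 1000, lagFwhm = 0, seed = 1L) {
  estimator <- match.arg(estimator)
  nt <- round(epochMs / 1000 * samplingRate)
  tt <- (seq_len(nt) - 1L) / samplingRate
  grid <- expand.grid(snp = snpValues, lag = lagValues)
  grid$coherence <- NA_real_
  withSeed(seed, {
    for (i in seq_len(nrow(grid))) {
      snp <- grid$snp[i]
      lags <- samplePhaseLags(grid$lag[i], lagFwhm, nEpochs)
      x <- array(0, c(nEpochs, 2L, nt))
      for (e in seq_len(nEpochs)) {
        phase <- runif(1L, 0, 2 * pi)
        s1 <- sin(2 * pi * freq * tt + phase)
        s2 <- sin(2 * pi * freq * tt + phase + lags[e])
        x[e, 1L, ] <- mixSnp(s1, rnorm(nt), snp)
        x[e, 2L, ] <- mixSnp(s2, rnorm(nt), snp)
      }
      sp <- fftEpochs(x, samplingRate)
      grid$coherence[i] <- if (estimator == "nzpl") {
        nz <- nzplCsd(sp, freq)
        suppressWarnings(nzplCoherence(nz)[1L, 2L])
      } else {
        abs(Im(coherency(csdFromSamples(sp, freq))))[1L, 2L]
      }
    }
  })
  grid
}

#' Evaluate a reconstruction container and write a report
#'
#' Scores a reconstruction against a truth matrix and writes the ROC table
#' (CSV) and a JSON report with the AUC and the critical AUC.
#'
#' @param contrast a [ConnectivityMatrix-class] reconstruction.
#' @param truth a [ConnectivityMatrix-class] smoothed truth.
#' @param outDir output directory (`NULL`: nothing written).
#' @param truthCut,nThresholds,fprFloor scoring parameters as in
#'   [reconstructNetwork()].
#' @return List with `auc`, `criticalAuc`, `roc` (invisible when writing).
#' @export
evaluateReconstruction <- function(contrast, truth, outDir = NULL,
                                   truthCut = 0.5, nThresholds = 120L,
                                   fprFloor = NULL) {
  roc <- logRoc(contrast, binariseTruth(truth, truthCut), nThresholds,
                fprFloor)
  res <- list(auc = logRocAuc(roc), criticalAuc = criticalAuc(), roc = roc)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(data.frame(threshold = roc@thresholds, tpr = roc@tpr,
                         fpr = roc@fpr, log_fpr = roc@logFpr),
              file.path(outDir, "roc.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(auc = res$auc, critical_auc = res$criticalAuc,
           n_positive = roc@nPositive, n_negative = roc@nNegative,
           fpr_floor = roc@fprFloor),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}
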