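#' Save / load a lead field as a plain-text container
#'
#' A lead field is written as a directory holding `meta.json` (modality,
#' reference, dimensions), `sensors.csv` (positions and orientations) and
#' `gains.csv` (long-format gains at full double precision).  The round trip
#' is bitwise exact.
#'
#' @param lead a [LeadField-class].
#' @param path directory to write to (created if missing).
#' @return `saveLeadField` returns `path` invisibly; `loadLeadField` returns
#'   the [LeadField-class].
#' @export
saveLeadField <- function(lead, path) {
  stopifnot(is(lead, "LeadField"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(lead@gains)
  meta <- list(container = "leadfield", version = 1L,
               modality = lead@modality, reference = lead@reference,
               n_sensors = d[1L], n_sources = d[2L], n_orientations = d[3L])
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  sens <- data.frame(
    px = fmt17(lead@sensorPositions[, 1L]),
    py = fmt17(lead@sensorPositions[, 2L]),
    pz = fmt17(lead@sensorPositions[, 3L]))
  if (nrow(lead@sensorOrientations) == nrow(lead@sensorPositions)) {
    sens$ox <- fmt17(lead@sensorOrientations[, 1L])
    sens$oy <- fmt17(lead@sensorOrientations[, 2L])
    sens$oz <- fmt17(lead@sensorOrientations[, 3L])
  }
  write.csv(sens, file.path(path, "sensors.csv"), row.names = FALSE,
            quote = FALSE)
  idx <- expand.grid(sensor = seq_len(d[1L]), source = seq_len(d[2L]),
                     orientation = seq_len(d[3L]))
  g <- data.frame(idx, value = fmt17(as.vector(lead@gains)))
  write.csv(g, file.path(path, "gains.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

fmt17 <- function(x) formatC(x, format = "g", digits = 17)

#' @rdname saveLeadField
#' @export
loadLeadField <- function(path) {
  metaFile <- file.path(path, "meta.json")
  if (!file.exists(metaFile)) stop("no meta.json in ", path)
  meta <- jsonlite::read_json(metaFile, simplifyVector = TRUE)
  if (!identical(meta$container, "leadfield"))
    stop("container at ", path, " is not a lead field")
  no <- meta$n_orientations
  if (is.null(no) || no != 3L)
    stop("lead-field container must declare 3 orientation components ",
         "(rank-3 gains); found ", if (is.null(no)) "none" else no)
  g <- read.csv(file.path(path, "gains.csv"))
  need <- meta$n_sensors * meta$n_sources * 3L
  if (nrow(g) != need)
    stop("gains.csv is truncated or inconsistent: ", nrow(g),
         " rows, expected ", need)
  gains <- array(0, c(meta$n_sensors, meta$n_sources, 3L))
  gains[cbind(g$sensor, g$source, g$orientation)] <- g$value
  sens <- read.csv(file.path(path, "sensors.csv"))
  if (nrow(sens) != meta$n_sensors)
    stop("sensors.csv has ", nrow(sens), " rows; meta declares ",
         meta$n_sensors, " sensors")
  spos <- as.matrix(sens[, c("px", "py", "pz")])
  dimnames(spos) <- NULL
  sori <- if (all(c("ox", "oy", "oz") %in% names(sens)))
    unname(as.matrix(sens[, c("ox", "oy", "oz")]))
  else matrix(0, 0L, 3L)
  new("LeadField", gains = gains, sensorPositions = spos,
      sensorOrientations = sori, modality = meta$modality,
      reference = meta$reference)
}
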