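#' Equal-area sensor layouts on a spherical cap
#'
#' Places `n` points quasi-uniformly (golden-angle spiral) on the upper cap
#' of a sphere, covering a fraction `coverage` of the full sphere area:
#' a synthetic stand-in for an EEG electrode cap or an MEG helmet.
#'
#' @param n number of sensors.
#' @param radius sphere radius in mm.
#' @param coverage fraction of the sphere's area covered from the top
#'   (0.5 = hemisphere).
#' @return Numeric `n x 3` matrix of positions (mm).
#' @export
capLayout <- function(n, radius, coverage = 0.65) {
  stopifnot(n >= 1, radius > 0, coverage > 0, coverage <= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * coverage * i / n          # cos(theta) from 1 downwards
  phi <- i * pi * (3 - sqrt(5))          # golden angle
  st <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(st * cos(phi), st * sin(phi), z)
}

#' @describeIn capLayout 64-electrode EEG layout on the scalp sphere
#'   (radius 100 mm).
#' @export
eegLayout64 <- function(n = 64L, radius = 100) capLayout(n, radius)

#' @describeIn capLayout 148-channel axial-gradiometer helmet layout
#'   (radius 120 mm); returns positions and radial coil orientations.
#' @export
megLayout148 <- function(n = 148L, radius = 120) {
  pos <- capLayout(n, radius, coverage = 0.6)
  list(positions = pos, orientations = pos / radius)
}

#' Regular source grid inside a spherical shell
#'
#' Builds a regular cubic grid of dipole positions restricted to a radial
#' shell of the head sphere (emulating superficial cortical grey matter) and
#' optionally truncated from below, with deterministic pseudo-random unit
#' normals (fixed-orientation mode) emulating the broad orientation
#' distribution of cortical columns on a convoluted surface.
#'
#' @param spacing grid spacing in mm.
#' @param rMin,rMax radial extent of the shell in mm.
#' @param zMin lowest z coordinate kept (mm), mimicking the cranial part of
#'   the head.
#' @param yMax largest y coordinate kept (mm); `Inf` keeps the whole shell,
#'   a finite value restricts the grid to a posterior region.
#' @param orientationSeed seed for the per-source normals (deterministic for
#'   a given geometry).
#' @return A [SourceGrid-class] in `fixed-normal` mode.
#' @export
sourceGridSphere <- function(spacing = 7.5, rMin = 45, rMax = 75,
                             zMin = -50, yMax = Inf,
                             orientationSeed = 7L) {
  stopifnot(spacing > 0, rMax > rMin)
  g <- seq(-rMax, rMax, by = spacing)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  r <- sqrt(rowSums(pts^2))
  keep <- r >= rMin & r <= rMax & pts[, 3L] >= zMin & pts[, 2L] <= yMax
  pts <- pts[keep, , drop = FALSE]
  nn <- withSeed(orientationSeed, {
    m <- matrix(rnorm(3L * nrow(pts)), ncol = 3L)
    m / sqrt(rowSums(m^2))
  })
  new("SourceGrid", positions = pts, orientationMode = "fixed-normal",
      normals = nn, spacing = spacing)
}
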