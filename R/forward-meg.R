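# Magnetic field (T) of a current dipole inside a homogeneous conducting
# sphere, at a point outside it (single-sphere analytic model; the volume
# currents are accounted for exactly, and a radially oriented dipole is
# magnetically silent).  r, r0 in metres, Q in A m.
sarvasField <- function(r, r0, Q) {
  mu0_4pi <- 1e-7
  a <- r - r0
  an <- sqrt(sum(a^2))
  rn <- sqrt(sum(r^2))
  if (an < 1e-12) stop("field point coincides with the dipole")
  F <- an * (rn * an + rn^2 - sum(r0 * r))
  gF <- (an^2 / rn + sum(a * r) / an + 2 * an + 2 * rn) * r -
        (an + 2 * rn + sum(a * r) / an) * r0
  Qxr0 <- c(Q[2L] * r0[3L] - Q[3L] * r0[2L],
            Q[3L] * r0[1L] - Q[1L] * r0[3L],
            Q[1L] * r0[2L] - Q[2L] * r0[1L])
  mu0_4pi / F^2 * (F * Qxr0 - sum(Qxr0 * r) * gF)
}

#' MEG lead field for the single-sphere model
#'
#' Magnetic fields of dipoles in a homogeneous conducting sphere
#' (quasi-static analytic solution including volume currents; radial dipoles
#' are silent).  Magnetometers measure the field component along their coil
#' orientation; axial gradiometers are modelled as two magnetometers
#' separated by `baseline` along the coil axis, differenced
#' (inner minus outer).  Gains are in fT per nA mm.
#'
#' @param grid a [SourceGrid-class]; positions must lie inside `radius`.
#' @param sensorPositions numeric `n_sens x 3` coil positions (mm), outside
#'   the sphere.
#' @param sensorOrientations numeric `n_sens x 3` unit coil orientations.
#' @param type `"magnetometer"` or `"axial-gradiometer"`.
#' @param baseline gradiometer baseline in mm (default 50).
#' @param radius conductor sphere radius in mm, for validation (default 87).
#' @return A [LeadField-class] with modality `"MEG"`.
#' @export
singleSphereMegLeadfield <- function(grid, sensorPositions,
                                     sensorOrientations,
                                     type = c("axial-gradiometer",
                                              "magnetometer"),
                                     baseline = 50,
                                     radius = 87) {
  type <- match.arg(type)
  stopifnot(is(grid, "SourceGrid"),
            ncol(sensorPositions) == 3L,
            all(dim(sensorOrientations) == dim(sensorPositions)))
  pos <- gridPositions(grid)
  b <- sqrt(rowSums(pos^2))
  if (any(b >= radius))
    stop("source(s) outside the conductor sphere (radius ", radius, " mm)")
  sn <- sqrt(rowSums(sensorPositions^2))
  if (any(sn <= radius))
    stop("sensor(s) ", paste(which(sn <= radius), collapse = ", "),
         " inside the conductor sphere")
  ori <- sensorOrientations / sqrt(rowSums(sensorOrientations^2))
  nsens <- nrow(sensorPositions); nsrc <- nrow(pos)
  gains <- array(0, c(nsens, nsrc, 3L))
  posm <- pos * 1e-3
  sensm <- sensorPositions * 1e-3
  basem <- baseline * 1e-3
  qunit <- 1e-12   # 1 nA mm in A m
  for (k in seq_len(nsrc)) {
    r0 <- posm[k, ]
    for (o in 1:3) {
      Q <- c(0, 0, 0); Q[o] <- qunit
      for (s in seq_len(nsens)) {
        B1 <- sarvasField(sensm[s, ], r0, Q)
        v <- sum(B1 * ori[s, ])
        if (type == "axial-gradiometer") {
          B2 <- sarvasField(sensm[s, ] + basem * ori[s, ], r0, Q)
          v <- v - sum(B2 * ori[s, ])
        }
        gains[s, k, o] <- v * 1e15   # T -> fT
      }
    }
  }
  new("LeadField", gains = gains, sensorPositions = sensorPositions,
      sensorOrientations = ori, modality = "MEG", reference = "none")
}
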