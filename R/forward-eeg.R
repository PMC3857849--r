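# Legendre polynomials P_n(c) and associated P_n^1(c) (positive convention,
# P_n^1 = sin(theta) dP_n/dc) for n = 1..N, vectorised over c.
legendreTables <- function(c, N) {
  s <- sqrt(pmax(0, 1 - c^2))
  P <- matrix(0, length(c), N)
  P1 <- matrix(0, length(c), N)
  Pm2 <- rep(1, length(c))   # P_0
  Pm1 <- c                   # P_1
  P[, 1L] <- Pm1
  P1m2 <- rep(0, length(c))  # P_0^1
  P1m1 <- s                  # P_1^1
  P1[, 1L] <- P1m1
  for (n in 2:N) {
    Pn <- ((2 * n - 1) * c * Pm1 - (n - 1) * Pm2) / n
    P[, n] <- Pn
    Pm2 <- Pm1; Pm1 <- Pn
    P1n <- ((2 * n - 1) * c * P1m1 - n * P1m2) / (n - 1)
    P1[, n] <- P1n
    P1m2 <- P1m1; P1m1 <- P1n
  }
  list(P = P, P1 = P1)
}

# Per-harmonic transfer factors tau_n for M concentric shells.
# Potential in shell j (normalised radius rho = r/R_outer):
#   V_j = A_j rho^n + B_j rho^-(n+1), with the dipole's exterior multipole
# carrying unit coefficient in the core.  Boundary conditions: continuity of
# V and of sigma dV/drho at every interface, zero radial current at the
# scalp.  tau_n is the surface potential for a unit core coefficient; for
# equal conductivities it reduces to (2n+1)/n.
sphereTransferFactors <- function(radii, conductivities, N) {
  M <- length(radii)
  stopifnot(length(conductivities) == M, all(diff(radii) > 0))
  rho <- radii / radii[M]
  if (M == 1L) return((2 * seq_len(N) + 1) / seq_len(N))
  # Scaled unknowns keep the system well conditioned at high n:
  # a_j = A_j rho_j^n, b_j = B_j rho_j^-(n+1), evaluated at each shell's
  # outer radius rho_j (rho_M = 1).
  tau <- numeric(N)
  nun <- 2L * M - 1L
  idxA <- function(j) if (j == 1L) 1L else 2L * j - 2L
  idxB <- function(j) 2L * j - 1L   # j >= 2
  for (n in seq_len(N)) {
    A <- matrix(0, nun, nun)
    rhs <- numeric(nun)
    row <- 0L
    for (j in seq_len(M - 1L)) {
      g <- rho[j] / rho[j + 1L]
      gup <- g^n; gdn <- g^(-(n + 1))
      src <- if (j == 1L) rho[1L]^(-(n + 1)) else 0   # core multipole
      # continuity of V at rho_j
      row <- row + 1L
      A[row, idxA(j)] <- 1
      if (j > 1L) A[row, idxB(j)] <- 1
      A[row, idxA(j + 1L)] <- -gup
      A[row, idxB(j + 1L)] <- -gdn
      rhs[row] <- -src
      # continuity of sigma dV/drho at rho_j (common 1/rho_j dropped)
      row <- row + 1L
      A[row, idxA(j)] <- conductivities[j] * n
      if (j > 1L) A[row, idxB(j)] <- -conductivities[j] * (n + 1)
      A[row, idxA(j + 1L)] <- -conductivities[j + 1L] * n * gup
      A[row, idxB(j + 1L)] <- conductivities[j + 1L] * (n + 1) * gdn
      rhs[row] <- conductivities[j] * (n + 1) * src
    }
    # insulating outer boundary at rho = 1
    row <- row + 1L
    A[row, idxA(M)] <- n
    A[row, idxB(M)] <- -(n + 1)
    sol <- solve(A, rhs)
    tau[n] <- sol[idxA(M)] + sol[idxB(M)]
  }
  tau
}

#' EEG lead field for a concentric-spheres head model
#'
#' Analytic scalp potentials of dipoles inside a set of concentric spherical
#' shells (brain, skull, scalp by default), computed from the spherical
#' harmonic series of the volume-conduction problem, truncated at `nTerms`.
#' Gains are in microvolts per nA mm of dipole moment, average-referenced
#' across electrodes.  Default conductivities are 33, 0.41 and 33 mS/m for
#' brain, skull and scalp.
#'
#' @param grid a [SourceGrid-class]; positions must lie strictly inside the
#'   innermost shell.
#' @param electrodes numeric `n_elec x 3` electrode positions (mm); they are
#'   projected radially onto the outer shell.
#' @param radii shell radii in mm, innermost first (default `c(87, 92, 100)`).
#' @param conductivities shell conductivities in S/m
#'   (default `c(0.033, 0.00041, 0.033)`).
#' @param nTerms series truncation order (default 80; the series decays as
#'   `(b/R)^n` with `b` the source depth).
#' @return A [LeadField-class] with modality `"EEG"` and average reference.
#' @export
sphericalEegLeadfield <- function(grid, electrodes,
                                  radii = c(87, 92, 100),
                                  conductivities = c(0.033, 0.00041, 0.033),
                                  nTerms = 80L) {
  stopifnot(is(grid, "SourceGrid"), ncol(electrodes) == 3L)
  pos <- gridPositions(grid)
  R <- radii[length(radii)]
  b <- sqrt(rowSums(pos^2))
  bad <- which(b >= radii[1L])
  if (length(bad))
    stop("source(s) ", paste(head(bad, 5L), collapse = ", "),
         " lie outside the innermost shell (radius ", radii[1L], " mm)")
  # electrodes radially projected onto the scalp
  enorm <- sqrt(rowSums(electrodes^2))
  if (any(enorm == 0)) stop("electrode at the sphere centre")
  elec <- electrodes * (R / enorm)
  ehat <- elec / R
  tau <- sphereTransferFactors(radii, conductivities, nTerms)
  nsens <- nrow(elec); nsrc <- nrow(pos)
  gains <- array(0, c(nsens, nsrc, 3L))
  nvec <- seq_len(nTerms)
  # SI scaling: mm -> m, 1 nA mm = 1e-12 A m, V -> microvolt
  Rm <- R * 1e-3
  scale <- 1e-12 / (4 * pi * conductivities[1L] * Rm^2) * 1e6
  for (k in seq_len(nsrc)) {
    bk <- b[k]
    if (bk < 1e-9) {
      zh <- c(0, 0, 1)
    } else zh <- pos[k, ] / bk
    # orthonormal tangent frame
    ref <- if (abs(zh[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    xh <- ref - sum(ref * zh) * zh
    xh <- xh / sqrt(sum(xh^2))
    yh <- c(zh[2L] * xh[3L] - zh[3L] * xh[2L],
            zh[3L] * xh[1L] - zh[1L] * xh[3L],
            zh[1L] * xh[2L] - zh[2L] * xh[1L])
    x <- bk / R
    xpow <- x^(nvec - 1L)   # 0^0 = 1 covers the central dipole
    ct <- as.vector(ehat %*% zh)
    ct <- pmin(1, pmax(-1, ct))
    leg <- legendreTables(ct, nTerms)
    radSeries <- as.vector(leg$P %*% (tau * nvec * xpow))
    tanSeries <- as.vector(leg$P1 %*% (tau * xpow))
    cphi <- as.vector(ehat %*% xh)
    sphi <- as.vector(ehat %*% yh)
    st <- sqrt(pmax(0, 1 - ct^2))
    az <- ifelse(st > 1e-12, atan2(sphi, cphi), 0)
    for (o in 1:3) {
      m <- c(0, 0, 0); m[o] <- 1
      mr <- sum(m * zh)
      mt <- m - mr * zh
      mtamp <- sqrt(sum(mt^2))
      phim <- if (mtamp > 1e-12) atan2(sum(mt * yh), sum(mt * xh)) else 0
      v <- scale * (mr * radSeries + mtamp * tanSeries * cos(az - phim))
      gains[, k, o] <- v - mean(v)  # average reference
    }
  }
  new("LeadField", gains = gains, sensorPositions = elec,
      sensorOrientations = matrix(0, 0L, 3L), modality = "EEG",
      reference = "average")
}
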