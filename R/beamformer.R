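#' Tikhonov-regularise a sensor CSD
#'
#' Returns \eqn{C + \gamma I} with \eqn{\gamma = \alpha \|C\|}: the absolute
#' regularisation is a multiple of the norm of the sensor CSD.  The norm is
#' the spectral (largest-singular-value) norm by default, so an identity CSD
#' with `alpha = 1` becomes exactly `2 I`; the Frobenius norm is selectable.
#'
#' @param csd a [CSDMatrix-class] or a square complex matrix.
#' @param alpha relative regularisation, `>= 0`.
#' @param norm `"spectral"` (default) or `"frobenius"`.
#' @return Complex matrix with attribute `"gamma"` (the shift applied).
#' @export
regulariseCsd <- function(csd, alpha, norm = c("spectral", "frobenius")) {
  norm <- match.arg(norm)
  v <- if (is(csd, "CSDMatrix")) csdValues(csd) else csd
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("alpha must be a single non-negative number")
  nrm <- if (norm == "spectral") spectralNorm(v) else sqrt(sum(Mod(v)^2))
  gamma <- alpha * nrm
  out <- v + diag(gamma + 0i, nrow(v))
  attr(out, "gamma") <- gamma
  out
}

#' Spatial filter for a single source
#'
#' The linearly-constrained minimum-variance solution
#' \eqn{W_k = (L_k^{H} C_r^{-1} L_k)^{-1} L_k^{H} C_r^{-1}}: among all
#' weight matrices with unit gain (`W L = I`), it minimises the filtered
#' power `tr(W C_r W^H)`.
#'
#' @param leadK numeric `n_sensors x 3` gains of the target source.
#' @param csdInv inverse of the regularised sensor CSD.
#' @return Complex `3 x n_sensors` weight matrix.
#' @keywords internal
filterForSource <- function(leadK, csdInv) {
  lh <- Conj(t(leadK)) %*% csdInv              # 3 x n_sens
  m <- lh %*% leadK                            # 3 x 3
  solve(m, lh)
}

#' DICS spatial filters for every source
#'
#' Builds one `3 x n_sensors` unit-gain minimum-variance filter per source
#' from a (full or NZPL) sensor CSD regularised with [regulariseCsd()].
#' When the regularised CSD is close to singular (condition number above
#' `1e12`) a pseudo-inverse with relative cutoff `1e-12` is used and a
#' warning logged; a numerically zero CSD (e.g. the NZPL CSD of zero-lag
#' data) is rejected with advice to increase `alpha`.
#'
#' With `orientation = "fixed"` the lead field is collapsed onto the grid's
#' fixed dipole normals and the filters are scalar (`1 x n_sensors`): the
#' protocol matching simulations whose dipole orientations are known.  With
#' `orientation = "free"` the full `n_sensors x 3` lead field is used and
#' filters are `3 x n_sensors`.
#'
#' @param lead a [LeadField-class].
#' @param csd a [CSDMatrix-class] of kind `"full"` or `"nzpl"`.
#' @param alpha relative regularisation (default `1e-6`).
#' @param norm norm convention passed to [regulariseCsd()].
#' @param orientation `"fixed"` (scalar filters along the grid normals;
#'   requires `grid`) or `"free"` (3-component filters).
#' @param grid the [SourceGrid-class] supplying fixed normals.
#' @return A [SpatialFilterSet-class].
#' @export
makeFilters <- function(lead, csd, alpha = 1e-6,
                        norm = c("spectral", "frobenius"),
                        orientation = c("free", "fixed"), grid = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(is(lead, "LeadField"), is(csd, "CSDMatrix"))
  if (!csd@kind %in% c("full", "nzpl"))
    stop("filters are built from 'full' or 'nzpl' CSDs")
  v <- csdValues(csd)
  if (nrow(v) != nSensors(lead))
    stop("CSD has ", nrow(v), " sensors; lead field has ", nSensors(lead))
  if (spectralNorm(v) < .Machine$double.xmin)
    stop("sensor CSD is numerically zero (no phase-lagged signal?); ",
         "cannot build a spatial filter - consider a larger alpha or the ",
         "full CSD")
  cr <- regulariseCsd(csd, alpha, norm)
  gamma <- attr(cr, "gamma")
  cond <- conditionNumber(cr)
  ci <- if (is.finite(cond) && cond <= 1e12) solve(cr) else {
    warning(sprintf(
      "regularised CSD is ill-conditioned (cond = %.3g); using a ",
      cond), "pseudo-inverse - consider a larger alpha")
    pinvCutoff(cr)
  }
  g <- lfGains(lead)
  nsrc <- dim(g)[2L]
  if (orientation == "fixed") {
    if (is.null(grid))
      stop("fixed-orientation filters need the source grid for its normals")
    G <- collapseGains(lead, grid)
    w <- array(0i, c(1L, nSensors(lead), nsrc))
    for (k in seq_len(nsrc))
      w[1L, , k] <- filterForSource(matrix(G[, k], ncol = 1L), ci)
  } else {
    w <- array(0i, c(3L, nSensors(lead), nsrc))
    for (k in seq_len(nsrc))
      w[, , k] <- filterForSource(g[, k, ], ci)
  }
  new("SpatialFilterSet", weights = w, alpha = alpha, gamma = gamma,
      csdKind = csd@kind, orientation = orientation, condition = cond)
}

#' Reconstructed source-pair CSD
#'
#' Projects a sensor CSD through two spatial filters:
#' \eqn{C_{kl} = W_k C W_l^{H}}, a `3 x 3` complex matrix between the
#' Cartesian components of sources `k` and `l`.
#'
#' @param filterK,filterL complex `3 x n_sensors` filter weights.
#' @param csd a [CSDMatrix-class] or square complex matrix.
#' @return Complex `3 x 3` matrix.
#' @export
reconstructPairCsd <- function(filterK, filterL, csd) {
  v <- if (is(csd, "CSDMatrix")) csdValues(csd) else csd
  if (ncol(filterK) != nrow(v) || ncol(filterL) != nrow(v))
    stop("filter and CSD sensor dimensions disagree")
  filterK %*% v %*% Conj(t(filterL))
}

#' Scalar amplitude of a reconstructed pair CSD
#'
#' The largest singular value of the `3 x 3` pair CSD when it clearly
#' dominates (ratio to the second singular value at least
#' `ratioThreshold`), otherwise the modulus of the trace.
#'
#' @param sourceCsd complex `3 x 3` matrix.
#' @param ratioThreshold dominance ratio (default 2).
#' @return Non-negative scalar.
#' @export
scalarise <- function(sourceCsd, ratioThreshold = 2) {
  stopifnot(all(dim(sourceCsd) == c(3L, 3L)), ratioThreshold > 1)
  d <- svd(sourceCsd, nu = 0, nv = 0)$d
  if (d[1L] == 0) return(0)
  if (d[2L] == 0 || d[1L] / d[2L] >= ratioThreshold) d[1L]
  else Mod(sum(diag(sourceCsd)))
}

# Eigenvalues of many Hermitian psd 3x3 matrices at once (analytic cubic).
# Entries are n x n matrices (h11,h22,h33 real; h12,h13,h23 complex upper
# triangle).  Returns list(e1, e2, e3) in decreasing order.
eigHerm3Array <- function(h11, h22, h33, h12, h13, h23) {
  q <- (h11 + h22 + h33) / 3
  p1 <- Mod(h12)^2 + Mod(h13)^2 + Mod(h23)^2
  p2 <- (h11 - q)^2 + (h22 - q)^2 + (h33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  a <- h11 - q; b <- h22 - q; cc <- h33 - q
  detB <- a * b * cc - a * Mod(h23)^2 - b * Mod(h13)^2 - cc * Mod(h12)^2 +
    2 * Re(h12 * h23 * Conj(h13))
  ok <- p > 0
  r <- ifelse(ok, detB / pmax(p, .Machine$double.xmin)^3 / 2, 0)
  r <- pmin(1, pmax(-1, r))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[!ok] <- q[!ok]; e2[!ok] <- q[!ok]; e3[!ok] <- q[!ok]
  list(e1 = e1, e2 = e2, e3 = e3)
}

#' Source-by-source coherence map
#'
#' Reconstructs the pair CSD `W_k C W_l^H` for every source pair, reduces
#' each to a scalar amplitude (directly for fixed-orientation scalar
#' filters, via [scalarise()] for free-orientation `3 x 3` blocks), and
#' normalises the cross amplitudes by the auto amplitudes in the standard
#' coherency form \eqn{|C_{kl}| / \sqrt{C_{kk} C_{ll}}}.  Pairs with zero
#' reconstructed auto-power become `NaN` sentinels; the diagonal is 1 by
#' convention.  Values are not clamped: a map reconstructed from an NZPL
#' CSD deliberately overestimates phase-lagged interactions and can exceed
#' 1 at genuinely interacting pairs.
#'
#' @param filters a [SpatialFilterSet-class].
#' @param csd the [CSDMatrix-class] to project (same kind as the filters,
#'   or any sensor CSD).
#' @param grid the [SourceGrid-class] the filters belong to.
#' @param ratioThreshold singular-value dominance ratio for [scalarise()].
#' @return A [ConnectivityMatrix-class] of kind `"coherence"`.
#' @export
sourceCoherenceMap <- function(filters, csd, grid, ratioThreshold = 2) {
  stopifnot(is(filters, "SpatialFilterSet"), is(csd, "CSDMatrix"),
            is(grid, "SourceGrid"))
  nsens <- nSensors(filters)
  if (nsens != nSensors(csd))
    stop("filters and CSD sensor dimensions disagree")
  nsrc <- nSources(filters)
  if (nsrc != nSources(grid))
    stop("filters and grid disagree on the number of sources")
  v <- csdValues(csd)
  if (filters@orientation == "fixed") {
    W <- t(matrix(filters@weights, nSensors(filters), nsrc))  # nsrc x nsens
    S <- Mod(W %*% v %*% Conj(t(W)))
    auto <- diag(S)
    bad <- !(auto > 0) | !is.finite(auto)
    auto[bad] <- NaN
    coh <- S / sqrt(outer(auto, auto))
    coh <- (coh + t(coh)) / 2
    diag(coh) <- ifelse(bad, NaN, 1)
    return(new("ConnectivityMatrix", values = coh, grid = grid,
               kind = "coherence"))
  }
  wall <- matrix(aperm(filters@weights, c(1L, 3L, 2L)), 3L * nsrc, nsens)
  z <- (wall %*% v) %*% Conj(t(wall))
  zarr <- array(z, c(3L, nsrc, 3L, nsrc))   # [a, k, b, l] = block(k,l)[a,b]
  # Gram matrices H = B^H B of every 3x3 block, as n x n entry matrices
  B <- lapply(1:3, function(a) lapply(1:3, function(b) zarr[a, , b, ]))
  if (nsrc == 1L)
    B <- lapply(B, function(row) lapply(row, function(x) matrix(x, 1L, 1L)))
  hc <- function(c1, c2) {
    Conj(B[[1L]][[c1]]) * B[[1L]][[c2]] +
    Conj(B[[2L]][[c1]]) * B[[2L]][[c2]] +
    Conj(B[[3L]][[c1]]) * B[[3L]][[c2]]
  }
  e <- eigHerm3Array(Re(hc(1L, 1L)), Re(hc(2L, 2L)), Re(hc(3L, 3L)),
                     hc(1L, 2L), hc(1L, 3L), hc(2L, 3L))
  s1 <- sqrt(pmax(e$e1, 0))
  s2 <- sqrt(pmax(e$e2, 0))
  tr <- Mod(B[[1L]][[1L]] + B[[2L]][[2L]] + B[[3L]][[3L]])
  useSv <- (s2 <= 0) | (s1 >= ratioThreshold * s2)
  S <- ifelse(useSv, s1, tr)
  auto <- diag(S)
  bad <- !(auto > 0) | !is.finite(auto)
  auto[bad] <- NaN
  coh <- S / sqrt(outer(auto, auto))
  coh <- (coh + t(coh)) / 2
  diag(coh) <- ifelse(bad, NaN, 1)
  new("ConnectivityMatrix", values = coh, grid = grid, kind = "coherence")
}

#' Noise contrast of two connectivity matrices
#'
#' Element-wise difference `post - pre`, removing systematic bias and
#' filter leakage by subtracting the pre-stimulus reconstruction from the
#' post-stimulus one.  `NaN` sentinels propagate.
#'
#' @param post,pre [ConnectivityMatrix-class] objects on the same grid.
#' @return A [ConnectivityMatrix-class] of kind `"noise-contrast"`.
#' @export
noiseContrast <- function(post, pre) {
  stopifnot(is(post, "ConnectivityMatrix"), is(pre, "ConnectivityMatrix"))
  if (!isTRUE(all.equal(gridPositions(post@grid), gridPositions(pre@grid))))
    stop("post and pre connectivity matrices are on different grids")
  new("ConnectivityMatrix", values = post@values - pre@values,
      grid = post@grid, kind = "noise-contrast")
}

#' Fisher-transform contrast of two coherence matrices
#'
#' `atanh(a) - atanh(b)` element-wise; coherences at or above 1 are clipped
#' to `1 - 1e-12` with a warning so the transform stays finite.
#'
#' @param a,b coherence-kind [ConnectivityMatrix-class] objects on the same
#'   grid.
#' @return A [ConnectivityMatrix-class] of kind `"fisher-contrast"`.
#' @export
fisherContrast <- function(a, b) {
  stopifnot(is(a, "ConnectivityMatrix"), is(b, "ConnectivityMatrix"))
  if (kindOf(a) != "coherence" || kindOf(b) != "coherence")
    stop("fisherContrast expects coherence-kind inputs")
  if (!isTRUE(all.equal(gridPositions(a@grid), gridPositions(b@grid))))
    stop("connectivity matrices are on different grids")
  clip <- function(v) {
    hi <- is.finite(v) & v >= 1
    if (any(hi)) {
      warning(sum(hi), " coherence value(s) >= 1 clipped before atanh")
      v[hi] <- 1 - 1e-12
    }
    v
  }
  new("ConnectivityMatrix",
      values = atanh(clip(a@values)) - atanh(clip(b@values)),
      grid = a@grid, kind = "fisher-contrast")
}

#' Export the strongest connections as an edge list
#'
#' Writes the top fraction `q` of finite upper-triangle pairs of a
#' connectivity matrix as a CSV edge list with grid coordinates.
#'
#' @param conn a [ConnectivityMatrix-class].
#' @param q fraction of pairs to keep (default 1e-4, i.e. the top 0.01%).
#' @param file output CSV path; `NULL` returns the data frame only.
#' @return Data frame with source indices, coordinates and values.
#' @export
exportTopPairs <- function(conn, q = 1e-4, file = NULL) {
  stopifnot(is(conn, "ConnectivityMatrix"), q > 0, q <= 1)
  v <- connValues(conn)
  ut <- which(upper.tri(v), arr.ind = TRUE)
  val <- v[ut]
  ok <- is.finite(val)
  ut <- ut[ok, , drop = FALSE]; val <- val[ok]
  keep <- val >= quantile(val, 1 - q)
  pos <- gridPositions(conn@grid)
  out <- data.frame(
    k = ut[keep, 1L], l = ut[keep, 2L],
    kx = pos[ut[keep, 1L], 1L], ky = pos[ut[keep, 1L], 2L],
    kz = pos[ut[keep, 1L], 3L],
    lx = pos[ut[keep, 2L], 1L], ly = pos[ut[keep, 2L], 2L],
    lz = pos[ut[keep, 2L], 3L],
    value = val[keep])
  out <- out[order(-out$value), ]
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
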