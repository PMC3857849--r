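# Shared fixtures, built once per test session (memoised in this env)

.fix <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

# small geometry for unit tests
smallGrid <- function() memo("smallGrid",
  sourceGridSphere(spacing = 20, rMin = 50, rMax = 70, zMin = 0))

smallEegLf <- function() memo("smallEegLf",
  sphericalEegLeadfield(smallGrid(), eegLayout64(16)))

# epoched two-channel sinusoid pair with a fixed lag, no noise
sinePairEpochs <- function(lag, nEpochs = 1L, fs = 200, freq = 33,
                           nt = 200L, amplitude = 1) {
  tt <- (seq_len(nt) - 1L) / fs
  x <- array(0, c(nEpochs, 2L, nt))
  for (e in seq_len(nEpochs)) {
    ph <- (e - 1L) * 0.7
    x[e, 1L, ] <- amplitude * cos(2 * pi * freq * tt + ph)
    x[e, 2L, ] <- amplitude * cos(2 * pi * freq * tt + ph - lag)
  }
  x
}

# closed-form surface potential of a dipole in a homogeneous sphere
# (radial + tangential components via generating-function identities);
# independent oracle for the truncated-series implementation
closedHomogPotential <- function(elec, r0, m, R, sigma) {
  b <- sqrt(sum(r0^2))
  zh <- if (b > 0) r0 / b else c(0, 0, 1)
  mr <- sum(m * zh)
  mt <- m - mr * zh
  mta <- sqrt(sum(mt^2))
  xh <- if (mta > 1e-12) mt / mta else {
    rr <- if (abs(zh[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    rr <- rr - sum(rr * zh) * zh
    rr / sqrt(sum(rr^2))
  }
  x <- b / R
  out <- numeric(nrow(elec))
  for (i in seq_len(nrow(elec))) {
    e <- elec[i, ] / sqrt(sum(elec[i, ]^2))
    ct <- sum(e * zh)
    st <- sqrt(max(0, 1 - ct^2))
    cphi <- if (st > 1e-12) sum(e * xh) / st else 1
    A <- 1 - 2 * x * ct + x^2
    radS <- if (x > 0) (2 * x * (ct - x) / A^1.5 + 1 / sqrt(A) - 1) / x
            else 2 * ct
    tanS <- if (x > 0)
      (2 * x * st / A^1.5 + ((x - ct) / sqrt(A) + ct) / st) / x
    else st * 0
    Rm <- R * 1e-3
    out[i] <- 1e-12 / (4 * pi * sigma * Rm^2) * 1e6 *
      (mr * radS + mta * tanS * cphi)
  }
  out - mean(out)
}

randomRotation <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
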