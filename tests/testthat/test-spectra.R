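test_that("epoch FFT concentrates a bin-aligned sinusoid and is linear", {
  x <- sinePairEpochs(lag = pi / 2)
  sp <- fftEpochs(x, 200)
  b33 <- which(sp@frequencies == 33)
  mags <- Mod(sp@coefficients[1, 1, ])
  expect_equal(mags[b33], 0.5, tolerance = 1e-10)
  expect_lt(max(mags[-b33]), 1e-10)
  # linearity
  sp2 <- fftEpochs(2 * x, 200)
  expect_equal(sp2@coefficients, 2 * sp@coefficients, tolerance = 1e-12)
  # phase difference of the two channels at 33 Hz is the imposed lag
  expect_equal(Arg(sp@coefficients[1, 1, b33] / sp@coefficients[1, 2, b33]),
               pi / 2, tolerance = 1e-8)
  # structural errors
  expect_error(fftEpochs(array(0, c(0, 2, 10)), 200), "empty")
  expect_error(fftEpochs(x, -1), "samplingRate")
})

test_that("CSD from samples matches the outer-product closed form", {
  # single sample p = (1, i): C = [[1, -i], [i, 1]]
  co <- array(0i, c(1, 2, 1))
  co[1, , 1] <- c(1 + 0i, 1i)
  sp <- new("SpectralSamples", coefficients = co, frequencies = 33,
            samplingRate = 200)
  C <- csdFromSamples(sp, 33)
  expect_equal(csdValues(C), rbind(c(1 + 0i, -1i), c(1i, 1 + 0i)),
               tolerance = 1e-12)
  # identical signal on two channels: coherency exactly 1
  x <- sinePairEpochs(lag = 0, nEpochs = 5)
  Cid <- csdFromSamples(fftEpochs(x, 200), 33)
  expect_equal(Mod(coherency(Cid)[1, 2]), 1, tolerance = 1e-10)
  # 100 epochs of unit sinusoids at fixed lag: off-diagonal is the
  # polar-form product r_i r_j (cos(lag) - i sin(lag)) with r = 1/2,
  # for lag defined as the phase deficit of channel 2
  lag <- 0.3 * pi
  C100 <- csdFromSamples(fftEpochs(sinePairEpochs(lag, 100), 200), 33)
  expect_equal(C100@values[2, 1], 0.25 * (cos(lag) - 1i * sin(lag)),
               tolerance = 1e-8)
  expect_equal(nEpochs(C100), 100L)
  expect_error(csdFromSamples(fftEpochs(x, 200), c(300, 400)), "band")
})

test_that("coherency is a unit-diagonal, bounded frequency-domain correlation", {
  C <- new("CSDMatrix", values = rbind(c(1 + 0i, -1i), c(1i, 1 + 0i)),
           band = c(33, 33), nEpochs = 1L, kind = "full")
  k <- coherency(C)
  expect_equal(k[1, 2], -1i)
  expect_equal(Im(k[1, 2]), -1)
  expect_equal(diag(k), c(1 + 0i, 1 + 0i))
  # diagonal-only CSD -> identity coherency
  D <- new("CSDMatrix", values = diag(c(2 + 0i, 3 + 0i)),
           band = c(33, 33), nEpochs = 1L, kind = "full")
  expect_equal(coherency(D), diag(2) + 0i)
  # zero auto-spectrum -> sentinel + warning
  Z <- new("CSDMatrix", values = diag(c(0i, 1 + 0i)), band = c(33, 33),
           nEpochs = 1L, kind = "full")
  expect_warning(kz <- coherency(Z), "zero auto-spectrum")
  expect_true(is.nan(Re(kz[1, 2])))
})

test_that("independent noise coherence shrinks with epoch count", {
  est <- function(ne, seed) {
    set.seed(seed)
    x <- array(rnorm(ne * 2 * 200), c(ne, 2, 200))
    mean(Mod(coherency(csdFromSamples(fftEpochs(x, 200), c(20, 80))))[1, 2])
  }
  c25 <- mean(sapply(1:5, function(s) est(25, s)))
  c100 <- mean(sapply(1:5, function(s) est(100, s + 50)))
  # 1/sqrt(n_e) trend: quadrupling epochs roughly halves |coherency|
  expect_lt(c100, c25)
  expect_gt(c25 / c100, 1.4)
})

test_that("rank-1 sample CSDs obey the eigen power identities", {
  set.seed(3)
  p <- complex(real = rnorm(5), imaginary = rnorm(5))
  S <- p %o% Conj(p)
  # full decomposition: one non-zero eigenvalue equal to the total power,
  # and the Hadamard-squared eigenvector times it gives per-channel power
  ef <- csdEigendecompose(S, "full")
  lam <- Mod(ef@values)
  expect_equal(max(lam), sum(Mod(p)^2), tolerance = 1e-10)
  expect_lt(sort(lam, decreasing = TRUE)[2] / max(lam), 1e-10)
  i1 <- which.max(lam)
  expect_equal(Mod(ef@vectors[, i1])^2 * lam[i1], Mod(p)^2,
               tolerance = 1e-8)
  # imaginary part: exactly two non-zero eigenvalues, a conjugate pair
  ei <- imagEigendecompose(S)
  lami <- ei@values[order(-Mod(ei@values))]
  expect_equal(lami[1], Conj(lami[2]), tolerance = 1e-10)
  expect_equal(lami[1] + lami[2], 0 + 0i, tolerance = 1e-10)
  expect_lt(Mod(lami[3]) / Mod(lami[1]), 1e-8)
  # eigenvalues of the traceless anti-symmetric part sum to zero
  expect_equal(sum(ei@values), 0 + 0i, tolerance = 1e-8)
  # reconstruction Q Lambda Q^-1
  M <- Im(S)
  rec <- ei@vectors %*% diag(ei@values) %*% solve(ei@vectors)
  expect_equal(Re(rec), M, tolerance = 1e-8)
  expect_error(csdEigendecompose(matrix(0i, 2, 3)), "square")
})

test_that("NZPL power matches the 2x2 closed form and annihilates zero lag", {
  r <- 1.7
  p <- c(r + 0i, r * exp(1i * pi / 2))
  ei <- imagEigendecompose(p %o% Conj(p))
  expect_equal(sort(Mod(ei@values), decreasing = TRUE)[1:2], c(r^2, r^2),
               tolerance = 1e-10)
  expect_equal(nzplPower(ei), c(r^2, r^2), tolerance = 1e-10)
  # zero-lag sample: all channels share one phase -> zero vector
  pz <- c(1, 2, 3) * exp(1i * 0.7)
  expect_equal(nzplPower(imagEigendecompose(pz %o% Conj(pz))),
               rep(0, 3), tolerance = 1e-6)
  # eigen route and the closed-form sample route agree on random samples
  set.seed(4)
  for (i in 1:10) {
    q <- complex(real = rnorm(6), imaginary = rnorm(6))
    expect_equal(nzplPower(imagEigendecompose(q %o% Conj(q))),
                 nzplDICS:::nzplPowerSample(q), tolerance = 1e-8)
  }
})

test_that("NZPL power interpolates from zero to full power with |sin(lag)|", {
  lags <- seq(0.1, pi - 0.1, length.out = 9)
  pw <- sapply(lags, function(lg) {
    p <- c(1 + 0i, exp(1i * lg))
    nzplDICS:::nzplPowerSample(p)[1]
  })
  expect_equal(pw, abs(sin(lags)), tolerance = 1e-8)
})

test_that("NZPL CSD: phase-lag invariance and zero-lag annihilation", {
  # pi/2 lag, unit amplitude: NZPL CSD equals the Hermitian completion of
  # the full CSD and NZPL coherence is 1
  sp <- fftEpochs(sinePairEpochs(pi / 2), 200)
  nz <- nzplCsd(sp, 33)
  expect_equal(csdValues(nz), 0.25 * rbind(c(1 + 0i, 1i), c(-1i, 1 + 0i)),
               tolerance = 1e-8)
  expect_equal(nzplCoherence(nz)[1, 2], 1, tolerance = 1e-8)
  # NZPL coherence is 1 for every fixed lag in (0, pi), while the
  # imaginary coherency magnitude is |sin(lag)|
  for (lg in c(0.1, 0.25 * pi, 0.5 * pi, 0.8 * pi)) {
    spl <- fftEpochs(sinePairEpochs(lg), 200)
    expect_equal(nzplCoherence(nzplCsd(spl, 33))[1, 2], 1,
                 tolerance = 1e-6)
    expect_equal(abs(Im(coherency(csdFromSamples(spl, 33))))[1, 2],
                 abs(sin(lg)), tolerance = 1e-6)
  }
  # zero-lag dataset: zero matrix, coherence flagged undefined
  spz <- fftEpochs(sinePairEpochs(0, 5), 200)
  nzz <- nzplCsd(spz, 33)
  expect_lt(max(Mod(csdValues(nzz))), 1e-8)
  expect_warning(cz <- nzplCoherence(nzz), "zero NZPL power")
  expect_true(is.nan(cz[1, 2]))
})

test_that("CSD containers satisfy their structural invariants", {
  set.seed(6)
  x <- array(rnorm(20 * 4 * 100), c(20, 4, 100))
  x[, 2, ] <- x[, 1, ] + 0.1 * x[, 2, ]   # correlated channels
  sp <- fftEpochs(x, 100)
  C <- csdFromSamples(sp, c(10, 40))
  v <- csdValues(C)
  scale <- max(Mod(v))
  expect_lt(max(Mod(v - Conj(t(v)))) / scale, 1e-10)
  expect_true(all(Re(diag(v)) >= 0))
  ic <- imaginaryCsd(C)
  vi <- csdValues(ic)
  # Im(C) is real anti-symmetric, so i*Im(C) is Hermitian with zero diagonal
  expect_lt(max(abs(Im(v) + t(Im(v)))) / scale, 1e-10)
  expect_lt(max(Mod(vi - Conj(t(vi)))) / scale, 1e-10)
  expect_equal(sum(Mod(diag(vi))), 0)
  expect_equal(Re(sum(diag(Im(csdValues(C))))), 0, tolerance = 1e-12)
  nz <- nzplCsd(sp, c(10, 40))
  vn <- csdValues(nz)
  expect_lt(max(Mod(vn - Conj(t(vn)))) / scale, 1e-10)
  expect_true(all(Re(diag(vn)) >= 0))
  # off-diagonal of the NZPL CSD is i Im of the full CSD
  expect_equal(vn - diag(diag(vn)), 1i * Im(v) - diag(1i * diag(Im(v))),
               tolerance = 1e-10 * scale)
})

test_that("Hann taper preserves the power scale of a bin-aligned tone", {
  x <- sinePairEpochs(pi / 3, nEpochs = 3)
  spN <- fftEpochs(x, 200, window = "none")
  spH <- fftEpochs(x, 200, window = "hann")
  # tapering smears the tone across bins but keeps band power comparable
  pN <- sum(Mod(spN@coefficients[1, 1, ])^2)
  pH <- sum(Mod(spH@coefficients[1, 1, ])^2)
  expect_equal(pH / pN, 1, tolerance = 0.1)
})
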