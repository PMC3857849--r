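randHermPsd <- function(n, seed) {
  set.seed(seed)
  X <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
  X %*% Conj(t(X)) / n
}

test_that("Tikhonov regularisation shifts the spectrum by alpha * norm", {
  C <- randHermPsd(6, 1)
  expect_equal(regulariseCsd(C, 0), C, ignore_attr = TRUE)
  # identity CSD with alpha 1 under the spectral norm: exactly 2 I
  I6 <- diag(6) + 0i
  expect_equal(regulariseCsd(I6, 1), 2 * I6, ignore_attr = TRUE)
  # every eigenvalue shifted by exactly gamma
  cr <- regulariseCsd(C, 1e-6)
  gamma <- attr(cr, "gamma")
  expect_equal(gamma, 1e-6 * max(eigen(C, only.values = TRUE)$values))
  expect_equal(Re(eigen(cr, only.values = TRUE)$values),
               Re(eigen(C, only.values = TRUE)$values) + gamma,
               tolerance = 1e-10)
  expect_error(regulariseCsd(C, -1), "alpha")
})

test_that("the unit-gain minimum-variance filter matches a brute-force optimiser", {
  ns <- 6
  C <- randHermPsd(ns, 2)
  set.seed(2)
  L <- matrix(rnorm(ns * 3), ns)
  W <- nzplDICS:::filterForSource(L, solve(C))
  expect_lt(max(Mod(W %*% L - diag(3))), 1e-10)
  # brute force over the unit-gain feasible set W = W0 + K P
  P <- diag(ns) - L %*% solve(t(L) %*% L) %*% t(L)
  W0 <- solve(t(L) %*% L) %*% t(L)
  obj <- function(par) {
    K <- matrix(complex(real = par[1:18], imaginary = par[19:36]), 3)
    Wc <- W0 + K %*% P
    Re(sum(diag(Wc %*% C %*% Conj(t(Wc)))))
  }
  o <- optim(rep(0, 36), obj, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  K <- matrix(complex(real = o$par[1:18], imaginary = o$par[19:36]), 3)
  expect_lt(max(Mod(W0 + K %*% P - W)), 1e-6)
  expect_equal(Re(sum(diag(W %*% C %*% Conj(t(W))))), o$value,
               tolerance = 1e-8)
  # trivial geometry: L = I with any invertible C forces W = I
  C3 <- randHermPsd(3, 3)
  expect_equal(nzplDICS:::filterForSource(diag(3), solve(C3)),
               diag(3) + 0i, tolerance = 1e-10)
})

test_that("filter sets satisfy unit gain for full and NZPL CSDs", {
  grid <- smallGrid()
  lf <- smallEegLf()
  set.seed(4)
  x <- array(rnorm(20 * 16 * 100), c(20, 16, 100))
  sp <- fftEpochs(x, 100)
  for (mk in list(csdFromSamples(sp, c(10, 40)), nzplCsd(sp, c(10, 40)))) {
    f <- makeFilters(lf, mk, 1e-6)
    for (k in c(1, nSources(grid)))
      expect_lt(max(Mod(filterWeights(f, k) %*% lfGains(lf)[, k, ] -
                          diag(3))), 1e-6)
  }
  # fixed-orientation filters: unit gain on the collapsed gains
  fF <- makeFilters(lf, csdFromSamples(sp, c(10, 40)), 1e-6,
                    orientation = "fixed", grid = grid)
  G <- nzplDICS:::collapseGains(lf, grid)
  for (k in c(1, nSources(grid)))
    expect_equal(Re(sum(filterWeights(fF, k) * G[, k])), 1,
                 tolerance = 1e-8)
})

test_that("the NZPL CSD of zero-lag data cannot drive a filter", {
  x <- sinePairEpochs(0, nEpochs = 4)
  sp <- fftEpochs(x, 200)
  nz <- nzplCsd(sp, 33)
  lf2 <- new("LeadField", gains = array(rnorm(2 * 1 * 3), c(2, 1, 3)),
             sensorPositions = matrix(rnorm(6), 2),
             sensorOrientations = matrix(0, 0, 3),
             modality = "EEG", reference = "average")
  expect_error(makeFilters(lf2, nz, 1e-6), "numerically zero")
})

test_that("pair CSD reconstruction and scalarisation follow their algebra", {
  C <- randHermPsd(8, 5)
  csd <- new("CSDMatrix", values = C, band = c(25, 40), nEpochs = 10L,
             kind = "full")
  set.seed(5)
  Wk <- matrix(complex(real = rnorm(24), imaginary = rnorm(24)), 3)
  Wl <- matrix(complex(real = rnorm(24), imaginary = rnorm(24)), 3)
  blk <- reconstructPairCsd(Wk, Wl, csd)
  expect_equal(blk, Wk %*% C %*% Conj(t(Wl)), tolerance = 1e-12)
  # self-pair: Hermitian with non-negative real diagonal
  auto <- reconstructPairCsd(Wk, Wk, csd)
  expect_lt(max(Mod(auto - Conj(t(auto)))), 1e-10 * max(Mod(auto)))
  expect_true(all(Re(diag(auto)) >= 0))
  expect_error(reconstructPairCsd(Wk[, 1:5], Wl, csd), "dimensions")
  # scalarise: rank-1 -> product of norms; identity -> trace fallback
  u <- complex(real = rnorm(3), imaginary = rnorm(3))
  v <- complex(real = rnorm(3), imaginary = rnorm(3))
  expect_equal(scalarise(u %o% Conj(v)),
               sqrt(sum(Mod(u)^2) * sum(Mod(v)^2)), tolerance = 1e-10)
  expect_equal(scalarise(diag(3) + 0i, ratioThreshold = 2), 3)
  for (i in 1:5) {
    M <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3)
    d <- svd(M)$d
    expected <- if (d[1] / d[2] >= 2) d[1] else Mod(sum(diag(M)))
    expect_equal(scalarise(M), expected, tolerance = 1e-10)
  }
})

test_that("free-orientation coherence maps match a direct per-pair loop", {
  grid <- smallGrid()
  lf <- smallEegLf()
  set.seed(7)
  X <- matrix(complex(real = rnorm(16 * 16), imaginary = rnorm(16 * 16)), 16)
  Cn <- 1i * Im(X - t(X)) / 2
  diag(Cn) <- abs(rnorm(16))
  csd <- new("CSDMatrix", values = Cn, band = c(33, 33), nEpochs = 10L,
             kind = "nzpl")
  f <- makeFilters(lf, csd, 1e-6)
  mp <- sourceCoherenceMap(f, csd, grid)
  nsrc <- nSources(grid)
  S <- matrix(0, nsrc, nsrc)
  for (k in seq_len(nsrc)) for (l in seq_len(nsrc))
    S[k, l] <- scalarise(reconstructPairCsd(filterWeights(f, k),
                                            filterWeights(f, l), Cn))
  auto <- diag(S)
  coh <- S / sqrt(outer(auto, auto))
  coh <- (coh + t(coh)) / 2
  diag(coh) <- 1
  expect_equal(connValues(mp), coh, tolerance = 1e-10)
  expect_equal(diag(connValues(mp)), rep(1, nsrc))
})

test_that("coherence maps are equivariant under source permutation", {
  grid <- smallGrid()
  lf <- smallEegLf()
  C <- randHermPsd(16, 8)
  csd <- new("CSDMatrix", values = C, band = c(25, 40), nEpochs = 10L,
             kind = "full")
  f <- makeFilters(lf, csd, 1e-6, orientation = "fixed", grid = grid)
  mp <- sourceCoherenceMap(f, csd, grid)
  nsrc <- nSources(grid)
  set.seed(8)
  perm <- sample(nsrc)
  gridP <- new("SourceGrid", positions = gridPositions(grid)[perm, ],
               orientationMode = "fixed-normal",
               normals = gridNormals(grid)[perm, ], spacing = grid@spacing)
  lfP <- new("LeadField", gains = lfGains(lf)[, perm, , drop = FALSE],
             sensorPositions = lf@sensorPositions,
             sensorOrientations = lf@sensorOrientations,
             modality = "EEG", reference = "average")
  fP <- makeFilters(lfP, csd, 1e-6, orientation = "fixed", grid = gridP)
  mpP <- sourceCoherenceMap(fP, csd, gridP)
  expect_equal(connValues(mpP), connValues(mp)[perm, perm],
               tolerance = 1e-10)
})

test_that("full-CSD coherence maps stay within [0, 1]", {
  grid <- smallGrid()
  lf <- smallEegLf()
  C <- randHermPsd(16, 9)
  csd <- new("CSDMatrix", values = C, band = c(25, 40), nEpochs = 10L,
             kind = "full")
  f <- makeFilters(lf, csd, 1e-6, orientation = "fixed", grid = grid)
  v <- connValues(sourceCoherenceMap(f, csd, grid))
  expect_true(all(v >= -1e-10 & v <= 1 + 1e-8))
})

test_that("noise contrast subtracts element-wise and checks grids", {
  grid <- smallGrid()
  v <- matrix(runif(nSources(grid)^2), nSources(grid))
  v <- (v + t(v)) / 2; diag(v) <- 1
  a <- new("ConnectivityMatrix", values = v, grid = grid,
           kind = "coherence")
  b <- new("ConnectivityMatrix", values = v / 2, grid = grid,
           kind = "coherence")
  expect_equal(connValues(noiseContrast(a, a)),
               matrix(0, nSources(grid), nSources(grid)))
  expect_equal(connValues(noiseContrast(a, b)), v / 2)
  gridB <- sourceGridSphere(spacing = 25, rMin = 50, rMax = 70, zMin = 0)
  cB <- new("ConnectivityMatrix",
            values = diag(nSources(gridB)), grid = gridB,
            kind = "coherence")
  expect_error(noiseContrast(a, cB), "different grids")
})

test_that("Fisher contrast is atanh-based, clipped, and monotone", {
  grid <- smallGrid()
  n <- nSources(grid)
  mk <- function(val) {
    v <- matrix(val, n, n)
    new("ConnectivityMatrix", values = v, grid = grid, kind = "coherence")
  }
  fc <- fisherContrast(mk(0.5), mk(0))
  expect_equal(connValues(fc)[1, 2], atanh(0.5), tolerance = 1e-12)
  expect_equal(connValues(fisherContrast(mk(0.3), mk(0.3)))[1, 2], 0)
  # monotone in the first argument
  expect_gt(connValues(fisherContrast(mk(0.6), mk(0.2)))[1, 2],
            connValues(fisherContrast(mk(0.5), mk(0.2)))[1, 2])
  expect_warning(fisherContrast(mk(1), mk(0)), "clipped")
})

test_that("NZPL reconstruction suppresses higher-order echo artefacts", {
  # two lagged sources plus a zero-lag 'volume conduction echo' of the
  # first at a third location: the echo's pairings with the true sources
  # are 2nd/3rd-order artefacts which the filter must keep below the
  # true pair's coherence
  grid <- smallGrid()
  lf <- smallEegLf()
  G <- nzplDICS:::collapseGains(lf, grid)
  ks <- c(2, 9, 14)   # source 1, source 2, echo location
  fs <- 200; nt <- 200; ne <- 50
  tt <- (seq_len(nt) - 1) / fs
  set.seed(11)
  x <- array(0, c(ne, 16, nt))
  for (e in seq_len(ne)) {
    ph <- runif(1, 0, 2 * pi)
    s1 <- sin(2 * pi * 33 * tt + ph)
    s2 <- sin(2 * pi * 33 * tt + ph + pi / 2)
    act <- matrix(0, nSources(grid), nt)
    act[ks[1], ] <- s1
    act[ks[2], ] <- s2
    act[ks[3], ] <- 0.5 * s1          # instantaneous echo
    act <- act + 0.05 * matrix(rnorm(nSources(grid) * nt),
                               nSources(grid), nt)
    x[e, , ] <- G %*% act
  }
  sp <- fftEpochs(x, fs)
  nz <- nzplCsd(sp, 33)
  f <- makeFilters(lf, nz, 1e-6, orientation = "fixed", grid = grid)
  v <- connValues(sourceCoherenceMap(f, nz, grid))
  truePair <- v[ks[1], ks[2]]
  expect_gt(truePair, v[ks[1], ks[3]])
  expect_gt(truePair, v[ks[2], ks[3]])
})

test_that("top-pair export returns the strongest finite edges", {
  grid <- smallGrid()
  n <- nSources(grid)
  v <- matrix(0, n, n)
  v[1, 2] <- v[2, 1] <- 0.9
  v[3, 4] <- v[4, 3] <- 0.5
  diag(v) <- 1
  cm <- new("ConnectivityMatrix", values = v, grid = grid,
            kind = "coherence")
  top <- exportTopPairs(cm, q = 2 / choose(n, 2))
  expect_equal(top$value[1], 0.9)
  expect_equal(c(top$k[1], top$l[1]), c(1, 2))
  f <- tempfile(fileext = ".csv")
  exportTopPairs(cm, q = 0.01, file = f)
  expect_true(file.exists(f))
})
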