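# internal helpers

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. With seed = NULL the global stream is used.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Hermitian part of a complex matrix (guards against numerical drift)
hermitianise <- function(m) (m + Conj(t(m))) / 2

# largest singular value of a (complex) matrix
spectralNorm <- function(m) {
  if (all(Mod(m) == 0)) return(0)
  max(svd(m, nu = 0, nv = 0)$d)
}

# condition number from singular values, Inf when rank-deficient
conditionNumber <- function(m) {
  d <- svd(m, nu = 0, nv = 0)$d
  if (min(d) == 0) Inf else max(d) / min(d)
}

# Moore-Penrose pseudo-inverse with a relative cutoff
pinvCutoff <- function(m, rcut = 1e-12) {
  s <- svd(m)
  keep <- s$d > rcut * max(s$d)
  if (!any(keep)) stop("matrix is numerically zero; cannot invert")
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * Conj(t(s$u[, keep, drop = FALSE])))
}

# root-mean-square power of a series
seriesPower <- function(x) mean(x^2)

`%||%` <- function(a, b) if (is.null(a)) b else a
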