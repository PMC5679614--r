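# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementation.

# Static-dephasing integral evaluated directly on its original
# parameterization, (1/3) Int_0^1 (2+u) sqrt(1-u) (1 - J0(1.5 x u))/u^2 du,
# by adaptive quadrature (the package's quadrature path integrates a
# substituted form; its fast path uses a Gauss-Legendre lookup table).
fs_oracle <- function(x) {
  vapply(x, function(xi) {
    if (xi == 0) return(0)
    integrand <- function(u) {
      z <- 1.5 * xi * u
      omj <- ifelse(z < 1e-3, z^2 / 4 * (1 - z^2 / 16 * (1 - z^2 / 36)),
                    1 - besselJ(z, 0))
      (2 + u) * sqrt(1 - u) * omj / u^2
    }
    stats::integrate(integrand, 0, 1, rel.tol = 1e-11, abs.tol = 0,
                     subdivisions = 500L)$value / 3
  }, numeric(1))
}

# Brute-force Benjamini-Hochberg step-up: for each i, the minimum over
# j >= i (in sort order) of min(1, p_(j) * m / j) -- a direct transcription
# of the definition, quadratic in m.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(vapply(i:m, function(j) min(1, ps[j] * m / j), numeric(1)))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Residualize-then-correlate partial correlation built on lm() and
# cor.test(), independent of the package's qr-based path.
partial_cor_oracle <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    ct <- stats::cor.test(x, y)
    return(list(r = unname(ct$estimate), p = ct$p.value,
                df = unname(ct$parameter)))
  }
  d <- data.frame(x = x, y = y, as.data.frame(covariates))
  cv <- paste(colnames(as.data.frame(covariates)), collapse = " + ")
  rx <- stats::residuals(stats::lm(stats::as.formula(paste("x ~", cv)), d))
  ry <- stats::residuals(stats::lm(stats::as.formula(paste("y ~", cv)), d))
  r <- stats::cor(rx, ry)
  k <- ncol(as.matrix(covariates))
  df <- length(x) - k - 2
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df)
}

# Small fixed dataset exercising the partial-correlation paths.
partial_fixture <- function() {
  list(
    x = c(2.1, 3.4, 1.9, 4.8, 3.3, 5.1, 2.7, 4.0),
    y = c(1.0, 2.2, 1.5, 3.9, 2.0, 4.4, 1.1, 3.5),
    covariates = cbind(age = c(41, 55, 38, 62, 50, 66, 44, 58),
                       gender = c(0, 1, 0, 1, 0, 1, 1, 0)))
}

# A small noiseless phantom cached per session (building + fitting a
# phantom is the most expensive fixture).
noiseless_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_phantom(phantom_spec(seed = 101, snr = Inf,
                                          nav_amplitude = 0,
                                          b0_coef = c(const = 0)))
    cache
  }
})
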