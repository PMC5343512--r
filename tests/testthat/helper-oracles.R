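# Independent oracle for the AR(1)-error trend fit: exact Gaussian
# log-likelihood for each fixed phi via the full stationary covariance
# (Cholesky route), maximized over a phi grid. Deliberately a different
# computational path than the Prais-Winsten profile in the package.
grid_ml_oracle <- function(years, values, phis = seq(-0.95, 0.95, by = 0.01)) {
  n <- length(values)
  X <- cbind(1, years - mean(years))
  one <- function(phi) {
    S <- stats::toeplitz(phi^(0:(n - 1))) / (1 - phi^2)
    U <- chol(S)
    yw <- backsolve(U, values, transpose = TRUE)
    Xw <- backsolve(U, X, transpose = TRUE)
    beta <- qr.coef(qr(Xw), yw)
    r <- yw - Xw %*% beta
    s2 <- sum(r^2) / n
    list(ll = -n / 2 * log(2 * pi * s2) - n / 2 - sum(log(diag(U))),
         beta = beta)
  }
  fits <- lapply(phis, one)
  k <- which.max(vapply(fits, `[[`, numeric(1), "ll"))
  list(phi = phis[k], loglik = fits[[k]]$ll, beta = fits[[k]]$beta)
}

# annual series with a linear trend and stationary AR(1) noise
sim_ar1_series <- function(n, phi, sd_eps, omega, mu = 2, seed = 1) {
  set.seed(seed)
  N <- as.numeric(stats::filter(
    stats::rnorm(n, 0, sd_eps), phi, method = "recursive",
    init = stats::rnorm(1, 0, sd_eps / sqrt(1 - phi^2))))
  list(years = 1860 + seq_len(n), values = mu + omega * seq_len(n) + N)
}
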