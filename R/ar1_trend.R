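#' Linear trend with AR(1) errors by exact maximum likelihood
#'
#' Fits `Y_t = mu + omega * t + N_t`, with `N_t` a stationary first-order
#' autoregressive process (`N_t = phi * N_{t-1} + eps_t`), to an annual
#' series. Estimation maximizes the exact Gaussian likelihood: for each
#' candidate `phi` the model is solved by generalized least squares via the
#' Prais-Winsten transform (which whitens the stationary AR(1) covariance
#' exactly, including the first observation), the innovation variance is
#' concentrated out, and the profile likelihood is maximized over
#' `phi` in (-0.999, 0.999) — a coarse grid pass followed by golden-section
#' refinement guards against local optima; ties are broken toward smaller
#' `|phi|`.
#'
#' The time covariate is centered internally for conditioning; `omega` is
#' reported per calendar year and `mu` is the fitted level at the series
#' midpoint year. The slope standard error comes from the GLS covariance at
#' the fitted `phi`.
#'
#' @param years integer vector of calendar years.
#' @param values numeric vector, same length; missing pairs must be dropped
#'   beforehand (NAs are removed pairwise here, with the series treated as
#'   contiguous).
#' @return an object of class `trend_fit`: list with `mu`, `omega`, `phi`,
#'   `sigma_eps` (innovation s.d.), `omega_se`, `residuals` (estimated
#'   `N_t`), `loglik`, `n`, and a `degenerate` flag (constant or exactly
#'   collinear input).
#' @export
fit_ar1_gls <- function(years, values) {
  keep <- !(is.na(values) | is.na(years))
  years <- years[keep]; values <- values[keep]
  n <- length(values)
  if (n < 10) stop("need at least 10 points to fit the AR(1) trend model",
                   call. = FALSE)
  tc <- years - mean(years)
  scale <- max(abs(values - mean(values)), 1)

  if (stats::var(values) == 0) {
    return(new_trend_fit(mu = values[1], omega = 0, phi = 0, sigma_eps = 0,
                         omega_se = 0, residuals = rep(0, n),
                         loglik = Inf, n = n, degenerate = TRUE))
  }

  X <- cbind(1, tc)
  ols <- stats::lm.fit(X, values)
  rss_ols <- sum(ols$residuals^2)
  if (rss_ols <= (1e-10 * scale)^2 * n) {   # numerically exact line
    return(new_trend_fit(mu = ols$coefficients[1], omega = ols$coefficients[2],
                         phi = 0, sigma_eps = 0, omega_se = 0,
                         residuals = rep(0, n), loglik = Inf, n = n,
                         degenerate = TRUE))
  }

  prof <- function(phi) {
    rss <- pw_rss(phi, values, X)$rss
    0.5 * log1p(-phi^2) - n / 2 * log(rss / n)
  }
  grid <- seq(-0.95, 0.95, by = 0.05)
  ll <- vapply(grid, prof, numeric(1))
  best <- grid[which.max(ll)]
  opt <- stats::optimize(prof, c(max(-0.999, best - 0.06),
                                 min(0.999, best + 0.06)),
                         maximum = TRUE, tol = 1e-7)
  phi <- opt$maximum
  if (prof(0) >= opt$objective - 1e-10) phi <- 0   # ties toward smaller |phi|

  sol <- pw_rss(phi, values, X)
  beta <- sol$beta
  rss <- sol$rss
  sigma2 <- rss / (n - 2)
  xtxinv <- chol2inv(chol(crossprod(sol$Xs)))
  mu <- unname(beta[1]); omega <- unname(beta[2])
  new_trend_fit(
    mu = mu, omega = omega, phi = phi,
    sigma_eps = sqrt(sigma2),
    omega_se = sqrt(sigma2 * xtxinv[2, 2]),
    residuals = values - (mu + omega * tc),
    loglik = -n / 2 * (log(2 * pi * rss / n) + 1) + 0.5 * log1p(-phi^2),
    n = n, degenerate = FALSE)
}

# Prais-Winsten whitening of y and X for a given phi, plus the GLS solution
pw_rss <- function(phi, y, X) {
  n <- length(y)
  a <- sqrt(1 - phi^2)
  ys <- c(a * y[1], y[-1] - phi * y[-n])
  Xs <- rbind(a * X[1, ], X[-1, , drop = FALSE] - phi * X[-n, , drop = FALSE])
  fit <- stats::lm.fit(Xs, ys)
  list(rss = sum(fit$residuals^2), beta = fit$coefficients, Xs = Xs)
}

new_trend_fit <- function(mu, omega, phi, sigma_eps, omega_se, residuals,
                          loglik, n, degenerate) {
  structure(list(mu = mu, omega = omega, phi = phi, sigma_eps = sigma_eps,
                 omega_se = omega_se, residuals = residuals, loglik = loglik,
                 n = n, degenerate = degenerate),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("AR(1)-GLS trend fit (n = %d%s)\n", x$n,
              if (x$degenerate) ", degenerate" else ""))
  cat(sprintf("  omega = %.6g per yr (se %.3g), phi = %.3f, sigma_eps = %.4g\n",
              x$omega, x$omega_se, x$phi, x$sigma_eps))
  invisible(x)
}

#' Trend in conventional reporting units
#'
#' SST-like variables report the slope in variable units per decade; the
#' others as percent change per decade relative to a late-historical baseline
#' mean (the 1986-2005 mean of the series).
#'
#' @param fit a [fit_ar1_gls()] result (or any list with `omega`).
#' @param report `"absolute"` or `"percent"`.
#' @param baseline_mean the 1986-2005 mean of the series; required (and
#'   nonzero) for percentage variables.
#' @return the trend per decade, absolute or in percent.
#' @export
trend_in_reporting_units <- function(fit, report = c("percent", "absolute"),
                                     baseline_mean = NULL) {
  report <- match.arg(report)
  if (report == "absolute") return(fit$omega * 10)
  if (is.null(baseline_mean) || baseline_mean == 0)
    stop("a nonzero baseline_mean is required for percentage reporting",
         call. = FALSE)
  100 * fit$omega * 10 / baseline_mean
}

#' Mean of a series over the 1986-2005 baseline window
#'
#' @param years,values the annual series.
#' @param window baseline years, default `c(1986, 2005)`.
#' @return the baseline mean.
#' @export
baseline_mean <- function(years, values, window = c(1986, 2005)) {
  sel <- years >= window[1] & years <= window[2]
  if (!any(sel)) stop("series does not cover the baseline window", call. = FALSE)
  mean(values[sel], na.rm = TRUE)
}
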