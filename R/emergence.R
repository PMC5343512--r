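#' Detect the start of the climate-change signal
#'
#' Computes first differences of the annual series, their cumulative sum
#' `C(t) = Y_t - Y_first`, takes the trend sign from the full-series OLS
#' slope, and returns the year *preceding* the first time `C(t)` is strictly
#' positive (negative for downward trends) and remains so through the final
#' year — the last year still inside the old regime. If no persistent
#' exceedance exists (or the series is constant), the first year is returned
#' with `flagged = TRUE`.
#'
#' @param years,values annual series, at least 20 years.
#' @return list with `start_year`, `trend_sign` (+1/-1/0) and `flagged`.
#' @export
detect_start <- function(years, values) {
  stopifnot(length(years) == length(values))
  n <- length(values)
  if (n < 20) stop("need at least 20 years to locate the signal start",
                   call. = FALSE)
  if (stats::var(values) == 0)
    return(list(start_year = years[1], trend_sign = 0, flagged = TRUE))
  s <- sign(sum((years - mean(years)) * (values - mean(values))))
  if (s == 0)
    return(list(start_year = years[1], trend_sign = 0, flagged = TRUE))
  C <- cumsum(diff(values))               # C[k] = Y_{k+1} - Y_1
  ok <- s * C > 0
  persistent <- rev(cumprod(rev(ok))) == 1  # TRUE where ok from k through end
  k <- which(persistent)[1]
  if (is.na(k))
    return(list(start_year = years[1], trend_sign = s, flagged = TRUE))
  list(start_year = years[k], trend_sign = s, flagged = FALSE)
}

#' Natural variability from a control run
#'
#' One sample standard deviation (n-1 denominator) of the last 100 years of
#' (detrended) control-run annual extrema — the noise level of the emergence
#' criterion.
#'
#' @param values control annual extrema (detrended where necessary, see
#'   [detrend_linear()]); at least 100 years.
#' @return the noise s.d.
#' @export
noise_sd <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 100)
    stop("the control segment must provide at least 100 years of annual ",
         "extrema", call. = FALSE)
  stats::sd(utils::tail(values, 100))
}

#' Time of emergence of a linear signal above 2-sigma noise
#'
#' First integer year `y >= start_year` at which the fitted linear signal
#' strictly exceeds twice the noise level,
#' `|omega| * (y - start_year) > 2 * sigma_noise` — a threshold that exceeds
#' 95% of normally distributed noise values — persisting through `horizon`
#' (automatic for a linear signal). Years beyond `horizon` are excluded
#' (`NA`). Zero noise with a nonzero slope emerges immediately at
#' `start_year`.
#'
#' @param start_year start of the climate-change signal (see
#'   [detect_start()]).
#' @param omega trend slope fitted from `start_year` to `horizon`, per year.
#' @param sigma_noise control-run noise s.d. (see [noise_sd()]).
#' @param horizon last admissible year, default 2100.
#' @return integer year of emergence, or `NA_integer_`.
#' @export
compute_toe <- function(start_year, omega, sigma_noise, horizon = 2100) {
  stopifnot(sigma_noise >= 0)
  if (is.na(omega) || omega == 0) return(NA_integer_)
  if (sigma_noise == 0) return(as.integer(start_year))
  yrs <- seq(start_year, horizon)
  hit <- abs(omega) * (yrs - start_year) > 2 * sigma_noise
  if (!any(hit)) return(NA_integer_)
  as.integer(yrs[which(hit)[1]])
}

#' Pace of climate change
#'
#' Years between the start of the climate-change signal and its emergence.
#'
#' @param result an [emergence_series()] result (or any list with `toe`,
#'   `start_year`, `emerged`).
#' @return integer years, or `NA_integer_` when not emerged.
#' @export
pace <- function(result) {
  if (!isTRUE(result$emerged)) return(NA_integer_)
  as.integer(result$toe - result$start_year)
}

#' Full emergence analysis of one pixel series
#'
#' Runs the per-pixel chain: locate the signal start ([detect_start()]),
#' refit the AR(1)-GLS trend from that start forward to `horizon`
#' ([fit_ar1_gls()]), and apply the 2-sigma emergence criterion
#' ([compute_toe()]) against the control-run noise level.
#'
#' The default criterion compares the fitted linear signal to the noise. The
#' `"raw"` alternative (comparison only) instead takes the first year from
#' which the observed extrema themselves stay beyond the 2-sigma band around
#' the level at the signal start.
#'
#' A pixel is treated as having no climate-change signal (not emerged, `toe`
#' NA) when the cumulative sum never becomes persistently uni-directional
#' (the detector's `flagged` case) or when the detected start leaves fewer
#' than `min_window` years to `horizon` — too short a record to establish a
#' climate trend (the default, 30 years, is the usual climate-normal
#' convention).
#'
#' @param years,values conjoined historical + scenario annual extrema.
#' @param sigma_noise control-run noise s.d.
#' @param horizon last admissible emergence year.
#' @param criterion `"trend"` (default) or `"raw"`.
#' @param min_window minimum years from the detected start to `horizon`.
#' @return an object of class `emergence_result`: `start_year`, `toe`,
#'   `pace`, `sigma_noise`, `omega_used`, `emerged`, `flagged`, `fit`.
#' @export
emergence_series <- function(years, values, sigma_noise, horizon = 2100,
                             criterion = c("trend", "raw"),
                             min_window = 30) {
  criterion <- match.arg(criterion)
  st <- detect_start(years, values)
  win <- years >= st$start_year & years <= horizon
  fit <- NULL
  toe <- NA_integer_
  omega <- NA_real_
  if (!st$flagged && sum(win) >= max(10, min_window) && st$trend_sign != 0) {
    fit <- fit_ar1_gls(years[win], values[win])
    omega <- fit$omega
    if (criterion == "trend") {
      toe <- compute_toe(st$start_year, omega, sigma_noise, horizon)
    } else {
      base <- values[years == st$start_year][1]
      yrs <- years[win]; v <- values[win]
      out <- st$trend_sign * (v - base) > 2 * sigma_noise
      persistent <- rev(cumprod(rev(out))) == 1
      k <- which(persistent)[1]
      toe <- if (is.na(k)) NA_integer_ else as.integer(yrs[k])
    }
  }
  res <- structure(list(start_year = st$start_year, toe = toe,
                        sigma_noise = sigma_noise, omega_used = omega,
                        emerged = !is.na(toe), flagged = st$flagged,
                        fit = fit),
                   class = "emergence_result")
  res$pace <- pace(res)
  res
}

#' Per-pixel emergence maps for one model, one variable
#'
#' Applies [emergence_series()] at every pixel of a conjoined annual-extrema
#' stack, using a control stack (detrended per pixel) for the noise level.
#'
#' @param extrema conjoined historical + scenario `annual_extrema` stack.
#' @param control control-run `annual_extrema` stack on the same grid
#'   (detrended internally via [detrend_linear()]).
#' @param horizon last admissible emergence year.
#' @param criterion,min_window see [emergence_series()].
#' @param keep_fits keep each pixel's `trend_fit` (for QC on residuals).
#' @return list of `nlat x nlon` matrices `start_year`, `toe`, `pace`,
#'   `sigma_noise`, `omega`, `emerged`, plus `lat`, `lon`, `variable` and
#'   (optionally) `fits`.
#' @export
emergence_map <- function(extrema, control, horizon = 2100,
                          criterion = "trend", min_window = 30,
                          keep_fits = FALSE) {
  stopifnot(inherits(extrema, "annual_extrema"),
            inherits(control, "annual_extrema"))
  ctl <- detrend_linear(control)
  nlat <- length(extrema$lat); nlon <- length(extrema$lon)
  npix <- nlat * nlon
  ev <- matrix(extrema$values, nrow = length(extrema$years))
  cv <- matrix(ctl$values, nrow = length(ctl$years))
  m <- function() matrix(NA_real_, nlat, nlon)
  out <- list(start_year = m(), toe = m(), pace = m(), sigma_noise = m(),
              omega = m(), emerged = matrix(FALSE, nlat, nlon),
              lat = extrema$lat, lon = extrema$lon,
              variable = extrema$variable)
  if (keep_fits) out$fits <- vector("list", npix)
  for (k in seq_len(npix)) {
    if (anyNA(ev[, k]) || anyNA(cv[, k])) next   # land / missing pixel
    sig <- noise_sd(cv[, k])
    r <- emergence_series(extrema$years, ev[, k], sig, horizon, criterion,
                          min_window)
    out$start_year[k] <- r$start_year
    out$toe[k] <- r$toe
    out$pace[k] <- r$pace
    out$sigma_noise[k] <- sig
    out$omega[k] <- r$omega_used
    out$emerged[k] <- r$emerged
    if (keep_fits && !is.null(r$fit)) out$fits[[k]] <- r$fit
  }
  out
}
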