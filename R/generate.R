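#' Gridded monthly field
#'
#' Container for one variable of one run segment: a `(time, lat, lon)` array
#' of monthly values with integer year/month coordinates. Land (if any) is NA.
#'
#' @param variable variable name.
#' @param run run label, `"control"` or `"scenario"`.
#' @param values numeric array `(n_months, nlat, nlon)`.
#' @param year,month integer vectors, one entry per time step (12 steps per
#'   calendar year, strictly increasing).
#' @param lat,lon cell-center coordinates in degrees.
#' @param units unit string.
#' @return an object of class `monthly_field`.
#' @export
monthly_field <- function(variable, run, values, year, month, lat, lon,
                          units = "") {
  stopifnot(length(year) == dim(values)[1], length(month) == length(year),
            dim(values)[2] == length(lat), dim(values)[3] == length(lon))
  tindex <- year * 12 + month
  if (any(diff(tindex) != 1))
    stop("time steps must be strictly increasing, 12 per calendar year",
         call. = FALSE)
  structure(list(variable = variable, run = run, values = values,
                 year = as.integer(year), month = as.integer(month),
                 lat = lat, lon = lon, units = units),
            class = "monthly_field")
}

#' Realized per-model parameters
#'
#' Applies the pseudo-model jitter to a variable's pixel parameters:
#' `trend_slope` and `innovation_sd` are multiplied by log-normal factors with
#' mean 1 and fractional s.d. `inter_model_jitter`, drawn from a substream
#' keyed by (seed, model, variable). All fields are returned expanded to
#' `nlat x nlon` matrices.
#'
#' @param config a [generator_config()].
#' @param model_index pseudo-model index, `1..n_models`.
#' @param variable variable name (must match a config entry).
#' @return a list of `nlat x nlon` parameter matrices plus the jitter factors.
#' @export
model_params <- function(config, model_index, variable) {
  stopifnot(inherits(config, "generator_config"))
  if (model_index < 1 || model_index > config$n_models)
    stop("model_index must be in 1..n_models", call. = FALSE)
  vs <- config$variables[[variable]]
  if (is.null(vs)) stop("unknown variable: ", variable, call. = FALSE)
  nlat <- length(config$lat); nlon <- length(config$lon)
  p <- lapply(vs$params, expand_param, nlat = nlat, nlon = nlon)
  j <- config$inter_model_jitter
  if (j > 0) {
    sdl <- sqrt(log1p(j^2))                     # log-normal with mean 1, sd j
    f <- with_seed(substream_seed(config$seed, "jitter", model_index, variable),
                   exp(stats::rnorm(2, -sdl^2 / 2, sdl)))
  } else f <- c(1, 1)
  p$trend_slope <- p$trend_slope * f[1]
  p$innovation_sd <- p$innovation_sd * f[2]
  p$jitter_factors <- c(slope = f[1], innovation_sd = f[2])
  p
}

# stationary AR(1) paths, one column per pixel, from a dedicated substream
ar1_noise_matrix <- function(n, phi, innov_sd, seed) {
  npix <- length(phi)
  with_seed(seed, {
    init <- stats::rnorm(npix, 0, innov_sd / sqrt(1 - phi^2))
    eps <- matrix(stats::rnorm(n * npix), n, npix) *
      rep(innov_sd, each = n)
    out <- matrix(0, n, npix)
    for (k in seq_len(npix)) {
      out[, k] <- if (innov_sd[k] == 0) 0 else
        as.numeric(stats::filter(eps[, k], phi[k], method = "recursive",
                                 init = init[k]))
    }
    out
  })
}

generate_run <- function(config, model_index, variable,
                         run = c("control", "scenario"), slope_scale = 1) {
  run <- match.arg(run)
  p <- model_params(config, model_index, variable)
  vs <- config$variables[[variable]]
  nlat <- length(config$lat); nlon <- length(config$lon)
  npix <- nlat * nlon
  years <- if (run == "control") {
    seq(min(config$scenario_years) - config$years_control,
        length.out = config$years_control)
  } else config$scenario_years
  ny <- length(years)
  yr <- rep(years, each = 12)
  mo <- rep(1:12, ny)
  n <- length(yr)

  # per-pixel peak month (may vary over the grid)
  peak <- as.vector(p$seasonal_peak_month)
  amp <- as.vector(p$seasonal_amplitude)
  seasonal <- vapply(seq_len(npix), function(k)
    amp[k] * cos(2 * pi * (mo - peak[k]) / 12), numeric(n))

  vals <- matrix(rep(as.vector(p$mean_level), each = n), n, npix) + seasonal

  if (run == "scenario") {
    t0 <- as.vector(p$trend_start_year)
    if (any(t0 > max(years)))
      stop("scenario span does not cover trend_start_year", call. = FALSE)
    tm <- yr + (mo - 1) / 12
    slope <- as.vector(p$trend_slope) * slope_scale
    trend <- vapply(seq_len(npix), function(k)
      slope[k] * pmax(0, tm - t0[k]), numeric(n))
    vals <- vals + trend
  }

  noise_seed <- substream_seed(config$seed, "noise", model_index, variable, run)
  vals <- vals + ar1_noise_matrix(n, as.vector(p$ar1_coeff),
                                  as.vector(p$innovation_sd), noise_seed)

  monthly_field(variable, run, array(vals, c(n, nlat, nlon)),
                year = yr, month = mo,
                lat = config$lat, lon = config$lon, units = vs$units)
}

#' Generate a trend-free preindustrial control segment
#'
#' Mean + seasonal cycle + stationary AR(1) noise, with the AR(1) state
#' initialized from its stationary distribution (no burn-in transient).
#' Deterministic given `(seed, model_index, variable)`.
#'
#' @inheritParams model_params
#' @return a [monthly_field()] labelled `"control"`, covering
#'   `years_control` years immediately preceding the scenario span.
#' @export
generate_control <- function(config, model_index, variable) {
  generate_run(config, model_index, variable, "control")
}

#' Generate a conjoined historical + scenario run
#'
#' As [generate_control()] plus the secular trend: zero before each pixel's
#' `trend_start_year`, then `slope * (t - trend_start_year)` with `t` the
#' fractional time of the month (`year + (month - 1)/12`). Mitigation
#' pathways are emulated by `slope_scale`; the noise path is keyed
#' independently of `slope_scale`, so scenarios with different scalings share
#' identical noise (paired scenarios).
#'
#' @inheritParams model_params
#' @param slope_scale multiplier applied to every pixel's trend slope
#'   (e.g. 0.5 for a mitigation pathway).
#' @return a [monthly_field()] labelled `"scenario"`.
#' @export
generate_scenario <- function(config, model_index, variable, slope_scale = 1) {
  generate_run(config, model_index, variable, "scenario", slope_scale)
}

#' Closed-form ground-truth time of emergence
#'
#' For a piecewise-linear signal of slope `trend_slope` starting at
#' `trend_start_year` and noise level `sigma_extrema` (s.d. of control-run
#' annual extrema), the first integer year `y` with
#' `|slope| * (y - start) > 2 * sigma_extrema`, or `NA` if that exceeds
#' `horizon`. With `sigma_extrema = 0` and a nonzero slope, emergence is
#' immediate (the start year itself).
#'
#' @param params a [pixel_params()] (scalar fields), or any list with
#'   `trend_slope` and `trend_start_year`.
#' @param sigma_extrema noise level, `>= 0`.
#' @param horizon last admissible emergence year.
#' @return integer year, or `NA_integer_` if never/too late.
#' @export
true_toe <- function(params, sigma_extrema, horizon = 2100) {
  stopifnot(sigma_extrema >= 0)
  s <- params$trend_slope
  t0 <- params$trend_start_year
  if (s == 0) return(NA_integer_)
  if (sigma_extrema == 0) return(as.integer(t0))
  dt <- 2 * sigma_extrema / abs(s)
  y <- t0 + floor(dt) + 1          # first integer year strictly exceeding
  if (y > horizon) NA_integer_ else as.integer(y)
}
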