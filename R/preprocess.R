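#' Per-pixel annual-extrema stack
#'
#' One value per pixel per calendar year: the annual maximum (SST) or minimum
#' (pH, oxygen, primary production) of the twelve monthly values, i.e. the
#' seasonally worst-case condition the analysis tracks.
#'
#' @param field a [monthly_field()]. Partial calendar years at either end are
#'   dropped; a year with any missing month yields NA for that year (never
#'   silently filled).
#' @param direction `"max"` or `"min"`.
#' @return an object of class `annual_extrema`: list with `variable`,
#'   `direction`, integer `years`, `values` array `(n_years, nlat, nlon)`,
#'   `lat`, `lon`, `units`.
#' @export
annual_extrema <- function(field, direction = c("max", "min")) {
  direction <- match.arg(direction)
  annual_stat(field, direction)
}

#' Per-pixel annual means
#'
#' Companion to [annual_extrema()] for the annual-mean sensitivity analysis.
#' @inheritParams annual_extrema
#' @return an `annual_extrema` object with `direction = "mean"`.
#' @export
annual_mean <- function(field) annual_stat(field, "mean")

annual_stat <- function(field, direction) {
  stopifnot(inherits(field, "monthly_field"))
  complete <- names(which(table(field$year) == 12))
  keep <- field$year %in% as.integer(complete)
  yr <- field$year[keep]
  years <- sort(unique(yr))
  ny <- length(years)
  nlat <- length(field$lat); nlon <- length(field$lon)
  npix <- nlat * nlon
  v <- matrix(field$values[keep, , ], nrow = sum(keep), ncol = npix)
  dim(v) <- c(12, ny, npix)
  f <- switch(direction, max = max, min = min, mean = mean)
  out <- apply(v, c(2, 3), f)     # NA months propagate: the year is flagged NA
  structure(list(variable = field$variable, direction = direction,
                 years = years, values = array(out, c(ny, nlat, nlon)),
                 lat = field$lat, lon = field$lon, units = field$units),
            class = "annual_extrema")
}

#' Thickness-weighted thermocline mean of a depth-resolved field
#'
#' Collapses a monthly field with a depth axis to the 200-600 m layer:
#' the thickness-weighted mean concentration over the portion of each layer
#' lying inside the depth window. Layers partially overlapping the window
#' contribute their overlapping thickness. Columns with no coverage are NA.
#'
#' @param field a list like a [monthly_field()] but with `values` of shape
#'   `(time, depth, lat, lon)`, plus `depth_bounds` (an `ndepth x 2` matrix of
#'   upper/lower layer bounds) and `depth_units` (must be `"m"`).
#' @param window depth window in meters, default `c(200, 600)`.
#' @return a [monthly_field()] without the depth axis.
#' @export
thermocline_mean <- function(field, window = c(200, 600)) {
  if (!identical(field$depth_units, "m"))
    stop("depth units must be meters ('m')", call. = FALSE)
  db <- field$depth_bounds
  w <- pmax(0, pmin(db[, 2], window[2]) - pmax(db[, 1], window[1]))
  if (all(w == 0))
    stop("depth axis does not intersect the ", window[1], "-", window[2],
         " m window", call. = FALSE)
  dm <- dim(field$values)            # (time, depth, lat, lon)
  v <- matrix(aperm(field$values, c(2, 1, 3, 4)), nrow = dm[2])
  out <- colSums(v * w) / sum(w)     # NA layers with weight > 0 propagate
  monthly_field(field$variable, field$run,
                array(out, c(dm[1], dm[3], dm[4])),
                year = field$year, month = field$month,
                lat = field$lat, lon = field$lon, units = field$units)
}

#' Nearest-neighbour regridding onto a regular grid
#'
#' Each target cell takes the value of the great-circle-nearest source cell
#' center; missing values (land) propagate unchanged.
#'
#' @param x a [monthly_field()] or `annual_extrema` stack.
#' @param target_lat,target_lon target cell-center coordinates (degrees).
#' @return an object of the same class on the target grid.
#' @export
regrid_nearest <- function(x, target_lat, target_lon) {
  if (length(target_lat) == 0 || length(target_lon) == 0)
    stop("target grid is empty", call. = FALSE)
  src <- expand.grid(lat = x$lat, lon = x$lon)     # column-major pixel order
  idx <- integer(length(target_lat) * length(target_lon))
  k <- 1L
  for (j in seq_along(target_lon)) {
    for (i in seq_along(target_lat)) {
      d <- gc_dist(target_lat[i], target_lon[j], src$lat, src$lon)
      idx[k] <- which.min(d)
      k <- k + 1L
    }
  }
  nt <- dim(x$values)[1]
  v <- matrix(x$values, nrow = nt)[, idx, drop = FALSE]
  out <- x
  out$values <- array(v, c(nt, length(target_lat), length(target_lon)))
  out$lat <- target_lat
  out$lon <- target_lon
  out
}

# great-circle central angle (haversine), degrees in, radians out
gc_dist <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  a <- sin((lat2 - lat1) * r / 2)^2 +
    cos(lat1 * r) * cos(lat2 * r) * sin((lon2 - lon1) * r / 2)^2
  2 * asin(pmin(1, sqrt(a)))
}

#' Conjoin historical and scenario annual-extrema stacks
#'
#' @param historical,scenario `annual_extrema` stacks on the same grid for the
#'   same variable; `historical` must end the year before `scenario` begins.
#' @return a single contiguous `annual_extrema` stack.
#' @export
concat_runs <- function(historical, scenario) {
  stopifnot(inherits(historical, "annual_extrema"),
            inherits(scenario, "annual_extrema"))
  if (!identical(historical$variable, scenario$variable) ||
      !identical(historical$direction, scenario$direction) ||
      !identical(historical$lat, scenario$lat) ||
      !identical(historical$lon, scenario$lon))
    stop("segments must share variable, direction and grid", call. = FALSE)
  if (max(historical$years) + 1L != min(scenario$years))
    stop("segments must be contiguous: historical ends ",
         max(historical$years), ", scenario begins ", min(scenario$years),
         call. = FALSE)
  out <- historical
  out$years <- c(historical$years, scenario$years)
  nlat <- length(out$lat); nlon <- length(out$lon)
  # rbind along the year axis
  v <- rbind(matrix(historical$values, nrow = length(historical$years)),
             matrix(scenario$values, nrow = length(scenario$years)))
  out$values <- array(v, c(length(out$years), nlat, nlon))
  out
}

#' Conditionally detrend a control-run stack
#'
#' Removes a per-pixel ordinary-least-squares line from control annual
#' extrema, but only where the fitted slope is significant at `alpha`
#' (a drifting control needs detrending; a stationary one is left alone).
#' The pixel mean is preserved.
#'
#' @param control an `annual_extrema` stack (or a plain numeric vector with
#'   `years` supplied).
#' @param alpha significance level for the slope t-test.
#' @param years year coordinates when `control` is a plain vector.
#' @return same class as the input, detrended where necessary.
#' @export
detrend_linear <- function(control, alpha = 0.05, years = NULL) {
  if (is.numeric(control)) {
    return(detrend_series(years, control, alpha))
  }
  stopifnot(inherits(control, "annual_extrema"))
  out <- control
  ny <- length(control$years)
  v <- matrix(control$values, nrow = ny)
  for (k in seq_len(ncol(v))) {
    if (!anyNA(v[, k])) v[, k] <- detrend_series(control$years, v[, k], alpha)
  }
  out$values <- array(v, dim(control$values))
  out
}

detrend_series <- function(years, values, alpha = 0.05) {
  stopifnot(length(years) == length(values), length(values) >= 3)
  if (stats::var(values) == 0) return(values)
  fit <- stats::lm(values ~ years)
  r <- unname(stats::residuals(fit))
  if (sum(r^2) <= 1e-20 * sum((values - mean(values))^2))
    return(r + mean(values))                    # exact line: always removed
  pval <- summary(fit)$coefficients[2, 4]
  if (is.na(pval) || pval >= alpha) return(values)
  r + mean(values)
}
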