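#' Per-pixel generative parameters
#'
#' Describes one grid cell of the synthetic Earth-system-model world: a mean
#' level, a sinusoidal seasonal cycle, a piecewise-linear secular trend (flat
#' until `trend_start_year`, then a linear ramp) and stationary AR(1) noise at
#' monthly resolution.
#'
#' @param mean_level mean level, in variable units.
#' @param seasonal_amplitude amplitude of the seasonal cosine, `>= 0`.
#' @param seasonal_peak_month calendar month (1-12) at which the seasonal
#'   cycle peaks.
#' @param trend_start_year calendar year at which the secular ramp begins.
#' @param trend_slope ramp slope, variable units per year (sign free).
#' @param ar1_coeff lag-1 autocorrelation of the monthly noise, in (-1, 1).
#' @param innovation_sd standard deviation of the monthly AR(1) innovations,
#'   `>= 0`, variable units.
#'
#' Any field may be a scalar or an `nlat x nlon` matrix (latitude-dependent
#' worlds); scalars are recycled over the grid.
#'
#' @return an object of class `pixel_params` (a validated list).
#' @export
pixel_params <- function(mean_level,
                         seasonal_amplitude = 0,
                         seasonal_peak_month = 1,
                         trend_start_year = 1950,
                         trend_slope = 0,
                         ar1_coeff = 0,
                         innovation_sd = 0) {
  p <- list(
    mean_level = mean_level,
    seasonal_amplitude = seasonal_amplitude,
    seasonal_peak_month = seasonal_peak_month,
    trend_start_year = trend_start_year,
    trend_slope = trend_slope,
    ar1_coeff = ar1_coeff,
    innovation_sd = innovation_sd
  )
  validate_pixel_params(p)
  structure(p, class = "pixel_params")
}

validate_pixel_params <- function(p) {
  if (any(abs(p$ar1_coeff) >= 1))
    stop("invalid ar1_coeff: |phi| must be < 1 for stationary AR(1) noise",
         call. = FALSE)
  if (any(p$seasonal_amplitude < 0))
    stop("seasonal_amplitude must be >= 0", call. = FALSE)
  if (any(p$innovation_sd < 0))
    stop("innovation_sd must be >= 0", call. = FALSE)
  if (any(p$seasonal_peak_month < 1 | p$seasonal_peak_month > 12))
    stop("seasonal_peak_month must be in 1..12", call. = FALSE)
  invisible(p)
}

#' Declare one driver variable for the generator
#'
#' @param name short variable name (e.g. `"sst"`, `"ph"`, `"o2"`, `"pp"`).
#' @param direction which annual extremum the analysis uses: `"max"` (SST) or
#'   `"min"` (pH, oxygen, primary production).
#' @param params a [pixel_params()] object (fields scalar or gridded).
#' @param units unit string carried into output metadata.
#' @param report how trends are reported downstream: `"absolute"` (per decade
#'   in variable units) or `"percent"` (% per decade relative to a baseline
#'   mean).
#' @return an object of class `variable_spec`.
#' @export
variable_spec <- function(name, direction = c("max", "min"), params,
                          units = "", report = c("percent", "absolute")) {
  direction <- match.arg(direction)
  report <- match.arg(report)
  stopifnot(inherits(params, "pixel_params"))
  structure(list(name = name, direction = direction, params = params,
                 units = units, report = report),
            class = "variable_spec")
}

#' Configuration of the synthetic Earth-system-model ensemble
#'
#' Defines the grid, run segments, driver variables and pseudo-model ensemble
#' of a synthetic world. Each pseudo-model perturbs every variable's
#' `trend_slope` and `innovation_sd` by a multiplicative log-normal factor
#' with fractional s.d. `inter_model_jitter` (mean 1), emulating inter-model
#' spread while preserving the sign of the trend.
#'
#' @param lat,lon grid-cell-center coordinates in degrees; latitudes strictly
#'   inside (-90, 90), longitudes in \[0, 360).
#' @param variables a list of [variable_spec()] objects.
#' @param n_models number of pseudo-models (`>= 1`).
#' @param years_control length of the preindustrial control segment in years
#'   (`>= 100`).
#' @param scenario_years contiguous calendar years of the conjoined
#'   historical + scenario run (default 1860:2100).
#' @param inter_model_jitter fractional s.d. of the per-model multiplicative
#'   jitter on trend slope and innovation s.d.
#' @param seed root integer seed; all substreams derive from it.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(lat, lon, variables,
                             n_models = 1L,
                             years_control = 100L,
                             scenario_years = 1860:2100,
                             inter_model_jitter = 0,
                             seed = 1L) {
  if (years_control < 100)
    stop("years_control must be >= 100 (a 100-year control section is the ",
         "minimum the noise estimate uses)", call. = FALSE)
  if (any(lat <= -90 | lat >= 90))
    stop("grid latitudes must lie strictly within (-90, 90)", call. = FALSE)
  if (any(lon < 0 | lon >= 360))
    stop("grid longitudes must lie within [0, 360)", call. = FALSE)
  if (n_models < 1) stop("n_models must be >= 1", call. = FALSE)
  if (any(diff(scenario_years) != 1))
    stop("scenario_years must be contiguous", call. = FALSE)
  if (is.null(names(variables)))
    names(variables) <- vapply(variables, function(v) v$name, character(1))
  for (v in variables) stopifnot(inherits(v, "variable_spec"))
  structure(list(lat = as.double(lat), lon = as.double(lon),
                 variables = variables,
                 n_models = as.integer(n_models),
                 years_control = as.integer(years_control),
                 scenario_years = as.integer(scenario_years),
                 inter_model_jitter = inter_model_jitter,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# recycle a scalar parameter over the grid, or check a supplied matrix
expand_param <- function(x, nlat, nlon) {
  if (length(x) == 1) return(matrix(x, nlat, nlon))
  if (is.matrix(x) && all(dim(x) == c(nlat, nlon))) return(x)
  stop("parameter fields must be scalars or nlat x nlon matrices",
       call. = FALSE)
}

#' Read a generator configuration from YAML or JSON
#'
#' The on-disk form mirrors [generator_config()]: top-level keys `lat`, `lon`,
#' `n_models`, `years_control`, `scenario_years` (`[first, last]`),
#' `inter_model_jitter`, `seed`, and a `variables` map whose entries hold
#' `direction`, `units`, `report` and the [pixel_params()] fields.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  vars <- lapply(names(raw$variables), function(nm) {
    v <- raw$variables[[nm]]
    pp <- do.call(pixel_params, v[intersect(names(v), names(formals(pixel_params)))])
    variable_spec(nm, direction = v$direction, params = pp,
                  units = if (is.null(v$units)) "" else v$units,
                  report = if (is.null(v$report)) "percent" else v$report)
  })
  names(vars) <- names(raw$variables)
  sy <- raw$scenario_years
  generator_config(lat = raw$lat, lon = raw$lon, variables = vars,
                   n_models = raw$n_models %||% 1L,
                   years_control = raw$years_control %||% 100L,
                   scenario_years = if (length(sy) == 2) sy[1]:sy[2] else sy,
                   inter_model_jitter = raw$inter_model_jitter %||% 0,
                   seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
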