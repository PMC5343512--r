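# small single-variable worlds used across tests

one_pixel_config <- function(params, direction = "max", seed = 1,
                             years_control = 100, n_models = 1,
                             jitter = 0, lat = 0, lon = 0) {
  generator_config(
    lat = lat, lon = lon,
    variables = list(x = variable_spec("x", direction, params)),
    n_models = n_models, years_control = years_control,
    inter_model_jitter = jitter, seed = seed)
}

# monthly field built directly from a value matrix (months x 1 pixel)
tiny_field <- function(values, start_year = 2000, lat = 0, lon = 0,
                       variable = "x", run = "scenario") {
  n <- length(values)
  stopifnot(n %% 12 == 0)
  ny <- n / 12
  monthly_field(variable, run,
                array(values, c(n, length(lat), length(lon))),
                year = rep(start_year + 0:(ny - 1), each = 12),
                month = rep(1:12, ny), lat = lat, lon = lon)
}

pixel_values <- function(ae, i = 1, j = 1) {
  matrix(ae$values, nrow = length(ae$years))[, (j - 1) * length(ae$lat) + i]
}
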