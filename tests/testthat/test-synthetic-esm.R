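test_that("noise-free generator reproduces mean and seasonal cycle exactly", {
  cfg <- one_pixel_config(pixel_params(mean_level = 5))
  ctl <- generate_control(cfg, 1, "x")
  expect_true(all(ctl$values == 5))

  cfg <- one_pixel_config(pixel_params(mean_level = 10, seasonal_amplitude = 2,
                                       seasonal_peak_month = 7))
  ctl <- generate_control(cfg, 1, "x")
  m <- ctl$month
  expect_equal(as.vector(ctl$values), 10 + 2 * cos(2 * pi * (m - 7) / 12))
  expect_equal(ctl$values[m == 7][1], 12)
})

test_that("monthly AR(1) noise has the configured lag-1 autocorrelation", {
  cfg <- one_pixel_config(pixel_params(mean_level = 0, ar1_coeff = 0.6,
                                       innovation_sd = 1),
                          years_control = 10000, seed = 4)
  x <- as.vector(generate_control(cfg, 1, "x")$values)
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 0.6), 0.02)
  # stationary variance 1/(1-phi^2)
  expect_lt(abs(sd(x) - 1 / sqrt(1 - 0.36)), 0.02)
})

test_that("scenario equals the paired zero-slope path plus the exact ramp", {
  p <- pixel_params(mean_level = 10, seasonal_amplitude = 2,
                    seasonal_peak_month = 7, trend_start_year = 1950,
                    trend_slope = 0.02, ar1_coeff = 0.5, innovation_sd = 0.3)
  cfg <- one_pixel_config(p, seed = 3)
  full <- generate_scenario(cfg, 1, "x", slope_scale = 1)
  flat <- generate_scenario(cfg, 1, "x", slope_scale = 0)
  tm <- full$year + (full$month - 1) / 12
  expect_equal(as.vector(full$values - flat$values),
               0.02 * pmax(0, tm - 1950))
  # noise-free: Jan 2000 exceeds Jan 1940 by 50 yr x 0.02
  p0 <- pixel_params(mean_level = 10, trend_start_year = 1950,
                     trend_slope = 0.02)
  s <- generate_scenario(one_pixel_config(p0), 1, "x")
  jan <- function(y) s$values[s$year == y & s$month == 1, 1, 1]
  expect_equal(jan(2000) - jan(1940), 1.00)
})

test_that("inter-model jitter has the configured fractional spread", {
  slopes <- unlist(lapply(1:200, function(seed) {
    cfg <- one_pixel_config(pixel_params(mean_level = 0, trend_slope = 1),
                            n_models = 12, jitter = 0.10, seed = seed)
    vapply(1:12, function(m) model_params(cfg, m, "x")$trend_slope[1, 1],
           numeric(1))
  }))
  expect_lt(abs(sd(slopes) / 1 - 0.10), 0.04)
  expect_lt(abs(mean(slopes) - 1), 0.01)      # jitter factors have mean 1
  expect_true(all(slopes > 0))                # sign-preserving
})

test_that("closed-form oracle emergence matches its defining inequality", {
  expect_identical(true_toe(list(trend_slope = 0.25, trend_start_year = 2000), 1),
                   2009L)  # 2008 gives exactly 2.0: not an exceedance
  expect_identical(true_toe(list(trend_slope = 0, trend_start_year = 2000), 1),
                   NA_integer_)
  expect_identical(true_toe(list(trend_slope = -0.02, trend_start_year = 1900),
                            0.005), 1901L)
  expect_identical(true_toe(list(trend_slope = 0.001, trend_start_year = 2090), 1),
                   NA_integer_)
})

test_that("halving trend slopes never makes oracle emergence earlier", {
  grid <- expand.grid(slope = c(-0.5, -0.05, 0.01, 0.1, 2),
                      sigma = c(0, 0.04, 0.9, 7),
                      start = c(1870, 1950, 2020))
  for (k in seq_len(nrow(grid))) {
    p1 <- list(trend_slope = grid$slope[k], trend_start_year = grid$start[k])
    p2 <- list(trend_slope = grid$slope[k] / 2, trend_start_year = grid$start[k])
    t1 <- true_toe(p1, grid$sigma[k])
    t2 <- true_toe(p2, grid$sigma[k])
    expect_true(is.na(t2) || (!is.na(t1) && t2 >= t1),
                info = paste(grid[k, ], collapse = " "))
  }
})

test_that("control-run annual extrema are time-stationary (split halves)", {
  cfg <- one_pixel_config(pixel_params(mean_level = 3, seasonal_amplitude = 1,
                                       seasonal_peak_month = 6,
                                       ar1_coeff = 0.7, innovation_sd = 0.5),
                          years_control = 4000, seed = 9)
  v <- as.vector(annual_extrema(generate_control(cfg, 1, "x"), "max")$values)
  h1 <- v[1:2000]; h2 <- v[2001:4000]
  se <- sqrt(var(h1) / 2000 + var(h2) / 2000)
  expect_lt(abs(mean(h1) - mean(h2)), 3 * se)
})

test_that("generator rejects invalid configurations", {
  expect_error(pixel_params(mean_level = 0, ar1_coeff = 1),
               "ar1_coeff")
  expect_error(pixel_params(mean_level = 0, innovation_sd = -1))
  expect_error(generate_scenario(
    one_pixel_config(pixel_params(mean_level = 0, trend_slope = 1,
                                  trend_start_year = 2150)), 1, "x"),
    "does not cover")
  expect_error(generator_config(lat = 90, lon = 0, variables = list(
    x = variable_spec("x", "max", pixel_params(mean_level = 0)))),
    "strictly within")
  expect_error(one_pixel_config(pixel_params(mean_level = 0),
                                years_control = 50),
               ">= 100")
})

test_that("generation is deterministic given (seed, model) and models differ", {
  p <- pixel_params(mean_level = 0, ar1_coeff = 0.5, innovation_sd = 1)
  cfg <- one_pixel_config(p, n_models = 2, seed = 21)
  a <- generate_control(cfg, 1, "x")
  b <- generate_control(cfg, 1, "x")
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$values,
                                generate_control(cfg, 2, "x")$values)))
})
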