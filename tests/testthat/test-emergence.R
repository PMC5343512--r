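# brute-force persistence scan: try every candidate year and check the
# cumulative sum stays on the trend side of zero through the end
brute_force_start <- function(years, values) {
  s <- sign(coef(lm(values ~ years))[2])
  C <- cumsum(diff(values))
  for (k in seq_along(C)) {
    if (all(s * C[k:length(C)] > 0)) return(years[k])
  }
  NA_integer_
}

test_that("signal start is located by persistent uni-directionality", {
  yrs <- 1860:2100
  expect_equal(detect_start(yrs, 1.5 * (yrs - 1860))$start_year, 1860)

  flat_ramp <- c(rep(0, 90), 0.3 * (1950:2100 - 1950))  # flat 1860-1949
  st <- detect_start(yrs, flat_ramp)
  expect_equal(st$start_year, 1950)
  expect_false(st$flagged)

  # constructed sign-alternating wiggles until 1970, monotone rise after
  wig <- c(rep(c(0.5, -0.5), length.out = 111), 1 + 0.2 * (1971:2100 - 1970))
  st <- detect_start(yrs, wig)
  expect_equal(st$start_year, 1970)
  expect_equal(st$start_year, unname(brute_force_start(yrs, wig)))

  # brute force agrees on noisy generated series too
  set.seed(13)
  for (rep in 1:20) {
    y <- cumsum(rnorm(120, 0.01)) + 0.05 * pmax(0, (1:120) - 60)
    st <- detect_start(1901:2020, y)
    bf <- brute_force_start(1901:2020, y)
    if (!st$flagged) expect_equal(st$start_year, unname(bf))
  }

  cst <- detect_start(yrs, rep(3, 241))
  expect_true(cst$flagged)
  expect_equal(cst$start_year, 1860)
  expect_error(detect_start(2001:2010, rnorm(10)), "at least 20")
})

test_that("noise level is the sample s.d. of the last 100 control years", {
  expect_equal(noise_sd(rep(4, 120)), 0)
  alt <- rep(c(-1, 1), 50)
  expect_equal(noise_sd(alt), sqrt(100 / 99))   # closed-form sample s.d.
  # only the final 100 years count
  expect_equal(noise_sd(c(rep(1000, 30), alt)), sqrt(100 / 99))
  # a drifting control is flat after conditional detrending
  yrs <- 1801:1900
  drift <- 5 + 0.04 * (yrs - 1801)
  expect_equal(noise_sd(detrend_linear(drift, years = yrs)), 0, tolerance = 1e-10)
  expect_error(noise_sd(rnorm(99)), "100")
})

test_that("emergence year follows the two-sigma exceedance rule", {
  expect_identical(compute_toe(2000, 0.25, 1), 2009L)   # 2008 hits exactly 2.0
  expect_identical(compute_toe(2090, 0.001, 1), NA_integer_)
  expect_identical(compute_toe(2000, 0, 1), NA_integer_)
  expect_identical(compute_toe(2000, -0.5, 0), 2000L)   # zero noise: immediate
  # agreement with the closed-form oracle across magnitudes
  for (om in c(-2, -0.11, 0.013, 0.4, 5)) {
    for (sg in c(0.001, 0.07, 1.3, 20)) {
      for (st in c(1870, 1920, 2050)) {
        expect_identical(compute_toe(st, om, sg),
                         true_toe(list(trend_slope = om,
                                       trend_start_year = st), sg))
      }
    }
  }
})

test_that("pace is the lag from signal start to emergence", {
  r <- list(start_year = 2000, toe = 2009, emerged = TRUE)
  expect_identical(pace(r), 9L)
  expect_identical(pace(list(start_year = 2000, toe = NA, emerged = FALSE)),
                   NA_integer_)
  expect_identical(pace(list(start_year = 2000, toe = 2000, emerged = TRUE)), 0L)
})

test_that("emergence is monotone in signal strength and noise level", {
  toes <- sapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(om)
    compute_toe(1950, om, 1))
  expect_true(all(diff(toes) <= 0))             # stronger trend: never later
  toes <- sapply(c(0.1, 0.5, 1, 2, 4), function(sg)
    compute_toe(1950, 0.2, sg))
  expect_true(all(diff(toes) >= 0))             # more noise: never earlier
})

test_that("flagged or short-window detections do not emerge", {
  yrs <- 1860:2100
  set.seed(2)
  pure_noise <- rnorm(241)
  r <- emergence_series(yrs, pure_noise, sigma_noise = 1)
  expect_false(r$emerged)
  # ramp starting 2085: persistent but leaves < 30 years of record
  late <- c(rep(0, 225), 2 * (1:16))
  r <- emergence_series(yrs, late, sigma_noise = 0.1)
  expect_false(r$emerged)
})

test_that("a clean piecewise-linear pixel reproduces the oracle exactly", {
  yrs <- 1860:2100
  v <- c(rep(10, 141), 10 + 0.12 * (1:100))     # flat through 2000, then ramp
  r <- emergence_series(yrs, v, sigma_noise = 0.9)
  expect_equal(r$start_year, 2000)
  expect_equal(unname(r$omega_used), 0.12, tolerance = 1e-8)
  expect_identical(r$toe, true_toe(list(trend_slope = 0.12,
                                        trend_start_year = 2000), 0.9))
  expect_identical(r$pace, r$toe - 2000L)
})

test_that("annual means emerge no later than annual extrema (medians)", {
  p <- pixel_params(mean_level = 15, seasonal_amplitude = 3,
                    seasonal_peak_month = 8, trend_start_year = 1950,
                    trend_slope = 0.06, ar1_coeff = 0.5, innovation_sd = 0.4)
  cfg <- generator_config(lat = seq(-40, 40, by = 10), lon = seq(20, 340, by = 40),
                          variables = list(x = variable_spec("x", "max", p)),
                          seed = 31)
  ctl <- generate_control(cfg, 1, "x")
  scn <- generate_scenario(cfg, 1, "x")
  em_ext <- emergence_map(annual_extrema(scn, "max"),
                          annual_extrema(ctl, "max"))
  em_mean <- emergence_map(annual_mean(scn), annual_mean(ctl))
  expect_lte(median(em_mean$toe, na.rm = TRUE),
             median(em_ext$toe, na.rm = TRUE))
})

test_that("start detection delays emergence in weak-signal regimes", {
  # the cusum start detector waits for the last dip of the series below its
  # first-year anchor, so when noise is large relative to the trend the
  # detected start — and with it the ToE — lags the closed-form oracle by
  # a delay of order sigma/omega; in this regime the pipeline median ToE
  # must sit at or above the oracle year
  p <- pixel_params(mean_level = 15, seasonal_amplitude = 3,
                    seasonal_peak_month = 8, trend_start_year = 1960,
                    trend_slope = 0.025, ar1_coeff = 0.5, innovation_sd = 0.26)
  cfg <- generator_config(lat = seq(-45, 45, by = 10),
                          lon = seq(18, 342, by = 36),
                          variables = list(x = variable_spec("x", "max", p)),
                          seed = 4)
  long <- generator_config(lat = 0, lon = 0,
                           variables = list(x = variable_spec("x", "max", p)),
                           years_control = 10000, seed = 104)
  sig <- sd(as.vector(annual_extrema(generate_control(long, 1, "x"), "max")$values))
  em <- emergence_map(annual_extrema(generate_scenario(cfg, 1, "x"), "max"),
                      annual_extrema(generate_control(cfg, 1, "x"), "max"))
  expect_gte(median(em$toe, na.rm = TRUE), true_toe(p, sig))
})
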