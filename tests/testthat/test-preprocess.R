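test_that("annual extrema pick the right monthly value per year", {
  f <- tiny_field(rep(7, 24))
  ae <- annual_extrema(f, "max")
  expect_equal(as.vector(ae$values), c(7, 7))
  expect_equal(ae$years, c(2000, 2001))

  f <- tiny_field(1:12)
  expect_equal(as.vector(annual_extrema(f, "min")$values), 1)
  expect_equal(as.vector(annual_extrema(f, "max")$values), 12)

  # cosine cycle sampled monthly peaks exactly at the peak month
  cfg <- one_pixel_config(pixel_params(mean_level = 10, seasonal_amplitude = 2,
                                       seasonal_peak_month = 7))
  ae <- annual_extrema(generate_control(cfg, 1, "x"), "max")
  expect_true(all(ae$values == 12))
  expect_true(all(annual_extrema(generate_control(cfg, 1, "x"), "min")$values == 8))
})

test_that("incomplete years are dropped and missing months flag the year", {
  v <- c(10, 11, rep(1:12, 2), 5)               # partial years at both ends
  f <- monthly_field("x", "scenario", array(v, c(27, 1, 1)),
                     year = c(1999, 1999, rep(2000:2001, each = 12), 2002),
                     month = c(11, 12, rep(1:12, 2), 1), lat = 0, lon = 0)
  ae <- annual_extrema(f, "max")
  expect_equal(ae$years, c(2000, 2001))

  v2 <- rep(1:12, 2); v2[5] <- NA
  f2 <- tiny_field(v2)
  expect_true(is.na(annual_extrema(f2, "max")$values[1]))
  expect_false(is.na(annual_extrema(f2, "max")$values[2]))
})

test_that("annual max dominates annual min pointwise", {
  cfg <- one_pixel_config(pixel_params(mean_level = 1, seasonal_amplitude = 0.5,
                                       seasonal_peak_month = 4,
                                       ar1_coeff = 0.4, innovation_sd = 0.7),
                          seed = 6)
  f <- generate_control(cfg, 1, "x")
  expect_true(all(annual_extrema(f, "max")$values >=
                  annual_extrema(f, "min")$values))
})

test_that("thermocline mean is the thickness-weighted layer average", {
  mk <- function(vals, bounds) {
    list(variable = "o2", run = "control",
         values = array(rep(vals, each = 12), c(12, length(vals), 1, 1)),
         year = rep(2000, 12), month = 1:12, lat = 0, lon = 0,
         depth_bounds = bounds, depth_units = "m", units = "umol/kg")
  }
  f <- mk(c(200, 100), rbind(c(200, 400), c(400, 600)))
  expect_equal(as.vector(thermocline_mean(f)$values), rep(150, 12))

  f <- mk(42, rbind(c(200, 600)))
  expect_equal(as.vector(thermocline_mean(f)$values), rep(42, 12))

  # hand-computed: (100*210 + 150*180 + 150*120) / 400 = 165
  f <- mk(c(210, 180, 120), rbind(c(200, 300), c(300, 450), c(450, 600)))
  expect_equal(as.vector(thermocline_mean(f)$values), rep(165, 12))

  # partial overlap: only the 200-600 m portion of each layer counts,
  # and the result stays within the layer-wise range
  f <- mk(c(300, 100, 50), rbind(c(0, 250), c(250, 500), c(500, 800)))
  got <- thermocline_mean(f)$values[1, 1, 1]
  expect_equal(got, (50 * 300 + 250 * 100 + 100 * 50) / 400)
  expect_gte(got, 50); expect_lte(got, 300)

  f$depth_units <- "cm"
  expect_error(thermocline_mean(f), "meters")
  f$depth_units <- "m"; f$depth_bounds <- rbind(c(0, 100))
  expect_error(thermocline_mean(f), "window")
})

test_that("nearest-neighbour regridding maps cells as expected", {
  f <- tiny_field(rep(c(1, 2, 3, 4), each = 12), lat = c(-1, 1), lon = c(90, 270))
  f$values <- array(c(rep(1, 12), rep(2, 12), rep(3, 12), rep(4, 12)),
                    c(12, 2, 2))
  same <- regrid_nearest(f, f$lat, f$lon)
  expect_equal(same$values, f$values)
  # idempotence on its own output grid
  expect_equal(regrid_nearest(same, f$lat, f$lon)$values, f$values)

  # 2-degree source onto 1-degree target: each fine cell inherits its
  # enclosing coarse cell's value
  src <- tiny_field(rep(0, 12), lat = c(-1, 1), lon = c(1, 3))
  src$values <- array(rep(c(10, 20, 30, 40), each = 12), c(12, 2, 2))
  tg <- regrid_nearest(src, c(-1.5, -0.5, 0.5, 1.5), c(0.5, 1.5, 2.5, 3.5))
  expect_equal(tg$values[1, , ],
               rbind(c(10, 10, 30, 30), c(10, 10, 30, 30),
                     c(20, 20, 40, 40), c(20, 20, 40, 40)))

  # single source cell floods the target; land (NA) propagates
  one <- tiny_field(rep(9, 12), lat = 10, lon = 100)
  out <- regrid_nearest(one, c(-5, 5), c(50, 150))
  expect_true(all(out$values == 9))
  one$values[] <- NA
  expect_true(all(is.na(regrid_nearest(one, c(-5, 5), c(50, 150))$values)))

  expect_error(regrid_nearest(one, numeric(0), 1:3), "empty")
})

test_that("historical and scenario segments conjoin verbatim or fail", {
  p <- pixel_params(mean_level = 2, ar1_coeff = 0.3, innovation_sd = 0.5)
  cfg <- one_pixel_config(p, seed = 8)
  ae <- annual_extrema(generate_scenario(cfg, 1, "x"), "max")
  split_at <- function(ae, yr) {
    pre <- ae; post <- ae
    keep <- ae$years <= yr
    pre$years <- ae$years[keep]
    pre$values <- ae$values[keep, , , drop = FALSE]
    post$years <- ae$years[!keep]
    post$values <- ae$values[!keep, , , drop = FALSE]
    list(pre, post)
  }
  halves <- split_at(ae, 2005)
  joined <- concat_runs(halves[[1]], halves[[2]])
  expect_equal(joined$years, 1860:2100)
  expect_equal(joined$values, ae$values)
  expect_equal(pixel_values(joined)[joined$years %in% c(2005, 2006)],
               pixel_values(ae)[ae$years %in% c(2005, 2006)])

  gap <- split_at(ae, 2004)
  gap[[2]]$years <- gap[[2]]$years[-1]
  gap[[2]]$values <- gap[[2]]$values[-1, , , drop = FALSE]
  expect_error(concat_runs(gap[[1]], gap[[2]]), "contiguous")
  bad <- halves[[2]]; bad$variable <- "y"
  expect_error(concat_runs(halves[[1]], bad), "share")
})

test_that("control detrending removes drift only when significant", {
  yrs <- 1901:2000
  line <- 3 + 0.05 * yrs
  out <- detrend_linear(line, years = yrs)
  expect_equal(out, rep(mean(line), 100))

  set.seed(42)
  flat <- rnorm(100)
  expect_equal(detrend_linear(flat, years = yrs), flat)  # slope n.s.: untouched

  drift <- 0.1 * (yrs - 1950) + rnorm(100, sd = 0.5)
  det <- detrend_linear(drift, years = yrs)
  refit <- summary(lm(det ~ yrs))$coefficients
  expect_lt(abs(refit[2, 1]), refit[2, 2])    # residual slope ~ 0
  expect_equal(mean(det), mean(drift))        # mean preserved
})
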