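#' Ensemble median time-of-emergence map
#'
#' Per pixel, the median ToE over the models in which the signal emerged
#' (ToE <= horizon); models without emergence at a pixel are excluded there,
#' and a pixel with no emerged model is left NA. Even model counts give the
#' mean of the central pair (kept fractional; round only for display). The
#' inter-model spread is the s.d. over the same subset.
#'
#' @param toe_maps list of `nlat x nlon` ToE matrices, one per model
#'   (NA = not emerged).
#' @return list with matrices `median`, `sd`, `n_models_emerged`.
#' @export
ensemble_median <- function(toe_maps) {
  stopifnot(length(toe_maps) >= 1)
  d <- dim(toe_maps[[1]])
  for (m in toe_maps) if (!identical(dim(m), d))
    stop("all models must be on a common grid", call. = FALSE)
  arr <- simplify2array(toe_maps)           # nlat x nlon x nmod
  dim(arr) <- c(prod(d), length(toe_maps))
  med <- apply(arr, 1, stats::median, na.rm = TRUE)
  sdv <- apply(arr, 1, stats::sd, na.rm = TRUE)
  nem <- rowSums(!is.na(arr))
  sdv[nem == 1] <- 0
  list(median = matrix(med, d[1], d[2]),
       sd = matrix(sdv, d[1], d[2]),
       n_models_emerged = matrix(nem, d[1], d[2]))
}

#' Area-weighted median with interpolation at the 50% mass point
#'
#' @param x values; NAs dropped (with their weights).
#' @param w nonnegative weights.
#' @return the weighted median (midpoint convention: linear interpolation
#'   between order statistics at cumulative-mass positions
#'   `(cum(w) - w/2) / sum(w)`).
#' @export
weighted_median <- function(x, w) {
  keep <- !is.na(x) & !is.na(w) & w > 0
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(x[1])
  if (0.5 >= p[length(p)]) return(x[length(x)])
  stats::approx(p, x, xout = 0.5, ties = "ordered")$y
}

#' Global median time of emergence
#'
#' The area-weighted median ToE over emerged ocean pixels of the ensemble
#' map. The quoted uncertainty is the s.d. across models of each model's own
#' global median (not the spread of pixels).
#'
#' @param per_model_toe list of per-model ToE matrices.
#' @param lat grid latitudes (weights are `cos(lat)` of the cell center).
#' @param ocean_mask optional logical matrix, TRUE = ocean; default all TRUE.
#' @param weighted area-weight by `cos(lat)` (default) or count pixels
#'   equally.
#' @return list with `median` (from the ensemble-median map), `sd`
#'   (inter-model), and `per_model` medians.
#' @export
global_median_toe <- function(per_model_toe, lat, ocean_mask = NULL,
                              weighted = TRUE) {
  d <- dim(per_model_toe[[1]])
  if (is.null(ocean_mask)) ocean_mask <- matrix(TRUE, d[1], d[2])
  if (!any(ocean_mask)) stop("ocean mask is empty", call. = FALSE)
  w <- matrix(if (weighted) cos(lat * pi / 180) else 1, d[1], d[2])
  w[!ocean_mask] <- 0
  ens <- ensemble_median(per_model_toe)
  per_model <- vapply(per_model_toe, function(m) weighted_median(m, w),
                      numeric(1))
  list(median = weighted_median(ens$median, w),
       sd = stats::sd(per_model, na.rm = TRUE),
       per_model = per_model)
}

#' Multi-driver classification at a query year
#'
#' Per pixel, the subset of drivers whose ensemble ToE has passed by
#' `query_year` (the 16 possible subsets of four drivers are the mosaic
#' categories).
#'
#' @param toe_by_var named list of ensemble-median ToE matrices, one per
#'   driver variable (NA = never emerges there).
#' @param query_year the year of the mosaic.
#' @return an object of class `driver_mosaic`: list with `query_year`,
#'   `emerged` (named list of logical matrices), `n_drivers` (count matrix)
#'   and `label` (matrix of `+`-joined driver subsets, `""` = none).
#' @export
classify_drivers <- function(toe_by_var, query_year) {
  em <- lapply(toe_by_var, function(m) !is.na(m) & m <= query_year)
  d <- dim(em[[1]])
  n <- Reduce(`+`, lapply(em, function(x) x * 1L))
  lab <- matrix("", d[1], d[2])
  for (nm in names(em)) {
    lab[] <- ifelse(em[[nm]], ifelse(lab == "", nm, paste0(lab, "+", nm)), lab)
  }
  structure(list(query_year = query_year, emerged = em, n_drivers = n,
                 label = lab),
            class = "driver_mosaic")
}

#' Ocean fraction under multiple and quadruple driver emergence
#'
#' For each year, the percentage of ocean area whose emerged-driver subset
#' has size greater than one (`frac_multi`) and equal to the full driver set
#' (`frac_quad`). Area weights are `cos(latitude)` of the cell center,
#' normalized over ocean pixels (`weights = "equal"` counts pixels instead).
#'
#' @param toe_by_var named list of ToE matrices (typically ensemble medians).
#' @param lat grid latitudes.
#' @param years years of the curve, default 1900:2100.
#' @param weights `"coslat"` (default) or `"equal"`.
#' @param ocean_mask optional logical matrix, TRUE = ocean.
#' @return data.frame with `year`, `frac_multi`, `frac_quad` (percent).
#' @export
ocean_fraction_series <- function(toe_by_var, lat, years = 1900:2100,
                                  weights = c("coslat", "equal"),
                                  ocean_mask = NULL) {
  weights <- match.arg(weights)
  d <- dim(toe_by_var[[1]])
  if (is.null(ocean_mask)) ocean_mask <- matrix(TRUE, d[1], d[2])
  w <- matrix(if (weights == "coslat") cos(lat * pi / 180) else 1, d[1], d[2])
  w[!ocean_mask] <- 0
  wt <- sum(w)
  nvar <- length(toe_by_var)
  toes <- simplify2array(toe_by_var)
  dim(toes) <- c(prod(d), nvar)
  wv <- as.vector(w)
  frac_multi <- frac_quad <- numeric(length(years))
  for (i in seq_along(years)) {
    cnt <- rowSums(!is.na(toes) & toes <= years[i])
    frac_multi[i] <- 100 * sum(wv[cnt > 1]) / wt
    frac_quad[i] <- 100 * sum(wv[cnt == nvar]) / wt
  }
  data.frame(year = years, frac_multi = frac_multi, frac_quad = frac_quad)
}

#' Ocean-fraction curves with an inter-model band
#'
#' The central curve is the mean across the per-model fraction curves and the
#' band is plus/minus one s.d. across the same curves, so curve and band
#' summarize the same family. (A curve computed from the ensemble-median ToE
#' maps is available via [ocean_fraction_series()]; because the per-pixel
#' median excludes non-emerged models it can move against the per-model
#' curves in years where few models have emerged.)
#'
#' @param per_model_toe_by_var list (over models) of named lists (over
#'   variables) of ToE matrices.
#' @inheritParams ocean_fraction_series
#' @param scenario scenario label carried into the output.
#' @return data.frame with `year`, `frac_multi`, `frac_quad`, `sd_multi`,
#'   `sd_quad`, `scenario`.
#' @export
ocean_fraction_ensemble <- function(per_model_toe_by_var, lat,
                                    years = 1900:2100,
                                    weights = "coslat", ocean_mask = NULL,
                                    scenario = "") {
  per <- lapply(per_model_toe_by_var, function(maps)
    ocean_fraction_series(maps, lat, years, weights, ocean_mask))
  mm <- sapply(per, `[[`, "frac_multi")
  qq <- sapply(per, `[[`, "frac_quad")
  one <- length(per) == 1
  data.frame(year = years,
             frac_multi = if (one) mm else rowMeans(mm),
             frac_quad = if (one) qq else rowMeans(qq),
             sd_multi = if (one) 0 else apply(mm, 1, stats::sd),
             sd_quad = if (one) 0 else apply(qq, 1, stats::sd),
             scenario = scenario)
}
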