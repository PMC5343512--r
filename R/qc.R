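#' Lilliefors test of composite normality
#'
#' Kolmogorov-Smirnov distance between the empirical CDF and a normal CDF
#' with mean and s.d. estimated from the sample. Because the parameters are
#' estimated, the usual KS null distribution does not apply; p-values come
#' from a Monte-Carlo null table (default 10,000 standard-normal samples per
#' sample size, generated once per `n` under a fixed internal seed and
#' cached for the session).
#'
#' @param sample numeric vector, `n >= 5`, nonconstant.
#' @param alpha rejection level.
#' @param n_mc Monte-Carlo replicates for the null table.
#' @return an object of class `qc_test`: `statistic`, `p_value`, `alpha`,
#'   `reject`, `method`.
#' @export
lilliefors <- function(sample, alpha = 0.05, n_mc = 10000) {
  sample <- sample[!is.na(sample)]
  n <- length(sample)
  if (n < 5) stop("need at least 5 observations", call. = FALSE)
  if (stats::sd(sample) == 0)
    stop("degenerate sample: zero variance", call. = FALSE)
  stat <- lilliefors_stat(sample)
  null <- lilliefors_null(n, n_mc)
  p <- (1 + sum(null >= stat)) / (length(null) + 1)
  new_qc_test(stat, p, alpha, "lilliefors")
}

lilliefors_stat <- function(x) {
  n <- length(x)
  p <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

# Monte-Carlo null distribution of the statistic, cached per (n, n_mc)
.qc_cache <- new.env(parent = emptyenv())

lilliefors_null <- function(n, n_mc = 10000) {
  key <- paste0("lf_", n, "_", n_mc)
  if (!is.null(.qc_cache[[key]])) return(.qc_cache[[key]])
  null <- with_seed(substream_seed(20160307, "lilliefors-null", n, n_mc), {
    z <- matrix(stats::rnorm(n * n_mc), n, n_mc)
    z <- apply(z, 2, sort)
    m <- colMeans(z)
    s <- sqrt((colSums(z^2) - n * m^2) / (n - 1))
    p <- stats::pnorm((z - rep(m, each = n)) / rep(s, each = n))
    i <- seq_len(n)
    apply(pmax(i / n - p, p - (i - 1) / n), 2, max)
  })
  .qc_cache[[key]] <- null
  null
}

#' Breusch-Pagan test of heteroskedasticity
#'
#' Lagrange-multiplier statistic `n * R^2` of the auxiliary regression of
#' squared residuals on the regressor (here: time, the only covariate of the
#' trend model), referred to a chi-square distribution with one degree of
#' freedom (the studentized form, robust to non-normality).
#'
#' @param residuals residuals from the trend regression.
#' @param regressor matching covariate values (time), same length,
#'   `n >= 10`.
#' @param alpha rejection level.
#' @return a `qc_test`.
#' @export
breusch_pagan <- function(residuals, regressor, alpha = 0.05) {
  stopifnot(length(residuals) == length(regressor))
  n <- length(residuals)
  if (n < 10) stop("need at least 10 observations", call. = FALSE)
  u <- residuals^2
  if (stats::var(u) == 0)
    return(new_qc_test(0, 1, alpha, "breusch_pagan"))
  aux <- stats::lm.fit(cbind(1, regressor), u)
  r2 <- 1 - sum(aux$residuals^2) / sum((u - mean(u))^2)
  stat <- n * r2
  new_qc_test(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE),
              alpha, "breusch_pagan")
}

new_qc_test <- function(stat, p, alpha, method) {
  structure(list(statistic = unname(stat), p_value = unname(p),
                 alpha = alpha, reject = p < alpha, method = method),
            class = "qc_test")
}

#' @export
print.qc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s at alpha = %g)\n",
              x$method, x$statistic, x$p_value,
              if (x$reject) "reject" else "pass", x$alpha))
  invisible(x)
}

#' Fraction of pixels passing a QC test
#'
#' @param results a list of `qc_test` objects, or a logical vector of
#'   rejections.
#' @return percent of tests not rejected.
#' @export
pass_fraction <- function(results) {
  rej <- if (is.logical(results)) results
  else vapply(results, function(r) isTRUE(r$reject), logical(1))
  if (length(rej) == 0) stop("no test results supplied", call. = FALSE)
  100 * mean(!rej)
}
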