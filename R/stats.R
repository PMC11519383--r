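# Group comparison and correlation summaries for per-sample metrics.

#' Paired-difference t-test between matched sites
#'
#' Classical paired t-test on per-donor metric pairs (e.g. irradiated vs
#' non-irradiated sites of the same donor): with differences `d = a - b`,
#' `t = mean(d) / (sd(d) / sqrt(n))` and a two-tailed p-value on `n - 1`
#' degrees of freedom. Identical vectors return a zero statistic and an
#' undefined (NA) p-value; a non-zero constant difference has zero variance
#' and no valid t statistic, which is an error.
#'
#' @param values_a,values_b equal-length paired numeric vectors, `n >= 2`.
#' @return list with `statistic`, `p_value` (two-tailed), `n`, `df`,
#'   `mean_difference`.
#' @export
paired_difference <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  n <- length(values_a)
  if (n < 2) stop("at least 2 pairs are required", call. = FALSE)
  if (any(!is.finite(values_a)) || any(!is.finite(values_b))) {
    stop("paired values must be finite", call. = FALSE)
  }
  d <- values_a - values_b
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) {
      return(list(statistic = 0, p_value = NA_real_, n = n, df = n - 1,
                  mean_difference = 0))
    }
    stop("degenerate test: differences have zero variance", call. = FALSE)
  }
  tstat <- md / (sdd / sqrt(n))
  list(
    statistic = tstat,
    p_value = 2 * stats::pt(-abs(tstat), df = n - 1),
    n = n, df = n - 1,
    mean_difference = md
  )
}

#' Pearson correlation of a metric with time since radiotherapy
#'
#' Product-moment correlation with the two-tailed p-value from the t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))`, as used to test whether a
#' functional readout tracks the months elapsed since irradiation.
#'
#' @param metric per-sample metric values, `n >= 3`, finite.
#' @param months_since_rt per-sample covariate (months), same length.
#' @return list with `r`, `p_value`, `n`.
#' @export
correlation_with_time <- function(metric, months_since_rt) {
  if (length(metric) != length(months_since_rt)) {
    stop("`metric` and `months_since_rt` must have equal length",
         call. = FALSE)
  }
  n <- length(metric)
  if (n < 3) stop("at least 3 samples are required", call. = FALSE)
  if (any(!is.finite(metric)) || any(!is.finite(months_since_rt))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (stats::sd(metric) == 0 || stats::sd(months_since_rt) == 0) {
    stop("degenerate input: correlation undefined for constant vectors",
         call. = FALSE)
  }
  ct <- stats::cor.test(metric, months_since_rt, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}
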