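# Wound contraction/closure percentages and one-phase-decay fits.

#' Wound contraction percentage
#'
#' `(IW_D0 - IW_t) / IW_D0 * 100`: the shrinkage of the area enclosed by the
#' initial wound edge, relative to baseline. 0% at day 0 by construction,
#' +100% at full closure.
#'
#' @param iw_t inner-wound area at the timepoint (same units as `iw_d0`),
#'   vectorised.
#' @param iw_d0 inner-wound area at day 0, `> 0`.
#' @return contraction in percent.
#' @export
wound_contraction <- function(iw_t, iw_d0) {
  if (length(iw_d0) != 1 || !is.finite(iw_d0) || iw_d0 <= 0) {
    stop("`iw_d0` must be a single positive area", call. = FALSE)
  }
  if (any(iw_t < 0)) stop("`iw_t` must be non-negative", call. = FALSE)
  (iw_d0 - iw_t) / iw_d0 * 100
}

#' Wound closure percentage
#'
#' `area_t / area_d0 * 100`: the open wound area relative to day 0. 100% at
#' baseline, falling to 0% at full closure.
#'
#' @param area_t wound area at the timepoint, vectorised.
#' @param area_d0 wound area at day 0, `> 0`.
#' @return closure measure in percent.
#' @export
wound_closure <- function(area_t, area_d0) {
  if (length(area_d0) != 1 || !is.finite(area_d0) || area_d0 <= 0) {
    stop("`area_d0` must be a single positive area", call. = FALSE)
  }
  if (any(area_t < 0)) stop("`area_t` must be non-negative", call. = FALSE)
  area_t / area_d0 * 100
}

# coerce a wound_series / data.frame to (time, y) for the chosen variable
.kinetics_xy <- function(series, fit_variable) {
  df <- as.data.frame(series)
  tcol <- intersect(c("time", "day"), names(df))[1]
  if (is.na(tcol) || !"area" %in% names(df)) {
    stop("series must have columns `time` (or `day`) and `area`",
         call. = FALSE)
  }
  t <- df[[tcol]]
  y <- df$area
  o <- order(t)
  t <- t[o]; y <- y[o]
  if (fit_variable == "contraction_complement") {
    if (y[1] <= 0) stop("baseline area must be positive to fit percentages",
                        call. = FALSE)
    y <- wound_closure(y, y[1]) # 100 - contraction%
  }
  list(t = t, y = y)
}

#' Fit a one-phase exponential decay to a wound-closure series
#'
#' Bounded Levenberg-Marquardt least squares of
#' `Y(t) = plateau + (Y0 - plateau) * exp(-k * t)` with `k >= 0` and
#' `plateau >= 0` (via \pkg{minpack.lm}). Initialisation: `Y0` from the
#' first observation, `plateau` from the minimum, and `k` from the slope of
#' a log-linear regression of `Y - 0.99 * plateau_init` on time — decay fits
#' on half a dozen points are sensitive to starting values, so the
#' initialisation is deterministic and data-driven. Convergence tolerance
#' 1e-8 on the parameters.
#'
#' @param series a `wound_series` from [generate_wound_series()], or any
#'   data.frame with columns `time` (or `day`) and `area`.
#' @param fit_variable `"area"` (default) fits the raw inner-wound area;
#'   `"contraction_complement"` fits the percentage of the baseline area
#'   still open (100 at day 0), i.e. 100 minus the contraction percentage.
#' @param fix_plateau optional known plateau; when given, only `Y0` and `k`
#'   are estimated.
#' @return a `decay_fit`: list with `Y0`, `plateau`, `k` (per day),
#'   `half_life` (`log(2)/k` days, `Inf` when `k = 0`), `rss`, `converged`,
#'   `fitted`, `fit_variable`, `n`.
#' @examples
#' ws <- generate_wound_series(wound_series_params(noise_sd = 0))
#' fit_one_phase_decay(ws)
#' @export
fit_one_phase_decay <- function(series,
                                fit_variable = c("area",
                                                 "contraction_complement"),
                                fix_plateau = NULL) {
  fit_variable <- match.arg(fit_variable)
  xy <- .kinetics_xy(series, fit_variable)
  t <- xy$t; y <- xy$y
  if (length(t) < 3) stop("at least 3 timepoints are required", call. = FALSE)
  if (diff(range(t)) <= 0) stop("times must span a positive range",
                                call. = FALSE)

  y0_init <- y[1]
  pl_init <- if (is.null(fix_plateau)) min(y) else fix_plateau
  resid0 <- pmax(y - 0.99 * pl_init, .Machine$double.eps)
  slope <- stats::coef(stats::lm(log(resid0) ~ t))[2]
  k_init <- max(-slope, 1e-6)

  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8, maxiter = 500)
  df <- data.frame(t = t, y = y)
  fit <- tryCatch({
    if (is.null(fix_plateau)) {
      minpack.lm::nlsLM(
        y ~ plateau + (Y0 - plateau) * exp(-k * t), data = df,
        start = list(Y0 = y0_init, plateau = pl_init, k = k_init),
        lower = c(Y0 = -Inf, plateau = 0, k = 0), control = ctrl
      )
    } else {
      minpack.lm::nlsLM(
        y ~ fix_plateau + (Y0 - fix_plateau) * exp(-k * t), data = df,
        start = list(Y0 = y0_init, k = k_init),
        lower = c(Y0 = -Inf, k = 0), control = ctrl
      )
    }
  }, error = function(e) NULL)

  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    Y0 <- unname(cf["Y0"])
    plateau <- if (is.null(fix_plateau)) unname(cf["plateau"]) else fix_plateau
    k <- unname(cf["k"])
    converged <- isTRUE(fit$convInfo$isConv)
    fitted_vals <- as.numeric(stats::fitted(fit))
  } else {
    # optimiser failed outright: fall back to bounded quasi-Newton on the
    # same objective and report the best iterate without raising
    obj <- function(p) {
      pl <- if (is.null(fix_plateau)) p[2] else fix_plateau
      k <- p[length(p)]
      sum((y - (pl + (p[1] - pl) * exp(-k * t)))^2)
    }
    par0 <- if (is.null(fix_plateau)) c(y0_init, pl_init, k_init)
            else c(y0_init, k_init)
    lower <- if (is.null(fix_plateau)) c(-Inf, 0, 0) else c(-Inf, 0)
    op <- stats::optim(par0, obj, method = "L-BFGS-B", lower = lower)
    Y0 <- op$par[1]
    plateau <- if (is.null(fix_plateau)) op$par[2] else fix_plateau
    k <- op$par[length(op$par)]
    converged <- FALSE
    fitted_vals <- plateau + (Y0 - plateau) * exp(-k * t)
  }

  structure(
    list(
      Y0 = Y0, plateau = plateau, k = k,
      half_life = if (k > 0) log(2) / k else Inf,
      rss = sum((y - fitted_vals)^2),
      converged = converged,
      fitted = data.frame(time = t, observed = y, fitted = fitted_vals),
      fit_variable = fit_variable,
      n = length(t)
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    paste0("one-phase decay fit (%s, n = %d)\n",
           "  Y0 = %.4g, plateau = %.4g, k = %.4g /day",
           " (half-life %.3g days)\n  rss = %.4g, converged: %s\n"),
    x$fit_variable, x$n, x$Y0, x$plateau, x$k, x$half_life, x$rss,
    x$converged
  ))
  invisible(x)
}

#' Fit decay kinetics for every series in a table
#'
#' @param data data.frame (or CSV path) with columns `label`, `time` (or
#'   `day`), `area`.
#' @param fit_variable passed to [fit_one_phase_decay()].
#' @return data.frame with one row per label: `label`, `Y0`, `plateau`,
#'   `k_per_day`, `half_life_days`, `rss`, `converged`.
#' @export
fit_kinetics_table <- function(data, fit_variable = "area") {
  if (is.character(data)) data <- utils::read.csv(data)
  if (!"label" %in% names(data)) data$label <- "series"
  out <- lapply(split(data, data$label), function(d) {
    f <- fit_one_phase_decay(d, fit_variable = fit_variable)
    data.frame(label = d$label[1], Y0 = f$Y0, plateau = f$plateau,
               k_per_day = f$k, half_life_days = f$half_life, rss = f$rss,
               converged = f$converged)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
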