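# Collagen isolation in CIELAB and grayscale enhancement.

#' Isolate the collagen signal from a CIELAB image
#'
#' In Masson's trichrome sections the aniline-blue collagen carries strongly
#' negative b* values. The default mode superimposes the full a* channel
#' onto the rectified negative b* channel by pixel-wise addition,
#' `C = max(a + max(-b, 0), 0)`, so intensity grows monotonically with
#' blueness while near-neutral background maps to ~0. Two alternative
#' readings of the channel superimposition are selectable:
#'
#' * `"negb_only"`: `C = max(-b, 0)` (blueness alone);
#' * `"negb_minus_posa"`: `C = max(max(-b, 0) - max(a, 0), 0)` (blueness
#'   penalised by redness, suppressing red cytoplasm).
#'
#' @param lab a `lab_image` from [rgb_to_lab()].
#' @param mode isolation mode, one of `"a_plus_negb"` (default),
#'   `"negb_only"`, `"negb_minus_posa"`.
#' @return a `collagen_map`: list with `values` (non-negative matrix in
#'   a*/b* channel units) and `mode`.
#' @export
isolate_collagen <- function(lab,
                             mode = c("a_plus_negb", "negb_only",
                                      "negb_minus_posa")) {
  stopifnot(inherits(lab, "lab_image"))
  if (is.character(mode) && length(mode) == 1 &&
      !mode %in% c("a_plus_negb", "negb_only", "negb_minus_posa")) {
    stop(sprintf("unknown isolation mode '%s'", mode), call. = FALSE)
  }
  mode <- match.arg(mode)
  negb <- pmax(-lab$b, 0)
  values <- switch(mode,
    a_plus_negb = pmax(lab$a + negb, 0),
    negb_only = negb,
    negb_minus_posa = pmax(negb - pmax(lab$a, 0), 0)
  )
  structure(list(values = values, mode = mode), class = "collagen_map")
}

#' Enhance a collagen map to a zero-floored grayscale image
#'
#' Gaussian smoothing, a linear contrast stretch mapping the `p_low` /
#' `p_high` percentiles to 0 / 1 (clipped), and a zero floor that sets
#' values below `zero_floor` to exactly 0. The exact zeros matter: the
#' density metric downstream counts the fraction of non-zero pixels, so the
#' background must end up at identically zero. A constant input has no
#' contrast to stretch and maps to an all-zero image.
#'
#' @param cmap a `collagen_map` (or bare numeric matrix).
#' @param p_low,p_high stretch percentiles in `[0, 100]`, `p_low < p_high`.
#' @param smooth_sigma Gaussian smoothing SD in pixels (0 disables).
#' @param zero_floor fraction in `[0, 1)`; output below it becomes 0.
#' @return an `enhanced_image`: list with `values` (matrix in `[0, 1]`),
#'   `zero_floor`, and `provenance` (the parameters used).
#' @export
enhance <- function(cmap, p_low = 1, p_high = 99, smooth_sigma = 1,
                    zero_floor = 0.1) {
  values <- if (inherits(cmap, "collagen_map")) cmap$values else cmap
  if (!is.matrix(values)) stop("`cmap` must be a collagen map or matrix",
                               call. = FALSE)
  if (p_low >= p_high) {
    stop("`p_low` must be strictly less than `p_high`", call. = FALSE)
  }
  if (zero_floor < 0 || zero_floor >= 1) {
    stop("`zero_floor` must lie in [0, 1)", call. = FALSE)
  }
  if (smooth_sigma < 0) stop("`smooth_sigma` must be >= 0", call. = FALSE)

  v <- values
  if (smooth_sigma > 0) {
    v <- EBImage::gblur(v, sigma = smooth_sigma)
  }
  q <- stats::quantile(v, c(p_low, p_high) / 100, names = FALSE)
  if (q[2] - q[1] <= .Machine$double.eps * max(abs(q), 1)) {
    v[] <- 0
  } else {
    v <- .clamp((v - q[1]) / (q[2] - q[1]), 0, 1)
    v[v < zero_floor] <- 0
  }
  structure(
    list(
      values = v, zero_floor = zero_floor,
      provenance = list(p_low = p_low, p_high = p_high,
                        smooth_sigma = smooth_sigma, zero_floor = zero_floor)
    ),
    class = "enhanced_image"
  )
}

#' @export
print.enhanced_image <- function(x, ...) {
  cat(sprintf(
    "enhanced image %d x %d, %.1f%% non-zero (zero floor %.2f)\n",
    nrow(x$values), ncol(x$values), 100 * mean(x$values > 0), x$zero_floor
  ))
  invisible(x)
}
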