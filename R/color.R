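# sRGB <-> CIELAB conversion (D65, standard companding).
#
# Implemented from the sRGB standard directly so that channel values match
# the reference colorimetric pipeline to machine precision; the a*/b*
# thresholds used for collagen isolation are calibrated against these exact
# values.

# linear-RGB <-> XYZ matrix for sRGB primaries, D65 white
.rgb2xyz <- matrix(c(
  0.412453, 0.357580, 0.180423,
  0.212671, 0.715160, 0.072169,
  0.019334, 0.119193, 0.950227
), nrow = 3, byrow = TRUE)
.xyz2rgb <- solve(.rgb2xyz)
.white_d65 <- rowSums(.rgb2xyz) # XYZ of sRGB white

.srgb_decompand <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}

.srgb_compand <- function(u) {
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.lab_finv <- function(f) {
  d <- 6 / 29
  ifelse(f > d, f^3, 3 * d^2 * (f - 4 / 29))
}

# m: n x 3 matrix of sRGB in [0, 1]
.srgb_to_lab_mat <- function(m) {
  xyz <- .srgb_decompand(m) %*% t(.rgb2xyz)
  fx <- .lab_f(xyz[, 1] / .white_d65[1])
  fy <- .lab_f(xyz[, 2] / .white_d65[2])
  fz <- .lab_f(xyz[, 3] / .white_d65[3])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

.lab_to_srgb_mat <- function(m) {
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(
    .lab_finv(fx) * .white_d65[1],
    .lab_finv(fy) * .white_d65[2],
    .lab_finv(fz) * .white_d65[3]
  )
  lin <- xyz %*% t(.xyz2rgb)
  pmin(pmax(.srgb_compand(pmin(pmax(lin, 0), 1)), 0), 1)
}

#' Convert an sRGB histology image to CIELAB
#'
#' Applies the standard sRGB decompanding (D65 white point) followed by the
#' CIE XYZ -> L*a*b* transform, per pixel. 16-bit inputs are rescaled to the
#' 8-bit range before conversion so that Lab magnitudes are calibrated
#' identically for all bit depths.
#'
#' @param image numeric `H x W x 3` array of sRGB values on the 8-bit scale
#'   (0-255) or 16-bit scale (0-65535; detected when values exceed 255).
#' @return a `lab_image`: list with matrices `L` (0-100), `a` and `b`
#'   (signed opponent channels), each of the source raster shape.
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' rgb_to_lab(px) # L ~ 53.24, a ~ 80.09, b ~ 67.20
#' @export
rgb_to_lab <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("`image` must be an H x W x 3 RGB array", call. = FALSE)
  }
  if (any(!is.finite(image)) || any(image < 0)) {
    stop("`image` must contain finite, non-negative intensities", call. = FALSE)
  }
  scale <- if (max(image) > 255) 65535 else 255
  d <- dim(image)[1:2]
  m <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3])) / scale
  lab <- .srgb_to_lab_mat(m)
  structure(
    list(
      L = matrix(lab[, 1], d[1], d[2]),
      a = matrix(lab[, 2], d[1], d[2]),
      b = matrix(lab[, 3], d[1], d[2])
    ),
    class = "lab_image"
  )
}

#' Convert a CIELAB image back to 8-bit sRGB
#'
#' Inverse of [rgb_to_lab()]; out-of-gamut values are clipped. Round-tripping
#' an 8-bit image reproduces it within one quantization level per channel.
#'
#' @param lab a `lab_image` as returned by [rgb_to_lab()].
#' @return numeric `H x W x 3` array on the 8-bit scale (0-255), rounded.
#' @export
lab_to_rgb <- function(lab) {
  stopifnot(inherits(lab, "lab_image"))
  d <- dim(lab$L)
  m <- cbind(as.vector(lab$L), as.vector(lab$a), as.vector(lab$b))
  rgb <- .lab_to_srgb_mat(m) * 255
  array(round(rgb), dim = c(d, 3L))
}

#' @export
print.lab_image <- function(x, ...) {
  cat(sprintf(
    "CIELAB image %d x %d  (L: %.1f-%.1f, a: %.1f-%.1f, b: %.1f-%.1f)\n",
    nrow(x$L), ncol(x$L), min(x$L), max(x$L),
    min(x$a), max(x$a), min(x$b), max(x$b)
  ))
  invisible(x)
}

# single colour (length-3 sRGB 0-255) -> named Lab vector; used by the
# simulator's construction-time stain checks
.color_to_lab <- function(rgb255) {
  lab <- unname(.srgb_to_lab_mat(matrix(rgb255 / 255, 1, 3)))
  c(L = lab[1, 1], a = lab[1, 2], b = lab[1, 3])
}
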