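# Synthetic trichrome-like fiber fields and wound-closure series.
#
# The generator emulates the geometry that matters to the downstream
# analysis -- blue-dominant (negative b*) collagen fibers with a controlled
# axial orientation distribution over a pale background, plus optional red
# (positive a*) cytoplasm-like distractors -- not histological texture.

#' Parameters of a simulated fiber field
#'
#' Fiber axes are undirected, so orientations are drawn on the doubled
#' angle: `phi ~ vonMises(2 * mean_orientation, kappa)` and
#' `theta = (phi / 2) mod pi`. `kappa = 0` gives isotropic fields;
#' large `kappa` gives near-perfect alignment along `mean_orientation`.
#'
#' Colours are validated at construction against the CIELAB contract the
#' collagen-isolation stage relies on: the collagen colour must have
#' `b* < 0` (trichrome aniline blue) and the background must be near-neutral
#' (`|a*|, |b*| < 5`).
#'
#' @param image_size side of the square canvas, pixels.
#' @param n_fibers number of fibers drawn.
#' @param mean_orientation mean fiber axis, radians in `[0, pi)`.
#' @param kappa non-negative von Mises concentration on the doubled angle.
#' @param fiber_length,fiber_width fiber dimensions in pixels.
#' @param collagen_color,background_color,red_color sRGB triples (0-255).
#' @param n_red_blobs number of disk-shaped red distractors.
#' @param red_blob_radius distractor radius, pixels.
#' @param noise_sd additive Gaussian noise SD in 8-bit intensity units.
#' @param seed integer RNG seed; all randomness flows from it.
#' @return a validated `fiber_field_params` list.
#' @export
fiber_field_params <- function(image_size = 512L,
                               n_fibers = 300L,
                               mean_orientation = pi / 4,
                               kappa = 2,
                               fiber_length = 120,
                               fiber_width = 3,
                               collagen_color = c(60, 90, 200),
                               background_color = c(240, 238, 242),
                               n_red_blobs = 0L,
                               red_color = c(200, 60, 80),
                               red_blob_radius = 8,
                               noise_sd = 3,
                               seed = 0L) {
  if (length(image_size) != 1L || image_size < 8 || image_size != round(image_size)) {
    stop("`image_size` must be a single integer >= 8 (square canvas)",
         call. = FALSE)
  }
  if (n_fibers < 0 || n_red_blobs < 0) {
    stop("fiber and blob counts must be non-negative", call. = FALSE)
  }
  if (kappa < 0) stop("`kappa` must be non-negative", call. = FALSE)
  if (mean_orientation < 0 || mean_orientation >= pi) {
    stop("`mean_orientation` must lie in [0, pi)", call. = FALSE)
  }
  if (fiber_length <= 0 || fiber_width <= 0 || red_blob_radius <= 0) {
    stop("fiber/blob dimensions must be positive", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  for (col in list(collagen_color, background_color, red_color)) {
    if (length(col) != 3L || any(col < 0) || any(col > 255)) {
      stop("colors must be sRGB triples within [0, 255]", call. = FALSE)
    }
  }
  lab_col <- .color_to_lab(collagen_color)
  if (lab_col[["b"]] >= 0) {
    stop("`collagen_color` must be blue-dominant (b* < 0 in CIELAB)",
         call. = FALSE)
  }
  lab_bg <- .color_to_lab(background_color)
  if (abs(lab_bg[["a"]]) >= 5 || abs(lab_bg[["b"]]) >= 5) {
    stop("`background_color` must be near-neutral (|a*|, |b*| < 5)",
         call. = FALSE)
  }
  structure(
    list(
      image_size = as.integer(image_size), n_fibers = as.integer(n_fibers),
      mean_orientation = mean_orientation, kappa = kappa,
      fiber_length = fiber_length, fiber_width = fiber_width,
      collagen_color = collagen_color, background_color = background_color,
      n_red_blobs = as.integer(n_red_blobs), red_color = red_color,
      red_blob_radius = red_blob_radius, noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "fiber_field_params"
  )
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` reduces to the circular
#' uniform. (No circular-statistics package ships with the supported stack,
#' so the standard sampler is provided here.)
#'
#' @param n sample size.
#' @param mu mean direction, radians.
#' @param kappa concentration, `>= 0`.
#' @return angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 0) stop("`kappa` must be non-negative", call. = FALSE)
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nok <- sum(ok)
    if (nok > 0) {
      th <- sign(u3[ok] - 0.5) * acos(f[ok]) + mu
      out[got + seq_len(nok)] <- th %% (2 * pi)
      got <- got + nok
    }
  }
  out
}

# accumulate anti-aliased coverage of a capsule (segment with round caps of
# radius w/2) into `cov`, restricted to the segment's bounding box
.draw_segment <- function(cov, cx, cy, theta, len, width) {
  d <- dim(cov)
  ux <- cos(theta); uy <- sin(theta)
  h <- len / 2
  p1x <- cx - h * ux; p1y <- cy - h * uy
  p2x <- cx + h * ux; p2y <- cy + h * uy
  pad <- width / 2 + 1.5
  r0 <- max(1L, floor(min(p1y, p2y) - pad))
  r1 <- min(d[1], ceiling(max(p1y, p2y) + pad))
  c0 <- max(1L, floor(min(p1x, p2x) - pad))
  c1 <- min(d[2], ceiling(max(p1x, p2x) + pad))
  if (r0 > r1 || c0 > c1) return(cov)
  rows <- r0:r1; cols <- c0:c1
  px <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  py <- matrix(rows, length(rows), length(cols))
  t <- .clamp(((px - p1x) * ux + (py - p1y) * uy) / len, 0, 1)
  dx <- px - (p1x + t * len * ux)
  dy <- py - (p1y + t * len * uy)
  dist <- sqrt(dx * dx + dy * dy)
  a <- .clamp(width / 2 + 0.5 - dist, 0, 1) # linear edge over one pixel
  cov[rows, cols] <- pmax(cov[rows, cols], a)
  cov
}

.draw_disk <- function(cov, cx, cy, radius) {
  .draw_segment(cov, cx, cy, 0, 1e-9, 2 * radius)
}

#' Generate a trichrome-like fiber-field image with known ground truth
#'
#' Draws `n_fibers` anti-aliased straight segments with centres uniform in
#' the frame and axial von Mises orientations, composited in the collagen
#' colour over the background; red blobs are drawn on top, then clipped
#' Gaussian noise is added and the raster quantised to 8 bits. Identical
#' parameters (including seed) give byte-identical output.
#'
#' @param params a [fiber_field_params()] object.
#' @return list with `image` (`H x W x 3` array, 0-255) and `truth`
#'   (list: `orientations`, the sampled fiber axes in `[0, pi)`, and
#'   `fiber_mask`, logical raster of pixels with fiber coverage >= 0.5).
#' @examples
#' sim <- generate_fiber_image(fiber_field_params(image_size = 64,
#'                                                n_fibers = 20, seed = 1))
#' true_alignment(sim$truth$orientations)
#' @export
generate_fiber_image <- function(params) {
  stopifnot(inherits(params, "fiber_field_params"))
  p <- params
  .with_seed(p$seed, {
    S <- p$image_size
    theta <- if (p$n_fibers > 0) {
      (rvonmises(p$n_fibers, 2 * p$mean_orientation, p$kappa) / 2) %% pi
    } else numeric(0)
    cx <- stats::runif(p$n_fibers, 1, S)
    cy <- stats::runif(p$n_fibers, 1, S)

    cov <- matrix(0, S, S)
    for (j in seq_len(p$n_fibers)) {
      cov <- .draw_segment(cov, cx[j], cy[j], theta[j],
                           p$fiber_length, p$fiber_width)
    }
    img <- array(0, dim = c(S, S, 3L))
    for (ch in 1:3) {
      img[, , ch] <- cov * p$collagen_color[ch] +
        (1 - cov) * p$background_color[ch]
    }

    if (p$n_red_blobs > 0) {
      bx <- stats::runif(p$n_red_blobs, 1, S)
      by <- stats::runif(p$n_red_blobs, 1, S)
      bcov <- matrix(0, S, S)
      for (j in seq_len(p$n_red_blobs)) {
        bcov <- .draw_disk(bcov, bx[j], by[j], p$red_blob_radius)
      }
      for (ch in 1:3) {
        img[, , ch] <- bcov * p$red_color[ch] + (1 - bcov) * img[, , ch]
      }
    }

    if (p$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), sd = p$noise_sd)
    }
    img <- .clamp(round(img), 0, 255)

    list(
      image = img,
      truth = list(orientations = theta, fiber_mask = cov >= 0.5)
    )
  })
}

#' Ground-truth alignment of a set of fiber axes
#'
#' Circular resultant length on doubled angles,
#' `R = | mean(exp(2i * theta)) |`: the reference statistic the image-based
#' alignment coefficient is calibrated against. 0 for a balanced (random)
#' axial distribution, 1 when all axes coincide.
#'
#' @param orientations non-empty vector of fiber axes, radians.
#' @return alignment in `[0, 1]`.
#' @examples
#' true_alignment(c(0, pi / 4)) # sqrt(2)/2
#' @export
true_alignment <- function(orientations) {
  if (length(orientations) == 0) {
    stop("`orientations` must be non-empty", call. = FALSE)
  }
  Mod(mean(exp(2i * orientations)))
}

#' Parameters of a simulated wound-closure series
#'
#' One-phase exponential decay of inner-wound area,
#' `Y(t) = plateau + (Y0 - plateau) * exp(-k * t)`, observed at `times`
#' with additive Gaussian noise. Defaults follow a 6-day ex vivo healing
#' course: day 0-5 daily measurements, a wound that shrinks from 10 to an
#' asymptote of 2 area units at rate 0.8/day, with 2% measurement noise.
#'
#' @param Y0 initial inner-wound area (>= plateau).
#' @param plateau asymptotic area, >= 0.
#' @param k decay rate per day, >= 0.
#' @param times observation days, strictly increasing, starting at 0.
#' @param noise_sd Gaussian noise SD on the area.
#' @param seed integer RNG seed.
#' @return a validated `wound_series_params` list.
#' @export
wound_series_params <- function(Y0 = 10, plateau = 2, k = 0.8,
                                times = 0:5, noise_sd = 0.2, seed = 0L) {
  if (!(Y0 >= plateau && plateau >= 0)) {
    stop("require Y0 >= plateau >= 0", call. = FALSE)
  }
  if (k < 0) stop("`k` must be non-negative", call. = FALSE)
  if (length(times) < 1 || times[1] != 0 || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing and start at 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(
    list(Y0 = Y0, plateau = plateau, k = k, times = times,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "wound_series_params"
  )
}

#' Simulate a noisy wound-closure time series
#'
#' @param params a [wound_series_params()] object.
#' @param label sample identifier carried into the output.
#' @return a `wound_series`: data.frame with columns `time` (days) and
#'   `area` (>= 0, noise clipped at zero), with attribute `label`.
#' @export
generate_wound_series <- function(params, label = "sim") {
  stopifnot(inherits(params, "wound_series_params"))
  p <- params
  .with_seed(p$seed, {
    y <- p$plateau + (p$Y0 - p$plateau) * exp(-p$k * p$times)
    if (p$noise_sd > 0) y <- y + stats::rnorm(length(y), sd = p$noise_sd)
    out <- data.frame(time = p$times, area = pmax(y, 0))
    attr(out, "label") <- label
    class(out) <- c("wound_series", "data.frame")
    out
  })
}
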