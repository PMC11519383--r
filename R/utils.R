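# shared raster helpers

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# DFT sample frequencies in cycles/pixel, fft ordering
.fft_freq <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k <= n %/% 2 - (n %% 2 == 0), k, k - n) / n
}

# run RNG-consuming code under a fixed seed without disturbing the caller's
# RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.assert_rgb <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop(sprintf("`%s` must be an H x W x 3 RGB array", arg), call. = FALSE)
  }
  invisible(image)
}

#' Read an RGB image from PNG or TIFF
#'
#' @param path file path (8- or 16-bit RGB; an alpha channel, if present, is
#'   dropped).
#' @return numeric `H x W x 3` array on the 8-bit scale (0-255).
#' @export
read_rgb <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) {
    a <- array(rep(a, 3L), dim = c(dim(a), 3L)) # grayscale promoted
  }
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  # EBImage stores x (width) first; transpose to row = y convention
  round(aperm(a, c(2L, 1L, 3L)) * 255)
}

#' Write an RGB image to PNG or TIFF
#'
#' @param image numeric `H x W x 3` array on the 8-bit scale (0-255).
#' @param path output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(image, path) {
  .assert_rgb(image)
  img <- EBImage::Image(aperm(image / 255, c(2L, 1L, 3L)),
                        colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}

#' Rotate an RGB image about its centre
#'
#' Bilinear rotation (via \pkg{EBImage}) keeping the original raster size;
#' corners swept in from outside the frame are filled with `bg`. A positive
#' angle increases the spatial orientation reported by
#' [dominant_orientation()] by the same amount (mod pi).
#'
#' @param image numeric `H x W x 3` array, 8-bit scale.
#' @param degrees rotation angle in degrees.
#' @param bg length-3 sRGB fill colour for exposed corners (default white).
#' @return rotated `H x W x 3` array, 8-bit scale.
#' @export
rotate_rgb <- function(image, degrees, bg = c(255, 255, 255)) {
  .assert_rgb(image)
  d <- dim(image)
  out <- array(0, dim = d)
  for (ch in 1:3) {
    # channel matrices are y-by-x while EBImage rotates x-by-y rasters;
    # positive here = +theta in the package's orientation convention
    r <- EBImage::rotate(t(image[, , ch]), degrees,
                         output.dim = c(d[2], d[1]),
                         bg.col = bg[ch] / 255)
    out[, , ch] <- t(EBImage::imageData(r))
  }
  .clamp(round(out), 0, 255)
}

#' Crop the central region of an RGB image
#'
#' @param image numeric `H x W x 3` array.
#' @param size side length in pixels of the square crop.
#' @return `size x size x 3` array.
#' @export
crop_center <- function(image, size) {
  .assert_rgb(image)
  d <- dim(image)
  if (size > min(d[1:2])) stop("crop larger than image", call. = FALSE)
  r0 <- (d[1] - size) %/% 2
  c0 <- (d[2] - size) %/% 2
  image[r0 + seq_len(size), c0 + seq_len(size), , drop = FALSE]
}

#' Downsample an RGB image by an integer factor
#'
#' Block-average downsampling (each output pixel is the mean of a
#' `factor x factor` block).
#'
#' @param image numeric `H x W x 3` array.
#' @param factor integer decimation factor (dimensions must be divisible).
#' @return downsampled array on the same intensity scale.
#' @export
downsample_rgb <- function(image, factor = 2L) {
  .assert_rgb(image)
  d <- dim(image)
  if (any(d[1:2] %% factor != 0)) {
    stop("image dimensions must be divisible by `factor`", call. = FALSE)
  }
  h <- d[1] %/% factor
  w <- d[2] %/% factor
  out <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) {
    m <- image[, , ch]
    dim(m) <- c(factor, h, factor, w)
    out[, , ch] <- colMeans(aperm(m, c(1, 3, 2, 4)), dims = 2)
  }
  out
}
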