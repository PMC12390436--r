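## Image utilities shared by the synthetic generator, the augmentation modes
## and the SSIM deduplication filter. Grayscale images are numeric H x W
## matrices in [0, 1]; RGB images are H x W x 3 arrays. Geometric transforms
## go through EBImage (which stores images width-first, hence the transposes).

.ebi <- function(m) EBImage::Image(t(m))
.unebi <- function(img) t(EBImage::imageData(img))

#' @noRd
rotate_image <- function(m, angle_deg, bg = 0.5) {
  if (angle_deg == 0) return(m)
  img <- EBImage::rotate(.ebi(m), angle_deg, filter = "bilinear",
                         output.dim = c(ncol(m), nrow(m)), bg.col = bg)
  .unebi(img)
}

#' @noRd
translate_image <- function(m, dy, dx, bg = 0.5) {
  if (dy == 0 && dx == 0) return(m)
  img <- EBImage::translate(.ebi(m), c(dx, dy), bg.col = bg)
  .unebi(img)
}

#' @noRd
resize_image <- function(m, h, w) {
  if (nrow(m) == h && ncol(m) == w) return(m)
  .unebi(EBImage::resize(.ebi(m), w = w, h = h, filter = "bilinear"))
}

## 1-D gaussian kernel, truncated at `radius` taps each side
gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## separable gaussian blur with replicate (nearest) boundary handling
gaussian_blur <- function(m, sigma, radius = max(1L, ceiling(3 * sigma))) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel_1d(sigma, radius)
  m <- .conv1_replicate(m, k, 1L)
  .conv1_replicate(m, k, 2L)
}

## correlate a matrix with a 1-D kernel along rows (dim 1) or columns (dim 2),
## replicate padding, output same size
.conv1_replicate <- function(m, k, dim) {
  r <- (length(k) - 1L) %/% 2L
  n <- if (dim == 1L) nrow(m) else ncol(m)
  out <- matrix(0, nrow(m), ncol(m))
  for (t in seq_along(k)) {
    idx <- pmin(pmax(seq_len(n) + t - r - 1L, 1L), n)
    out <- out + k[t] * (if (dim == 1L) m[idx, , drop = FALSE] else m[, idx, drop = FALSE])
  }
  out
}

#' Structural similarity index (SSIM) between two grayscale images
#'
#' Mean SSIM with the standard 11x11 gaussian weighting window
#' (sigma = 1.5), weighted (population) covariances, and a border crop of
#' half the window so every retained window lies fully inside the image.
#' Matches the reference implementation used in image-processing toolkits
#' under the same settings.
#'
#' @param x,y numeric matrices of equal size with values in `[0, data_range]`.
#' @param data_range dynamic range of the data (1 for unit-scaled images).
#' @return scalar SSIM in `[-1, 1]`.
#' @export
ssim <- function(x, y, data_range = 1) {
  if (length(dim(x)) == 3L) x <- rgb_to_gray(x)
  if (length(dim(y)) == 3L) y <- rgb_to_gray(y)
  assert_that(is.matrix(x) && is.matrix(y), "ssim expects matrices or RGB arrays")
  assert_that(all(dim(x) == dim(y)), "ssim: images must have the same size")
  assert_that(min(dim(x)) >= 11L, "ssim: images must be at least 11x11")
  sigma <- 1.5; r <- 5L
  k <- gaussian_kernel_1d(sigma, r)
  f <- function(m) .conv1_replicate(.conv1_replicate(m, k, 1L), k, 2L)
  ux <- f(x); uy <- f(y)
  vxx <- f(x * x) - ux^2
  vyy <- f(y * y) - uy^2
  vxy <- f(x * y) - ux * uy
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  s <- ((2 * ux * uy + c1) * (2 * vxy + c2)) /
       ((ux^2 + uy^2 + c1) * (vxx + vyy + c2))
  core <- s[(r + 1L):(nrow(s) - r), (r + 1L):(ncol(s) - r)]
  mean(core)
}

#' @noRd
rgb_to_gray <- function(a) {
  if (is.matrix(a)) return(a)
  (a[, , 1] + a[, , 2] + a[, , 3]) / 3
}

gray_to_rgb <- function(m) array(rep(m, 3L), c(dim(m), 3L))

clip01 <- function(m) pmin(pmax(m, 0), 1)

#' Read / write images
#'
#' Thin wrappers over the PNG codec; images are returned as `H x W` matrices
#' (grayscale) or `H x W x 3` arrays in `[0, 1]`.
#' @param path file path.
#' @rdname image_io
#' @export
read_image <- function(path) {
  assert_that(file.exists(path), paste0("no such image: ", path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L && dim(a)[3] >= 3L) a <- a[, , 1:3, drop = FALSE]
  a
}

#' @param image matrix or array in `[0, 1]`.
#' @rdname image_io
#' @export
write_image <- function(image, path) {
  png::writePNG(clip01(image), path)
  invisible(path)
}
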