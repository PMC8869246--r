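# Linear filters: Gaussian smoothing, box (mean) smoothing, Laplacian
# sharpening.  All use replicate-edge borders and round back to integers.

#' Discrete 1-D Gaussian kernel
#'
#' Weights proportional to `exp(-d^2 / (2 sigma^2))` at integer offsets,
#' normalised to sum to one.  When `sigma` is not given it is derived from the
#' kernel size by the common convention
#' `sigma = 0.3 * ((k - 1)/2 - 1) + 0.8`, so the default smoothing scale is a
#' reproducible function of `k` alone.
#'
#' @param k Odd kernel size (>= 1).
#' @param sigma Standard deviation in pixels; `NULL` for the size-derived
#'   default.
#' @return Numeric vector of length `k` summing to 1.
#' @examples
#' gaussian_kernel(3)
#' @export
gaussian_kernel <- function(k, sigma = NULL) {
  if (length(k) != 1L || is.na(k) || k < 1 || k %% 2 == 0)
    stop("kernel size must be a positive odd integer", call. = FALSE)
  if (is.null(sigma)) sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  d <- seq_len(k) - (k + 1) / 2
  w <- exp(-d^2 / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian blur
#'
#' Convolution with the normalised, separable discrete Gaussian kernel,
#' replicate borders, rounded back to integers in 0..255.  Used with `k = 3`
#' to remove high-frequency noise before edge synthesis, and with larger
#' kernels by the blur-robustness protocol.
#'
#' @inheritParams gray_dilate
#' @param k Odd kernel size.
#' @param sigma Optional standard deviation override (see
#'   [gaussian_kernel()]).
#' @return Blurred integer image.
#' @examples
#' gaussian_blur(matrix(100L, 4, 4), 3)
#' @export
gaussian_blur <- function(img, k = 3, sigma = NULL) {
  assert_gray(img)
  w <- gaussian_kernel(k, sigma)
  out <- cpp_conv_sep(img + 0, w, w)
  as_int_img(clamp255(round_px(out)))
}

#' Mean (box) blur
#'
#' Convolution with the uniform `k` x `k` kernel (all weights `1/k^2`),
#' replicate borders.  The more destructive of the two blur perturbations: at
#' matched kernel size it removes more edge information than the
#' centre-weighted Gaussian.
#'
#' @inheritParams gaussian_blur
#' @return Blurred integer image.
#' @export
mean_blur <- function(img, k = 3) {
  assert_gray(img)
  if (length(k) != 1L || is.na(k) || k < 1 || k %% 2 == 0)
    stop("kernel size must be a positive odd integer", call. = FALSE)
  w <- rep(1 / k, k)
  out <- cpp_conv_sep(img + 0, w, w)
  as_int_img(clamp255(round_px(out)))
}

#' Laplacian sharpening
#'
#' Applies the standard 3x3 sharpening kernel
#' `[[0,-1,0],[-1,5,-1],[0,-1,0]]` with saturating arithmetic (clamped to
#' 0..255).  The kernel sums to one, so flat regions are unchanged; intensity
#' transitions — in the pipeline, the dim morphological edge image — are
#' amplified before Otsu binarization.
#'
#' @inheritParams gray_dilate
#' @return Sharpened integer image.
#' @examples
#' sharpen(matrix(128L, 3, 3))
#' @export
sharpen <- function(img) {
  assert_gray(img)
  ker <- matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3)
  out <- cpp_conv2(img + 0, ker)
  as_int_img(clamp255(round_px(out)))
}
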