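# Morphological edge synthesis — the pipeline's replacement for
# convolutional edge detectors (Canny, Sobel, ...).
#
# With dilation d = f (+) D and erosion e = f (-) D over a small SE:
#   external edge = d - f   (lights up on the dark side of a transition)
#   internal edge = f - e   (lights up on the bright side)
#   middle edge   = d - e   (the morphological gradient, both sides)
# and the combined edge is their saturating sum.  Extensivity
# (e <= f <= d pointwise) guarantees all three differences are nonnegative,
# so the only clamping point is the final sum; below saturation the combined
# edge equals exactly twice the middle edge.

#' Morphological edge images
#'
#' `edge_external()`, `edge_internal()` and `edge_middle()` compute the three
#' grayscale-morphology edge images over a small structuring element (default
#' the full 3x3 square); `edge_all()` is their pointwise sum, saturated at
#' 255.  A locally constant image yields identically zero edges.
#'
#' @inheritParams gray_dilate
#' @return An integer matrix of the same dimensions with values in 0..255.
#' @examples
#' f <- matrix(0L, 5, 5); f[, 3:5] <- 200L
#' edge_middle(f)
#' @export
edge_external <- function(img, se = se_rect(3)) {
  assert_gray(img)
  as_int_img(gray_dilate(img, se) - img)
}

#' @rdname edge_external
#' @export
edge_internal <- function(img, se = se_rect(3)) {
  assert_gray(img)
  as_int_img(img - gray_erode(img, se))
}

#' @rdname edge_external
#' @export
edge_middle <- function(img, se = se_rect(3)) {
  assert_gray(img)
  as_int_img(gray_dilate(img, se) - gray_erode(img, se))
}

#' @rdname edge_external
#' @export
edge_all <- function(img, se = se_rect(3)) {
  assert_gray(img)
  se <- resolve_se(se)
  d <- gray_dilate(img, se)
  e <- gray_erode(img, se)
  as_int_img(pmin((d - img) + (d - e) + (img - e), 255L))
}
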