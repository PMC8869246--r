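# Grayscale and binary morphology.
#
# The structuring element (SE) is a small binary template whose anchor is its
# geometric centre; the pipeline uses the full 3x3 square for edge synthesis
# and the full 9x9 rectangle for cluster detection.  Border policy everywhere
# is replicate-edge padding (realised as window clamping, which is identical
# for order statistics).

#' Rectangular structuring element
#'
#' @param width SE width in pixels (odd).
#' @param height SE height in pixels (odd); defaults to `width`.
#' @return A `struct_el` object: a binary matrix of ones with the anchor at
#'   its centre.
#' @examples
#' se_rect(3)
#' @export
se_rect <- function(width, height = width) {
  as_se(matrix(1L, height, width))
}

#' @rdname se_rect
#' @param shape A binary matrix (odd side lengths, at least one active
#'   element) to use as an arbitrary-shaped SE.
#' @export
as_se <- function(shape) {
  if (inherits(shape, "struct_el")) return(shape)
  if (!is.matrix(shape) || !is.numeric(shape))
    stop("a structuring element must be a binary matrix", call. = FALSE)
  if (nrow(shape) %% 2L == 0L || ncol(shape) %% 2L == 0L)
    stop("structuring element side lengths must be odd", call. = FALSE)
  if (!any(shape != 0))
    stop("structuring element must have at least one active element",
         call. = FALSE)
  shape <- as_int_img((shape != 0) * 1L)
  structure(list(shape = shape,
                 anchor = c((nrow(shape) - 1L) %/% 2L,
                            (ncol(shape) - 1L) %/% 2L)),
            class = "struct_el")
}

#' @export
print.struct_el <- function(x, ...) {
  cat("Structuring element ", nrow(x$shape), "x", ncol(x$shape),
      " (", sum(x$shape), " active)\n", sep = "")
  invisible(x)
}

# Resolve a user-supplied SE (struct_el, matrix, or odd integer for a square).
resolve_se <- function(se) {
  if (inherits(se, "struct_el")) return(se)
  if (is.matrix(se)) return(as_se(se))
  if (is.numeric(se) && length(se) == 1L) return(se_rect(as.integer(se)))
  stop("invalid structuring element", call. = FALSE)
}

se_is_full_rect <- function(se) all(se$shape == 1L)

rank_op <- function(img, se, take_max) {
  se <- resolve_se(se)
  img <- as_int_img(img)
  if (se_is_full_rect(se))
    cpp_rect_rank(img, nrow(se$shape), ncol(se$shape), take_max)
  else
    cpp_window_rank(img, se$shape, se$anchor[1L], se$anchor[2L], take_max)
}

#' Grayscale morphological dilation and erosion
#'
#' Dilation assigns to each pixel the maximum input value over the SE window
#' anchored there; erosion assigns the minimum.  These are the primitives the
#' edge-synthesis stage composes, and they satisfy the extensivity sandwich
#' `gray_erode(f) <= f <= gray_dilate(f)` pointwise.
#'
#' @param img Grayscale image (integer matrix, 0..255).
#' @param se Structuring element: a [se_rect()] object, a binary matrix with
#'   odd sides, or a single odd integer `k` meaning the full `k`x`k` square.
#' @return An integer matrix of the same dimensions.
#' @examples
#' f <- matrix(0L, 3, 3); f[2, 2] <- 9L
#' gray_dilate(f, 3)
#' @export
gray_dilate <- function(img, se = se_rect(3)) {
  assert_gray(img)
  rank_op(img, se, TRUE)
}

#' @rdname gray_dilate
#' @export
gray_erode <- function(img, se = se_rect(3)) {
  assert_gray(img)
  rank_op(img, se, FALSE)
}

#' Binary morphology
#'
#' `binary_dilate()` sets a pixel to 255 iff any window pixel is 255;
#' `binary_erode()` sets it to 0 iff any window pixel is 0.  On \{0, 255\}
#' rasters these coincide with window max/min, so they share the grayscale
#' kernels.  `binary_close()` (dilate then erode) fills gaps smaller than the
#' SE; `binary_open()` (erode then dilate) removes features smaller than the
#' SE; both are idempotent.
#'
#' @param mask Binary mask (integer matrix over \{0, 255\}).
#' @inheritParams gray_dilate
#' @return A binary mask of the same dimensions.
#' @export
binary_dilate <- function(mask, se = se_rect(3)) {
  assert_mask(mask)
  rank_op(mask, se, TRUE)
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, se = se_rect(3)) {
  assert_mask(mask)
  rank_op(mask, se, FALSE)
}

#' @rdname binary_dilate
#' @export
binary_close <- function(mask, se = se_rect(3)) {
  binary_erode(binary_dilate(mask, se), se)
}

#' @rdname binary_dilate
#' @export
binary_open <- function(mask, se = se_rect(3)) {
  binary_dilate(binary_erode(mask, se), se)
}

# Connected-component labelling; connectivity 8 for foreground, 4 for holes
# (the standard duality avoiding topological paradoxes).
label_components <- function(mask, connectivity = 8L) {
  cpp_label(as_int_img(mask), as.integer(connectivity))
}

n_components <- function(mask, connectivity = 8L) {
  max(label_components(mask, connectivity))
}
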