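# Otsu's automatic threshold on the sharpened edge image.
#
# For a candidate threshold t, background = pixels <= t, foreground =
# pixels > t.  The chosen t minimises the weighted within-class variance
#   W_b(t) * var_b(t) + W_f(t) * var_f(t),
# where each class weight W is its pixel count divided by the total pixel
# count and empty classes contribute zero.  Minimising this objective is the
# classical dual of maximising the between-class variance.

#' Otsu threshold of a grayscale image
#'
#' Exhaustive search over the 256 candidate thresholds for the minimiser of
#' the weighted within-class variance.  Ties are broken toward the smallest
#' threshold (deterministic, and it favours retaining faint edges).  A
#' constant image returns its own value, so that thresholding with
#' "foreground = pixels above t" yields an empty mask: a constant image has
#' no edges.
#'
#' @inheritParams gray_dilate
#' @return An object of class `otsu_threshold`: a list with `threshold`
#'   (integer 0..255) and `objective` (the length-256 objective curve,
#'   indexed by t = 0..255).
#' @examples
#' img <- matrix(c(rep(10L, 50), rep(240L, 50)), 10, 10)
#' otsu_threshold(img)$threshold
#' @export
otsu_threshold <- function(img) {
  assert_gray(img)
  v <- as.integer(img)
  n <- length(v)
  counts <- tabulate(v + 1L, nbins = 256L)  # histogram over 0..255
  if (sum(counts > 0L) == 1L) {  # degenerate: constant image
    t <- which(counts > 0L) - 1L
    obj <- numeric(256L)
    return(structure(list(threshold = t, objective = obj),
                     class = "otsu_threshold"))
  }
  lev <- 0:255
  cw <- cumsum(counts)                 # background pixel count for t = 0..255
  cs <- cumsum(counts * lev)           # background intensity sum
  cs2 <- cumsum(counts * lev^2)        # background sum of squares
  nb <- cw
  nf <- n - cw
  # class variances (population form); empty classes contribute zero
  mb <- ifelse(nb > 0, cs / nb, 0)
  vb <- ifelse(nb > 0, cs2 / nb - mb^2, 0)
  mf <- ifelse(nf > 0, (cs[256L] - cs) / nf, 0)
  vf <- ifelse(nf > 0, (cs2[256L] - cs2) / nf - mf^2, 0)
  obj <- (nb / n) * vb + (nf / n) * vf
  obj <- pmax(obj, 0)  # guard tiny negative rounding residue
  t <- which.min(obj) - 1L  # which.min takes the first (smallest) minimiser
  structure(list(threshold = t, objective = obj), class = "otsu_threshold")
}

#' @export
print.otsu_threshold <- function(x, ...) {
  cat("Otsu threshold:", x$threshold,
      sprintf("(objective %.4f)\n", x$objective[x$threshold + 1L]))
  invisible(x)
}

#' Apply a fixed threshold to a grayscale image
#'
#' Pixels strictly above `t` become 255 (foreground), the rest 0.  In the
#' pipeline the foreground of the thresholded image is the bright edge
#' pixels.
#'
#' @inheritParams gray_dilate
#' @param t Threshold in 0..255.
#' @return A binary mask.
#' @export
apply_threshold <- function(img, t) {
  assert_gray(img)
  if (length(t) != 1L || is.na(t) || t < 0 || t > 255)
    stop("`t` must be a single value in 0..255", call. = FALSE)
  as_int_img((img > t) * 255L)
}
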