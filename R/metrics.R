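# Evaluation metrics: dice coefficient, intersection-over-union, relative
# error of the measured cell-growth area, and corpus-level aggregation.
#
# Internally all values are proportions in [0, 1]; percent formatting happens
# only at the reporting layer.  For masks X and Y (counting 255-pixels):
#   dice = 2|X n Y| / (|X| + |Y|),   iou = |X n Y| / |X u Y|,
# related by iou = dice / (2 - dice).  Two empty masks agree perfectly on
# absence, so dice = iou = 1 by convention; empty vs nonempty gives 0.

#' Dice coefficient of two binary masks
#'
#' @param x,y Binary masks (values in \{0, 255\}) of equal dimensions.
#' @return A proportion in \[0, 1\].
#' @examples
#' a <- matrix(c(255, 255, 255, 0), 2, 2)
#' b <- matrix(c(255, 255, 0, 255), 2, 2)
#' dice(a, b)
#' iou(a, b)
#' @export
dice <- function(x, y) {
  assert_mask(x); assert_mask(y); assert_same_dim(x, y)
  nx <- sum(x == 255L); ny <- sum(y == 255L)
  if (nx + ny == 0L) return(1)
  2 * sum(x == 255L & y == 255L) / (nx + ny)
}

#' @rdname dice
#' @export
iou <- function(x, y) {
  assert_mask(x); assert_mask(y); assert_same_dim(x, y)
  u <- sum(x == 255L | y == 255L)
  if (u == 0L) return(1)
  sum(x == 255L & y == 255L) / u
}

#' Relative error of the measured cell-growth area
#'
#' `abs(measured - actual) / actual`, for area fractions (or any positive
#' area measure on a common scale).
#'
#' @param measured Measured area fraction.
#' @param actual Reference (ground-truth) area fraction; must be positive.
#' @return A nonnegative proportion (may exceed 1).
#' @examples
#' relative_area_error(0.5, 0.4)
#' @export
relative_area_error <- function(measured, actual) {
  if (length(actual) != 1L || is.na(actual) || actual <= 0)
    stop("`actual` must be positive: relative area error is undefined for ",
         "an image with no true foreground", call. = FALSE)
  abs(measured - actual) / actual
}

#' Evaluate a corpus of predicted masks against reference masks
#'
#' Computes dice, IoU and relative area error per image pair, plus the mean
#' and standard deviation of each metric over the corpus.  The default
#' standard deviation is the population form (divide by n), the natural
#' summary of a fixed corpus; set `std_mode = "sample"` for the n-1 form.
#' Pairs whose reference mask is empty get `NA` relative area error and are
#' excluded from that metric's aggregates (with a warning).
#'
#' @param pred List of predicted binary masks.
#' @param truth List of reference binary masks, same length and per-pair
#'   dimensions.
#' @param names Optional character vector of image names for the per-image
#'   table.
#' @param std_mode `"population"` (default) or `"sample"`.
#' @return An object of class `metrics_report`: a list with `per_image` (a
#'   data frame with columns name, dice, iou, rel_area_error), `mean`, `std`
#'   and `n_images`.
#' @examples
#' m <- matrix(c(0, 255), 4, 4)
#' evaluate_corpus(list(m), list(m))
#' @export
evaluate_corpus <- function(pred, truth, names = NULL,
                            std_mode = c("population", "sample")) {
  std_mode <- match.arg(std_mode)
  if (!is.list(pred) || !is.list(truth) || length(pred) != length(truth) ||
      length(pred) < 1L)
    stop("`pred` and `truth` must be nonempty lists of equal length",
         call. = FALSE)
  n <- length(pred)
  if (is.null(names)) names <- sprintf("image_%04d", seq_len(n))
  d <- numeric(n); j <- numeric(n); r <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- dice(pred[[i]], truth[[i]])
    j[i] <- iou(pred[[i]], truth[[i]])
    ta <- mean(truth[[i]] == 255L)
    r[i] <- if (ta > 0) relative_area_error(mean(pred[[i]] == 255L), ta)
            else NA_real_
  }
  if (anyNA(r))
    warning(sum(is.na(r)), " pair(s) with empty reference mask excluded ",
            "from relative-area-error aggregates", call. = FALSE)
  stat <- function(v) {
    v <- v[!is.na(v)]
    std <- if (length(v) < 2L) 0
           else if (std_mode == "population")
             sqrt(mean((v - mean(v))^2))
           else sd(v)
    c(mean = mean(v), std = std)
  }
  sm <- vapply(list(dice = d, iou = j, rel_area_error = r), stat,
               numeric(2L))
  structure(list(
    per_image = data.frame(name = names, dice = d, iou = j,
                           rel_area_error = r, stringsAsFactors = FALSE),
    mean = sm["mean", ],
    std = sm["std", ],
    n_images = n,
    std_mode = std_mode
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Segmentation metrics over %d image(s) (%s std)\n",
              x$n_images, x$std_mode))
  cat(sprintf("  dice            : %6.2f%% (std %.2f%%)\n",
              100 * x$mean[["dice"]], 100 * x$std[["dice"]]))
  cat(sprintf("  IoU             : %6.2f%% (std %.2f%%)\n",
              100 * x$mean[["iou"]], 100 * x$std[["iou"]]))
  cat(sprintf("  rel. area error : %6.2f%% (std %.2f%%)\n",
              100 * x$mean[["rel_area_error"]],
              100 * x$std[["rel_area_error"]]))
  invisible(x)
}

#' Write a metrics report as CSV and JSON
#'
#' @param x A `metrics_report`.
#' @param stem Output path prefix; writes `<stem>.csv` (one row per image)
#'   and `<stem>.json` (per-image table plus aggregates).
#' @return The written paths, invisibly.
#' @export
write_metrics_report <- function(x, stem) {
  stopifnot(inherits(x, "metrics_report"))
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  write.csv(x$per_image, csv, row.names = FALSE)
  jsonlite::write_json(
    list(per_image = x$per_image, mean = as.list(x$mean),
         std = as.list(x$std), n_images = x$n_images,
         std_mode = x$std_mode),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}
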