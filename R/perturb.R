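# Robustness protocols: controlled degradations of the input image (blur,
# image size, illumination) swept over a level range, with segmentation
# quality measured at every level.  All transforms are deterministic.

#' Blur perturbation
#'
#' Degrades an image with Gaussian or mean (box) blur at kernel size `k`
#' (odd, 3..49).  Both methods use replicate borders; only odd kernels are
#' accepted since even kernels lack a centre anchor.
#'
#' @inheritParams gray_dilate
#' @param method `"gaussian"` or `"mean"`.
#' @param k Odd kernel size in 3..49.
#' @return The blurred image.
#' @export
blur_perturb <- function(img, method = c("gaussian", "mean"), k) {
  method <- match.arg(method)
  if (length(k) != 1L || is.na(k) || k < 3 || k > 49 || k %% 2 == 0)
    stop("blur kernel must be an odd integer in 3..49", call. = FALSE)
  if (method == "gaussian") gaussian_blur(img, k) else mean_blur(img, k)
}

#' Image-size perturbation
#'
#' Scales both image dimensions by the same scalar (0.5..3), rounding to the
#' nearest pixel count; aspect ratio is preserved.  Grayscale images use the
#' default interpolation of [resize_image()]; for reference masks use
#' [resize_mask()], which keeps the raster binary.
#'
#' @inheritParams gray_dilate
#' @param scalar Scale factor in \[0.5, 3\].
#' @return The rescaled image.
#' @export
resize_perturb <- function(img, scalar) {
  assert_gray(img)
  if (length(scalar) != 1L || is.na(scalar) || scalar < 0.5 || scalar > 3)
    stop("resize scalar must lie in [0.5, 3]", call. = FALSE)
  w <- max(1L, as.integer(round_px(ncol(img) * scalar)))
  h <- max(1L, as.integer(round_px(nrow(img) * scalar)))
  resize_image(img, w, h)
}

#' @rdname resize_perturb
#' @param mask Binary mask to co-resize with its image: nearest-neighbour
#'   interpolation followed by a defensive re-threshold at 128.
#' @export
resize_mask <- function(mask, scalar) {
  assert_mask(mask)
  if (length(scalar) != 1L || is.na(scalar) || scalar < 0.5 || scalar > 3)
    stop("resize scalar must lie in [0.5, 3]", call. = FALSE)
  w <- max(1L, as.integer(round_px(ncol(mask) * scalar)))
  h <- max(1L, as.integer(round_px(nrow(mask) * scalar)))
  out <- resize_image(mask, w, h, method = "nearest")
  as_int_img((out > 128L) * 255L)
}

#' Illumination perturbations
#'
#' `illum_normalize()` rescales the image: it is normalised to 0..1,
#' multiplied by `255 - s`, and rounded, so the maximum attainable value is
#' `255 - s` while pixel ordering is preserved (akin to a bit-depth
#' rescale).  `illum_subtract()` subtracts `s` from every pixel, clamped at
#' zero (akin to thresholding: values below `s` are lost).  `s` ranges over
#' 0..150 in steps of 5.
#'
#' @inheritParams gray_dilate
#' @param s Illumination scalar in 0..150, a multiple of 5.
#' @return The darkened image.
#' @examples
#' illum_normalize(matrix(255L, 2, 2), 150)  # 105 everywhere
#' @export
illum_normalize <- function(img, s) {
  assert_gray(img)
  check_illum_scalar(s)
  as_int_img(round_px((img / 255) * (255 - s)))
}

#' @rdname illum_normalize
#' @export
illum_subtract <- function(img, s) {
  assert_gray(img)
  check_illum_scalar(s)
  as_int_img(pmax(img - as.integer(s), 0L))
}

check_illum_scalar <- function(s) {
  if (length(s) != 1L || is.na(s) || s < 0 || s > 150 || s %% 5 != 0)
    stop("illumination scalar must be in 0..150 in steps of 5",
         call. = FALSE)
  invisible(s)
}

#' Default sweep levels per perturbation axis
#'
#' Blur: odd kernels 3..49.  Resize: scalars 0.5..3 (step 0.25, a readable
#' sampling of the continuous range).  Illumination: 0..150 in steps of 5.
#'
#' @param axis One of `"blur_gaussian"`, `"blur_mean"`, `"resize"`,
#'   `"illum_normalize"`, `"illum_subtract"`.
#' @return Numeric vector of levels.
#' @export
sweep_levels <- function(axis = c("blur_gaussian", "blur_mean", "resize",
                                  "illum_normalize", "illum_subtract")) {
  axis <- match.arg(axis)
  switch(axis,
    blur_gaussian = ,
    blur_mean = seq(3, 49, by = 2),
    resize = seq(0.5, 3, by = 0.25),
    illum_normalize = ,
    illum_subtract = seq(0, 150, by = 5)
  )
}

apply_perturbation <- function(img, axis, level) {
  switch(axis,
    blur_gaussian = blur_perturb(img, "gaussian", level),
    blur_mean = blur_perturb(img, "mean", level),
    resize = resize_perturb(img, level),
    illum_normalize = illum_normalize(img, level),
    illum_subtract = illum_subtract(img, level),
    stop("unknown perturbation axis: ", axis, call. = FALSE)
  )
}

#' Run a robustness sweep over a corpus
#'
#' For every level of the chosen perturbation axis, each corpus image is
#' perturbed, segmented with [segment_cells()], and scored against its
#' reference mask; per-level means of dice, IoU and relative area error are
#' collected.  For the `resize` axis the reference mask is co-resized
#' (nearest neighbour, re-thresholded) and metrics are computed at the
#' perturbed resolution; the pipeline's own resize stage is disabled on that
#' axis, since the protocol measures sensitivity to the native input size.
#' Relative errors above 100% are retained and flagged in the table.
#'
#' A per-image failure at some level is recorded as a missing row rather
#' than aborting the sweep.
#'
#' @param corpus A list of scenes: either `synthetic_scene` objects or lists
#'   with elements `image` and `truth_mask`.
#' @param axis Perturbation axis (see [sweep_levels()]).
#' @param levels Ordered numeric vector of levels (defaults to the
#'   axis-standard range).
#' @param config A [seg_config()]; on the resize axis its resize stage is
#'   forced off.
#' @return An object of class `sweep_report`: a list with `axis`, `levels`,
#'   `table` (one row per level x image: level, name, dice, iou,
#'   rel_area_error, over_100pct) and `summary` (per-level means).
#' @export
run_sweep <- function(corpus, axis, levels = sweep_levels(axis),
                      config = seg_config()) {
  axis <- match.arg(axis, c("blur_gaussian", "blur_mean", "resize",
                            "illum_normalize", "illum_subtract"))
  if (!is.list(corpus) || !length(corpus))
    stop("`corpus` must be a nonempty list", call. = FALSE)
  if (!length(levels)) stop("`levels` must be nonempty", call. = FALSE)
  if (axis == "resize" && config$resize) {
    config$resize <- FALSE
  }
  rows <- vector("list", length(levels) * length(corpus))
  k <- 0L
  for (lev in levels) {
    for (i in seq_along(corpus)) {
      sc <- corpus[[i]]
      nm <- if (!is.null(sc$name)) sc$name else sprintf("image_%04d", i)
      row <- tryCatch({
        pert <- apply_perturbation(sc$image, axis, lev)
        truth <- if (axis == "resize") resize_mask(sc$truth_mask, lev)
                 else sc$truth_mask
        res <- segment_cells(pert, config)
        ta <- mean(truth == 255L)
        data.frame(
          level = lev, name = nm,
          dice = dice(res$mask, truth),
          iou = iou(res$mask, truth),
          rel_area_error = if (ta > 0)
            relative_area_error(res$area_fraction, ta) else NA_real_,
          stringsAsFactors = FALSE)
      }, error = function(e) {
        warning(sprintf("sweep %s level %s, %s failed: %s", axis,
                        format(lev), nm, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
      if (!is.null(row)) {
        k <- k + 1L
        rows[[k]] <- row
      }
    }
  }
  tab <- do.call(rbind, rows[seq_len(k)])
  tab$over_100pct <- !is.na(tab$rel_area_error) & tab$rel_area_error > 1
  agg <- aggregate(tab[, c("dice", "iou", "rel_area_error")],
                   by = list(level = tab$level), FUN = mean, na.rm = TRUE)
  agg <- agg[order(agg$level), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(axis = axis, levels = levels, table = tab, summary = agg),
            class = "sweep_report")
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("Robustness sweep:", x$axis, "over", length(x$levels), "level(s)\n")
  s <- x$summary
  s$dice <- sprintf("%.4f", s$dice)
  s$iou <- sprintf("%.4f", s$iou)
  s$rel_area_error <- sprintf("%.4f", s$rel_area_error)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
plot.sweep_report <- function(x, ...) {
  s <- x$summary
  op <- par(mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(range(s$level), c(0, 1), type = "n", xlab = x$axis,
       ylab = "metric", main = "Segmentation quality vs perturbation level")
  matlines(s$level, cbind(s$dice, s$iou, pmin(s$rel_area_error, 1)),
           lty = 1, lwd = 2, col = c("#1b6ca8", "#43a047", "#e65100"))
  legend("bottomleft", c("dice", "IoU", "rel. area error (capped at 1)"),
         col = c("#1b6ca8", "#43a047", "#e65100"), lwd = 2, bty = "n")
  invisible(x)
}

#' Write a sweep report as CSV and JSON
#'
#' @param x A `sweep_report`.
#' @param stem Output prefix; writes `<stem>.csv` (per level x image rows)
#'   and `<stem>.json` (table plus per-level summary).
#' @return Written paths, invisibly.
#' @export
write_sweep_report <- function(x, stem) {
  stopifnot(inherits(x, "sweep_report"))
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  write.csv(x$table, csv, row.names = FALSE)
  jsonlite::write_json(list(axis = x$axis, levels = x$levels,
                            table = x$table, summary = x$summary),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}
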