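# The full segmentation pipeline and its result object.

#' Pipeline configuration
#'
#' Collects every tunable stage parameter of [segment_cells()].  The defaults
#' reproduce the reference pipeline: resize to 800x600, Gaussian pre-blur
#' with kernel 3, edge synthesis over the full 3x3 square, blur-then-sharpen
#' on the combined edge image, Otsu binarization, one 3x3 binary opening for
#' noise removal, a 20-pixel debris floor for the small-cell branch, a 9x9
#' rectangle for cluster closing/opening, and a tiny-gap ceiling of 1% of the
#' image area for conditional gap filling.
#'
#' @param resize_width,resize_height Working resolution the input is resized
#'   to; set `resize = FALSE` to segment at native resolution (used e.g. by
#'   the image-size robustness protocol).
#' @param resize Logical: resize the input at all?
#' @param resize_position `"first"` (resize before any filtering, the
#'   default) or `"with_sharpen"` (resize the edge image at the sharpening
#'   stage instead; the alternative reading of the stage order).
#' @param pre_blur_kernel Odd Gaussian kernel size for input denoising.
#' @param edge_se SE for the grayscale edge operators (odd integer for a full
#'   square, or a [se_rect()] object).
#' @param edge_blur_kernel Odd Gaussian kernel applied to the combined edge
#'   image before sharpening (set 1 to disable).
#' @param sharpen Logical: apply Laplacian sharpening to the edge image.
#' @param blur_before_sharpen Logical: blur the edge image before (TRUE,
#'   default) or after sharpening.
#' @param noise_se Odd SE size for the post-Otsu binary noise-removal step;
#'   `NULL` disables it.
#' @param noise_morph Which binary operator the noise step applies:
#'   `"close"` (default; welds breaks in the thin edge bands so contours
#'   stay fillable — speckle blobs are removed later by the debris floor
#'   and the 9x9 opening), `"open"` (removes sub-SE specks directly, at the
#'   cost of destroying edge bands thinner than the SE), or `"none"`.
#' @param debris_floor Minimum filled-component area (pixels) kept by the
#'   small-cell branch.
#' @param cluster_se Odd SE size for cluster closing/opening.
#' @param gap_area_frac Tiny-gap ceiling as a fraction of image area.
#' @param std_mode `"population"` or `"sample"` standard deviation in corpus
#'   reports.
#' @return An object of class `seg_config` (a named list).
#' @examples
#' seg_config(resize = FALSE)
#' @export
seg_config <- function(resize_width = 800L, resize_height = 600L,
                       resize = TRUE,
                       resize_position = c("first", "with_sharpen"),
                       pre_blur_kernel = 3L,
                       edge_se = 3L,
                       edge_blur_kernel = 3L,
                       sharpen = TRUE,
                       blur_before_sharpen = TRUE,
                       noise_se = 3L,
                       noise_morph = c("close", "open", "none"),
                       debris_floor = 20L,
                       cluster_se = 9L,
                       gap_area_frac = 0.01,
                       std_mode = c("population", "sample")) {
  cfg <- list(
    resize_width = as.integer(resize_width),
    resize_height = as.integer(resize_height),
    resize = isTRUE(resize),
    resize_position = match.arg(resize_position),
    pre_blur_kernel = as.integer(pre_blur_kernel),
    edge_se = edge_se,
    edge_blur_kernel = as.integer(edge_blur_kernel),
    sharpen = isTRUE(sharpen),
    blur_before_sharpen = isTRUE(blur_before_sharpen),
    noise_se = if (is.null(noise_se)) NULL else as.integer(noise_se),
    noise_morph = match.arg(noise_morph),
    debris_floor = as.integer(debris_floor),
    cluster_se = as.integer(cluster_se),
    gap_area_frac = as.numeric(gap_area_frac),
    std_mode = match.arg(std_mode)
  )
  if (cfg$resize_width < 1L || cfg$resize_height < 1L)
    stop("resize targets must be positive", call. = FALSE)
  if (cfg$gap_area_frac < 0 || cfg$gap_area_frac > 1)
    stop("`gap_area_frac` must be in [0, 1]", call. = FALSE)
  structure(cfg, class = "seg_config")
}

#' @export
print.seg_config <- function(x, ...) {
  cat("Segmentation pipeline configuration\n")
  cat("  working size : ",
      if (x$resize) paste0(x$resize_width, "x", x$resize_height,
                           " (", x$resize_position, ")")
      else "native resolution", "\n", sep = "")
  cat("  pre-blur k   : ", x$pre_blur_kernel, "\n", sep = "")
  ese <- resolve_se(x$edge_se)
  cat("  edge SE      : ", nrow(ese$shape), "x", ncol(ese$shape), "\n",
      sep = "")
  cat("  edge blur k  : ", x$edge_blur_kernel,
      if (x$sharpen) paste0(" + sharpen (",
                            if (x$blur_before_sharpen) "blur first"
                            else "sharpen first", ")"),
      "\n", sep = "")
  cat("  noise step   : ",
      if (is.null(x$noise_se) || x$noise_morph == "none") "off"
      else paste0(x$noise_morph, " ", x$noise_se, "x", x$noise_se),
      "\n", sep = "")
  cat("  debris floor : ", x$debris_floor, " px\n", sep = "")
  cat("  cluster SE   : ", x$cluster_se, "x", x$cluster_se, "\n", sep = "")
  cat("  gap ceiling  : ", format(100 * x$gap_area_frac),
      "% of image area\n", sep = "")
  invisible(x)
}

#' Segment a phase-contrast cell image
#'
#' Runs the full foreground-background pipeline: optional resize to the
#' working resolution, Gaussian pre-blur, grayscale morphological edge
#' synthesis (external + middle + internal over a 3x3 SE), Gaussian blur and
#' Laplacian sharpening of the combined edge image, Otsu binarization, one
#' binary opening for noise removal, then the two mask branches — small-cell
#' contour filling and 9x9 cluster detection with intensity-conditional gap
#' classification — whose union is the final mask.  The (resized) input is
#' split into a foreground image (input where the mask is set, 0 elsewhere)
#' and the complementary background image, and the area fraction (cell
#' confluence) is the proportion of mask pixels.
#'
#' The pipeline is fully deterministic: the image is the only input, and
#' identical inputs give bit-identical results.
#'
#' @param img A grayscale image (integer matrix, 0..255) or a path to a
#'   PNG/TIFF file.
#' @param config A [seg_config()] object.
#' @param keep_intermediates Logical: retain the named stage images
#'   (smoothed input, edge image, sharpened edge, binary edge, both branch
#'   masks) in the result.
#' @return An object of class `cell_segmentation`: a list with `mask`,
#'   `foreground`, `background`, `area_fraction`, `otsu_threshold`,
#'   `blob_count` (per branch), `input` (the working-resolution grayscale),
#'   `config`, and optionally `intermediate`.
#' @examples
#' scn <- generate_scene(scene_spec(width = 160, height = 120, n_cells = 3,
#'                                  cell_radius_range = c(12, 18), seed = 7))
#' res <- segment_cells(scn$image, seg_config(resize = FALSE))
#' res$area_fraction
#' @export
segment_cells <- function(img, config = seg_config(),
                          keep_intermediates = FALSE) {
  if (is.character(img)) img <- read_image(img)
  assert_gray(img)
  stopifnot(inherits(config, "seg_config"))
  work <- as_int_img(img)
  if (config$resize && config$resize_position == "first")
    work <- resize_image(work, config$resize_width, config$resize_height)

  smoothed <- gaussian_blur(work, config$pre_blur_kernel)
  edges <- edge_all(smoothed, config$edge_se)

  esh <- edges
  if (config$blur_before_sharpen) {
    if (config$edge_blur_kernel > 1L)
      esh <- gaussian_blur(esh, config$edge_blur_kernel)
    if (config$sharpen) esh <- sharpen(esh)
  } else {
    if (config$sharpen) esh <- sharpen(esh)
    if (config$edge_blur_kernel > 1L)
      esh <- gaussian_blur(esh, config$edge_blur_kernel)
  }
  if (config$resize && config$resize_position == "with_sharpen") {
    esh <- resize_image(esh, config$resize_width, config$resize_height)
    work <- resize_image(work, config$resize_width, config$resize_height)
  }

  ot <- otsu_threshold(esh)
  bin <- apply_threshold(esh, ot$threshold)
  if (!is.null(config$noise_se) && config$noise_morph != "none") {
    nse <- se_rect(config$noise_se)
    bin <- if (config$noise_morph == "close") binary_close(bin, nse)
           else binary_open(bin, nse)
  }

  mask_a <- small_cell_mask(bin, min_area = config$debris_floor)
  mask_b <- cluster_mask(bin, work, se = se_rect(config$cluster_se),
                         gap_ceiling = config$gap_area_frac * length(work))
  final <- combine_masks(mask_a, mask_b)

  fg <- work; fg[final == 0L] <- 0L
  bg <- work; bg[final == 255L] <- 0L

  res <- list(
    mask = final,
    foreground = as_int_img(fg),
    background = as_int_img(bg),
    area_fraction = mean(final == 255L),
    otsu_threshold = ot$threshold,
    blob_count = c(small = n_components(mask_a), cluster = n_components(mask_b)),
    input = work,
    config = config
  )
  if (keep_intermediates)
    res$intermediate <- list(smoothed = smoothed, edge = edges,
                             edge_sharpened = esh, edge_binary = bin,
                             small_mask = mask_a, cluster_mask = mask_b)
  structure(res, class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat("Phase-contrast cell segmentation\n")
  cat(sprintf("  image          : %d x %d px\n",
              ncol(x$input), nrow(x$input)))
  cat(sprintf("  Otsu threshold : %d\n", x$otsu_threshold))
  cat(sprintf("  area fraction  : %.4f (%.2f%% confluence)\n",
              x$area_fraction, 100 * x$area_fraction))
  cat(sprintf("  blobs          : %d small-cell, %d cluster\n",
              x$blob_count[["small"]], x$blob_count[["cluster"]]))
  invisible(x)
}

#' @export
summary.cell_segmentation <- function(object, ...) {
  lab <- label_components(object$mask, 8L)
  areas <- if (max(lab) > 0L) tabulate(lab, nbins = max(lab)) else integer()
  out <- list(
    width = ncol(object$input), height = nrow(object$input),
    otsu_threshold = object$otsu_threshold,
    area_fraction = object$area_fraction,
    n_regions = length(areas),
    region_area = if (length(areas)) summary(areas) else NULL,
    mean_foreground = if (any(object$mask == 255L))
      mean(object$input[object$mask == 255L]) else NA_real_,
    mean_background = if (any(object$mask == 0L))
      mean(object$input[object$mask == 0L]) else NA_real_
  )
  class(out) <- "summary.cell_segmentation"
  out
}

#' @export
print.summary.cell_segmentation <- function(x, ...) {
  cat(sprintf("Segmentation of a %d x %d image\n", x$width, x$height))
  cat(sprintf("  Otsu threshold     : %d\n", x$otsu_threshold))
  cat(sprintf("  confluence         : %.2f%%\n", 100 * x$area_fraction))
  cat(sprintf("  foreground regions : %d\n", x$n_regions))
  if (!is.null(x$region_area)) {
    cat("  region area (px)   : ")
    print(x$region_area)
  }
  cat(sprintf("  mean intensity     : %.1f foreground / %.1f background\n",
              x$mean_foreground, x$mean_background))
  invisible(x)
}

#' @export
plot.cell_segmentation <- function(x, which = c("overlay", "mask",
                                                "foreground", "background"),
                                   ...) {
  which <- match.arg(which)
  img <- switch(which,
    mask = x$mask,
    foreground = x$foreground,
    background = x$background,
    overlay = x$input
  )
  op <- par(mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit(par(op))
  plot.new()
  plot.window(xlim = c(0, ncol(img)), ylim = c(0, nrow(img)), asp = 1)
  rasterImage(as.raster(img / 255), 0, 0, ncol(img), nrow(img))
  if (which == "overlay") {
    # paint the mask boundary (mask minus its erosion) in semi-opaque red
    rim <- x$mask - binary_erode(x$mask, se_rect(3))
    ov <- array(0, dim = c(nrow(img), ncol(img), 4))
    ov[, , 1] <- 1
    ov[, , 4] <- (rim == 255L) * 0.9
    rasterImage(ov, 0, 0, ncol(img), nrow(img))
  }
  title(main = paste0(which, " (confluence ",
                      sprintf("%.1f", 100 * x$area_fraction), "%)"))
  invisible(x)
}

#' Write segmentation artifacts to disk
#'
#' Writes `<stem>_mask.png`, `<stem>_foreground.png`,
#' `<stem>_background.png` and a JSON sidecar `<stem>.json` holding the Otsu
#' threshold, area fraction and blob counts.
#'
#' @param x A `cell_segmentation` object.
#' @param stem Output path prefix (directories must exist).
#' @param intermediates Logical: also dump stage images when present.
#' @return Character vector of the written paths, invisibly.
#' @export
write_segmentation <- function(x, stem, intermediates = FALSE) {
  stopifnot(inherits(x, "cell_segmentation"))
  paths <- c(
    mask = paste0(stem, "_mask.png"),
    foreground = paste0(stem, "_foreground.png"),
    background = paste0(stem, "_background.png"),
    sidecar = paste0(stem, ".json")
  )
  write_mask(x$mask, paths[["mask"]])
  write_image(x$foreground, paths[["foreground"]])
  write_image(x$background, paths[["background"]])
  jsonlite::write_json(
    list(otsu_threshold = x$otsu_threshold,
         area_fraction = x$area_fraction,
         blob_count = as.list(x$blob_count)),
    paths[["sidecar"]], auto_unbox = TRUE, digits = NA)
  if (intermediates && !is.null(x$intermediate)) {
    for (nm in names(x$intermediate)) {
      p <- paste0(stem, "_", nm, ".png")
      write_image(x$intermediate[[nm]], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
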