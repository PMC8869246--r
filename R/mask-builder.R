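# From binary edge image to the final cell mask.
#
# Branch A (small cells): every external contour of the edge image is filled
# solid and components below the debris-area floor are discarded.
# Branch B (clusters): the edge image is closed then opened with the 9x9
# rectangle; interior holes of the resulting blobs are classified by
# comparing their mean grayscale intensity with the detected background and
# the contour bodies — holes that look like background stay open, holes that
# look like cell interior are filled.
# The final mask is the pixelwise union of the two branches.
#
# Connectivity convention: 8-connected foreground, 4-connected holes.

# Interior holes of `mask`: 4-connected components of the complement that do
# not touch the image border.  Returns the label matrix of the complement and
# the integer ids of hole components (possibly none).
find_holes <- function(mask) {
  lab <- label_components(mask == 0L, 4L)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  ids <- setdiff(seq_len(max(lab, 0L)), border)
  list(labels = lab, hole_ids = ids[ids > 0L])
}

# Fill every interior hole (flood-fill-from-border on the complement).
fill_holes <- function(mask) {
  h <- find_holes(mask)
  if (length(h$hole_ids)) mask[h$labels %in% h$hole_ids] <- 255L
  as_int_img(mask)
}

#' Small-cell mask (branch A)
#'
#' Fills every external contour of the binary edge image into a solid blob
#' (the closed edge ring of a small, well-separated cell becomes the cell
#' body) and removes components smaller than the debris-area floor, which
#' discards edge responses of bright debris specks.
#'
#' @param edge_binary Binary mask from thresholding the sharpened edge image.
#' @param min_area Debris floor in pixels: filled components with fewer
#'   pixels are dropped (default 20).
#' @return A binary mask.
#' @examples
#' ring <- matrix(0L, 9, 9)
#' ring[3:7, 3:7] <- 255L; ring[4:6, 4:6] <- 0L
#' sum(small_cell_mask(ring, min_area = 1) == 255L)  # solid 5x5 block
#' @export
small_cell_mask <- function(edge_binary, min_area = 20) {
  assert_mask(edge_binary)
  filled <- fill_holes(edge_binary)
  lab <- label_components(filled, 8L)
  if (max(lab) == 0L) return(filled)
  areas <- tabulate(lab, nbins = max(lab))
  drop <- which(areas < min_area)
  if (length(drop)) filled[lab %in% drop] <- 0L
  as_int_img(filled)
}

#' Gap classification inside a cell cluster
#'
#' A tiny enclosed gap inside a detected cluster contour is kept open
#' (classified as background) when its mean grayscale intensity is strictly
#' closer to the mean intensity of the detected background regions than to
#' the mean intensity of the contour bodies; otherwise it is filled as
#' cellular foreground.  Exact ties are filled (conservative toward cells),
#' as is the degenerate case of a cluster with no outside background.
#'
#' @param gap_mean Mean grayscale intensity (0..255) of the gap region.
#' @param background_mean Mean intensity of pixels outside all detected
#'   contours (may be `NA` when none exist).
#' @param foreground_mean Mean intensity of the detected contour-body pixels.
#' @return `"keep_open"` or `"fill"`.
#' @examples
#' classify_gap(200, 210, 90)  # looks like background
#' classify_gap(95, 210, 90)   # looks like cell interior
#' @export
classify_gap <- function(gap_mean, background_mean, foreground_mean) {
  if (is.na(background_mean) || is.na(foreground_mean)) return("fill")
  if (abs(gap_mean - background_mean) < abs(gap_mean - foreground_mean))
    "keep_open"
  else
    "fill"
}

#' Cluster mask with intensity-conditional gap filling (branch B)
#'
#' Closes then opens the binary edge image with a rectangular structuring
#' element (default the full 9x9), which welds the dense edge responses of
#' cell clusters into solid regions and deletes sub-SE specks.  Interior
#' holes of the result up to `gap_ceiling` pixels are then classified with
#' [classify_gap()] against the scene's background and contour-body
#' intensities; larger holes are always kept open.
#'
#' @inheritParams small_cell_mask
#' @param gray The grayscale image the edges were derived from (same
#'   dimensions; the resized, pre-edge pipeline image).
#' @param se Structuring element for closing/opening (default 9x9 square).
#' @param gap_ceiling Maximum gap area, in pixels, eligible for conditional
#'   filling; defaults to 1% of the image area.
#' @return A binary mask.
#' @export
cluster_mask <- function(edge_binary, gray, se = se_rect(9),
                         gap_ceiling = 0.01 * length(gray)) {
  assert_mask(edge_binary)
  assert_gray(gray)
  assert_same_dim(edge_binary, gray)
  m <- binary_open(binary_close(edge_binary, se), se)
  h <- find_holes(m)
  if (!length(h$hole_ids)) return(m)
  filled_all <- m
  filled_all[h$labels %in% h$hole_ids] <- 255L
  outside <- filled_all == 0L
  background_mean <- if (any(outside)) mean(gray[outside]) else NA_real_
  body <- m == 255L
  foreground_mean <- if (any(body)) mean(gray[body]) else NA_real_
  areas <- tabulate(h$labels, nbins = max(h$labels))
  for (id in h$hole_ids) {
    if (areas[id] > gap_ceiling) next  # large holes are always background
    px <- h$labels == id
    if (classify_gap(mean(gray[px]), background_mean, foreground_mean) ==
        "fill")
      m[px] <- 255L
  }
  as_int_img(m)
}

#' Union of two binary masks
#'
#' @param a,b Binary masks of equal dimensions.
#' @return The pixelwise union (255 where either mask is 255).
#' @export
combine_masks <- function(a, b) {
  assert_mask(a)
  assert_mask(b)
  assert_same_dim(a, b)
  as_int_img(pmax(a, b))
}
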