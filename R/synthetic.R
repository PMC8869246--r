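# Seeded generator of phase-contrast-like scenes with exact ground truth.
#
# The generator emulates the phenomenology of adherent-culture phase-contrast
# micrographs: dark-toned cell bodies (irregular perturbed ellipses) on a
# brighter fuzzy background, diffuse bright halo rings around a fraction of
# cells (out-of-focus detachment artifacts — diffuse by nature, which is
# precisely why a gradient-based segmenter can reject them), tiny bright
# debris specks, a smooth illumination vignette (bright centre, shaded
# corners), and Gaussian pixel noise.  The truth mask covers exactly the
# rendered cell-body pixels; halos and debris are artifacts and are excluded
# from truth by construction.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic phase-contrast scene
#'
#' The defaults describe a realistic 800x600 frame at roughly 10x
#' magnification of an epithelial culture: cell radii 25..50 px, body tone
#' around 85 on a background around 190, a quarter of the cells carrying a
#' diffuse bright halo, twenty debris specks, a 25-unit illumination
#' vignette, and pixel noise with standard deviation 4.
#'
#' @param width,height Scene size in pixels.
#' @param n_cells Exact number of cells to render, or `NULL` (default) to
#'   keep adding cells until `confluence_target` is reached.
#' @param confluence_target Target proportion of the frame covered by cell
#'   bodies, in (0, 1); used when `n_cells` is `NULL`.
#' @param cell_radius_range Min/max nominal cell radius in pixels.
#' @param cell_intensity Mean dark body tone (must be darker than the
#'   background).
#' @param background_intensity Mean bright background tone.
#' @param halo_fraction Proportion of cells rendered with a halo ring.
#' @param n_debris Number of small bright debris specks.
#' @param illumination_gradient_amp Peak-to-trough amplitude (intensity
#'   units, 0..60) of the smooth vignette.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise.
#' @param seed Integer seed; fixes the scene completely.
#' @return An object of class `scene_spec`.
#' @examples
#' scene_spec(width = 200, height = 150, n_cells = 2, seed = 42)
#' @export
scene_spec <- function(width = 800L, height = 600L,
                       n_cells = NULL,
                       confluence_target = 0.35,
                       cell_radius_range = c(25, 50),
                       cell_intensity = 85,
                       background_intensity = 190,
                       halo_fraction = 0.25,
                       n_debris = 20L,
                       illumination_gradient_amp = 25,
                       noise_sigma = 4,
                       seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_cells = if (is.null(n_cells)) NULL else as.integer(n_cells),
               confluence_target = as.numeric(confluence_target),
               cell_radius_range = as.numeric(cell_radius_range),
               cell_intensity = as.numeric(cell_intensity),
               background_intensity = as.numeric(background_intensity),
               halo_fraction = as.numeric(halo_fraction),
               n_debris = as.integer(n_debris),
               illumination_gradient_amp = as.numeric(illumination_gradient_amp),
               noise_sigma = as.numeric(noise_sigma),
               seed = as.integer(seed))
  if (spec$width < 8L || spec$height < 8L)
    stop("scene must be at least 8x8 pixels", call. = FALSE)
  if (spec$cell_intensity >= spec$background_intensity)
    stop("cell tone must be strictly darker than the background tone",
         call. = FALSE)
  if (spec$cell_intensity < 0 || spec$background_intensity > 255)
    stop("intensity bands must lie inside [0, 255]", call. = FALSE)
  if (is.null(spec$n_cells) &&
      (spec$confluence_target <= 0 || spec$confluence_target >= 1))
    stop("`confluence_target` must lie in (0, 1)", call. = FALSE)
  if (length(spec$cell_radius_range) != 2L ||
      spec$cell_radius_range[1L] <= 0 ||
      diff(spec$cell_radius_range) < 0)
    stop("`cell_radius_range` must be an increasing positive pair",
         call. = FALSE)
  if (spec$halo_fraction < 0 || spec$halo_fraction > 1)
    stop("`halo_fraction` must be a proportion", call. = FALSE)
  if (spec$illumination_gradient_amp < 0 ||
      spec$illumination_gradient_amp > 60)
    stop("`illumination_gradient_amp` must lie in [0, 60]", call. = FALSE)
  if (spec$noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  structure(spec, class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat("Synthetic phase-contrast scene spec\n")
  cat(sprintf("  frame      : %d x %d px (seed %d)\n", x$width, x$height,
              x$seed))
  cat("  cells      : ",
      if (is.null(x$n_cells))
        sprintf("to %.0f%% confluence", 100 * x$confluence_target)
      else x$n_cells,
      sprintf(", radius %.0f..%.0f px\n", x$cell_radius_range[1L],
              x$cell_radius_range[2L]), sep = "")
  cat(sprintf("  tones      : body %.0f on background %.0f\n",
              x$cell_intensity, x$background_intensity))
  cat(sprintf("  artifacts  : halo fraction %.2f, %d debris specks\n",
              x$halo_fraction, x$n_debris))
  cat(sprintf("  vignette   : %.0f units, noise sigma %.1f\n",
              x$illumination_gradient_amp, x$noise_sigma))
  invisible(x)
}

# Rasterize one irregular cell (perturbed rotated ellipse with 3..6 radial
# Fourier harmonics) into the scene.  Mutates and returns the environment's
# canvases via a list.
render_cell <- function(img, truth, halo, spec) {
  w <- spec$width; h <- spec$height
  cx <- runif(1, 1, w); cy <- runif(1, 1, h)
  rx <- runif(1, spec$cell_radius_range[1L], spec$cell_radius_range[2L])
  ry <- rx * runif(1, 0.7, 1)
  phi <- runif(1, 0, pi)
  nh <- sample(3:6, 1L)
  amps <- runif(nh, 0.01, 0.06)   # total boundary perturbation <= 25%
  phase <- runif(nh, 0, 2 * pi)
  tone <- spec$cell_intensity + runif(1, -12, 12)
  haloed <- runif(1) < spec$halo_fraction
  halo_amp <- runif(1, 25, 45)
  halo_w <- runif(1, 4, 7)        # px, diffuse falloff width

  rmax <- max(rx, ry) * 1.3 + halo_w + 2
  r0 <- max(1L, floor(cy - rmax)); r1 <- min(h, ceiling(cy + rmax))
  c0 <- max(1L, floor(cx - rmax)); c1 <- min(w, ceiling(cx + rmax))
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - cy, length(rows), length(cols))
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  u <- (dx * cos(phi) + dy * sin(phi)) / rx
  v <- (-dx * sin(phi) + dy * cos(phi)) / ry
  rad <- sqrt(u^2 + v^2)
  th <- atan2(v, u)
  bnd <- 1
  for (i in seq_len(nh)) bnd <- bnd + amps[i] * cos((i + 2) * th + phase[i])
  inside <- rad <= bnd

  sub_img <- img[rows, cols, drop = FALSE]
  sub_truth <- truth[rows, cols, drop = FALSE]
  sub_halo <- halo[rows, cols, drop = FALSE]
  n_in <- sum(inside)
  if (n_in > 0) {
    sub_img[inside] <- tone + rnorm(n_in, 0, 6)
    sub_truth[inside] <- TRUE
    # intracellular structure across scales — phase-contrast cell bodies are
    # strongly textured (nucleus, organelles, vesicles), which is what lights
    # the cell interior up under gradient-based edge extraction
    # nucleus: a brighter similar ellipse at a small offset from the centre
    nrad <- sqrt((u - runif(1, -0.25, 0.25))^2 +
                 (v - runif(1, -0.25, 0.25))^2)
    nuc <- inside & nrad <= runif(1, 0.35, 0.5)
    sub_img[nuc] <- sub_img[nuc] + runif(1, 10, 24)
    # organelle granules: mostly dark, two size classes (fine + medium)
    idx <- which(inside, arr.ind = TRUE)
    n_fine <- min(max(3L, round(n_in / 25)), nrow(idx))
    n_med <- min(max(1L, round(n_in / 350)), nrow(idx))
    pick <- idx[sample.int(nrow(idx), n_fine + n_med), , drop = FALSE]
    for (g in seq_len(nrow(pick))) {
      gr <- pick[g, 1L]; gc <- pick[g, 2L]
      if (g <= n_fine) {
        grad <- runif(1, 1, 2.5)
        off <- if (runif(1) < 0.75) runif(1, -60, -25) else runif(1, 15, 35)
      } else {
        grad <- runif(1, 3, 6)
        off <- if (runif(1) < 0.6) runif(1, -35, -15) else runif(1, 12, 25)
      }
      ext <- ceiling(grad)
      rr2 <- max(1L, gr - ext):min(nrow(sub_img), gr + ext)
      cc2 <- max(1L, gc - ext):min(ncol(sub_img), gc + ext)
      dd <- outer((rr2 - gr)^2, (cc2 - gc)^2, `+`) <= grad^2
      dd <- dd & inside[rr2, cc2, drop = FALSE]
      s <- sub_img[rr2, cc2, drop = FALSE]
      s[dd] <- s[dd] + off
      sub_img[rr2, cc2] <- s
    }
  }
  if (haloed) {
    hw_norm <- halo_w / mean(c(rx, ry))
    ring <- !inside & rad <= bnd + hw_norm & !sub_truth
    if (any(ring)) {
      t <- (rad[ring] - bnd[ring]) / hw_norm
      sub_img[ring] <- sub_img[ring] + halo_amp * (1 - pmin(t, 1))^2
      sub_halo[ring] <- TRUE
    }
  }
  img[rows, cols] <- sub_img
  truth[rows, cols] <- sub_truth
  halo[rows, cols] <- sub_halo
  list(img = img, truth = truth, halo = halo, new_px = n_in)
}

#' Generate a synthetic phase-contrast scene
#'
#' Renders the scene described by a [scene_spec()]: background tone plus
#' smooth vignette and low-frequency fuzz, dark irregular cell bodies (added
#' until the confluence target is met, or exactly `n_cells` of them),
#' diffuse halo rings on a random subset of cells, bright debris specks on
#' the background, and Gaussian pixel noise; everything clamped to 0..255.
#' The same spec (including its seed) always produces a bit-identical scene.
#'
#' @param spec A [scene_spec()].
#' @param max_cells Safety cap on the number of cells placed while chasing
#'   `confluence_target`; exceeding it raises a generation error naming the
#'   unreachable constraint.
#' @return An object of class `synthetic_scene`: a list with `image`
#'   (grayscale integer matrix), `truth_mask` (binary mask of the cell
#'   bodies), `halo_mask` and `debris_mask` (binary masks of the artifact
#'   pixels, disjoint from truth), `spec`, and `true_area_fraction`.
#' @examples
#' scn <- generate_scene(scene_spec(width = 160, height = 120, n_cells = 2,
#'                                  cell_radius_range = c(10, 16), seed = 3))
#' scn$true_area_fraction
#' @export
generate_scene <- function(spec, max_cells = 5000L) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    w <- spec$width; h <- spec$height
    # background: base tone + centre-bright vignette + low-frequency fuzz
    xs <- (seq_len(w) - (w + 1) / 2) / ((w - 1) / 2)
    ys <- (seq_len(h) - (h + 1) / 2) / ((h - 1) / 2)
    r2 <- outer(ys^2, xs^2, `+`) / 2
    img <- spec$background_intensity +
      spec$illumination_gradient_amp * (0.5 - r2)
    # low-frequency background "fuzziness", scaled with the noise level so a
    # noise-free spec renders an exactly uniform background
    if (spec$noise_sigma > 0) {
      fuzz_k <- gaussian_kernel(31, sigma = 8)
      fuzz <- cpp_conv_sep(matrix(rnorm(h * w, 0, 7.5 * spec$noise_sigma),
                                  h, w), fuzz_k, fuzz_k)
      img <- img + fuzz
    }

    truth <- matrix(FALSE, h, w)
    halo <- matrix(FALSE, h, w)

    if (!is.null(spec$n_cells)) {
      for (i in seq_len(spec$n_cells)) {
        st <- render_cell(img, truth, halo, spec)
        img <- st$img; truth <- st$truth; halo <- st$halo
      }
    } else {
      target_px <- spec$confluence_target * w * h
      placed <- 0L
      while (sum(truth) < target_px) {
        placed <- placed + 1L
        if (placed > max_cells)
          stop(sprintf(paste0("confluence target %.2f unreachable within ",
                              "%d cells at radii %.0f..%.0f"),
                       spec$confluence_target, max_cells,
                       spec$cell_radius_range[1L],
                       spec$cell_radius_range[2L]), call. = FALSE)
        st <- render_cell(img, truth, halo, spec)
        img <- st$img; truth <- st$truth; halo <- st$halo
      }
    }
    halo <- halo & !truth

    debris <- matrix(FALSE, h, w)
    for (i in seq_len(spec$n_debris)) {
      for (try in 1:30) {
        dc <- runif(1, 2, w - 1); dr <- runif(1, 2, h - 1)
        if (!truth[round(dr), round(dc)]) break
      }
      drad <- runif(1, 0.7, 1.8)
      dtone <- runif(1, 225, 250)
      rr <- max(1L, floor(dr - 3)):min(h, ceiling(dr + 3))
      cc <- max(1L, floor(dc - 3)):min(w, ceiling(dc + 3))
      dd <- outer((rr - dr)^2, (cc - dc)^2, `+`) <= drad^2
      sub_t <- truth[rr, cc, drop = FALSE]
      dd <- dd & !sub_t
      if (any(dd)) {
        sub <- img[rr, cc, drop = FALSE]
        sub[dd] <- dtone
        img[rr, cc] <- sub
        sub_d <- debris[rr, cc, drop = FALSE]
        sub_d[dd] <- TRUE
        debris[rr, cc] <- sub_d
      }
    }

    if (spec$noise_sigma > 0)
      img <- img + rnorm(h * w, 0, spec$noise_sigma)
    img <- as_int_img(clamp255(round_px(img)))
    truth_mask <- as_int_img(truth * 255L)
    structure(list(image = img,
                   truth_mask = truth_mask,
                   halo_mask = as_int_img(halo * 255L),
                   debris_mask = as_int_img(debris * 255L),
                   spec = spec,
                   true_area_fraction = mean(truth)),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene %d x %d (seed %d): %.2f%% true confluence\n",
              x$spec$width, x$spec$height, x$spec$seed,
              100 * x$true_area_fraction))
  invisible(x)
}

#' @export
plot.synthetic_scene <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit(par(op))
  for (nm in c("image", "truth_mask")) {
    plot.new()
    plot.window(xlim = c(0, ncol(x$image)), ylim = c(0, nrow(x$image)),
                asp = 1)
    rasterImage(as.raster(x[[nm]] / 255), 0, 0, ncol(x$image),
                nrow(x$image))
    title(main = nm)
  }
  invisible(x)
}

# Stable per-scene seed derivation: distinct, order-independent, < 2^31.
derive_seed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed) * 1000003 + index * 7919 + salt * 104729) %%
    2147483629
  as.integer(s) + 1L
}

#' Generate a corpus of synthetic scenes
#'
#' Draws `n` scenes from a template spec with per-scene seeds derived
#' deterministically from `(seed, index)`, and with the confluence target
#' jittered uniformly within +/-20% of the template value so the corpus
#' spans lower- and higher-density regimes.
#'
#' @param spec_template A [scene_spec()] used for every scene.
#' @param n Number of scenes (>= 1).
#' @param seed Corpus seed; defaults to the template's seed.
#' @return A list of `synthetic_scene` objects, each carrying a `name`
#'   element (`scene_0001`, ...).
#' @export
generate_corpus <- function(spec_template, n, seed = spec_template$seed) {
  stopifnot(inherits(spec_template, "scene_spec"))
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("`n` must be a positive count", call. = FALSE)
  lapply(seq_len(n), function(i) {
    sp <- spec_template
    if (is.null(sp$n_cells)) {
      jit <- with_seed(derive_seed(seed, i, 1L), runif(1, 0.8, 1.2))
      sp$confluence_target <-
        min(0.95, max(0.01, sp$confluence_target * jit))
    }
    sp$seed <- derive_seed(seed, i)
    scn <- tryCatch(generate_scene(sp),
                    error = function(e)
                      stop(sprintf("scene %d: %s", i, conditionMessage(e)),
                           call. = FALSE))
    scn$name <- sprintf("scene_%04d", i)
    scn
  })
}

#' Write a synthetic corpus as paired image/mask files
#'
#' Writes `image_####.png` and `mask_####.png` pairs plus a `manifest.json`
#' recording each scene's spec, seed and true area fraction — the layout the
#' evaluation and sweep commands consume.
#'
#' @param corpus A list of `synthetic_scene` objects.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- vector("list", length(corpus))
  for (i in seq_along(corpus)) {
    scn <- corpus[[i]]
    imgf <- file.path(dir, sprintf("image_%04d.png", i))
    maskf <- file.path(dir, sprintf("mask_%04d.png", i))
    write_image(scn$image, imgf)
    write_mask(scn$truth_mask, maskf)
    manifest[[i]] <- list(image = basename(imgf), mask = basename(maskf),
                          seed = scn$spec$seed,
                          true_area_fraction = scn$true_area_fraction,
                          spec = unclass(scn$spec))
  }
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(mf)
}

#' Fraction of artifact pixels leaking into a predicted mask
#'
#' Halo rings and debris specks are uncountable artifacts that a correct
#' segmentation excludes from the foreground.  This helper measures, for a
#' predicted mask over a synthetic scene, the fraction of the scene's halo
#' pixels and debris pixels that the mask wrongly includes (`NA` when the
#' scene has none of that artifact).
#'
#' @param mask Predicted binary mask.
#' @param scene A `synthetic_scene`.
#' @return Named numeric vector with elements `halo` and `debris`.
#' @export
artifact_inclusion <- function(mask, scene) {
  assert_mask(mask)
  stopifnot(inherits(scene, "synthetic_scene"))
  assert_same_dim(mask, scene$image)
  frac <- function(am) {
    n <- sum(am == 255L)
    if (n == 0L) NA_real_ else sum(am == 255L & mask == 255L) / n
  }
  c(halo = frac(scene$halo_mask), debris = frac(scene$debris_mask))
}
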