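# Synthetic scene generator: determinism, bookkeeping, artifact separation.

test_that("an empty noise-free scene is a constant background", {
  spec <- scene_spec(width = 64, height = 48, n_cells = 0, n_debris = 0,
                     illumination_gradient_amp = 0, noise_sigma = 0,
                     seed = 1)
  scn <- generate_scene(spec)
  expect_true(all(scn$image == scn$image[1, 1]))
  expect_true(all(scn$truth_mask == 0L))
  expect_equal(scn$true_area_fraction, 0)
})

test_that("identical specs yield bit-identical scenes", {
  spec <- scene_spec(width = 128, height = 96, cell_radius_range = c(10, 16),
                     seed = 99)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth_mask, b$truth_mask)
  expect_identical(a$halo_mask, b$halo_mask)
  expect_identical(a$debris_mask, b$debris_mask)
})

test_that("truth bookkeeping is exact and cell size is plausible", {
  spec <- scene_spec(width = 200, height = 200, n_cells = 1,
                     cell_radius_range = c(20, 20), halo_fraction = 0,
                     n_debris = 0, noise_sigma = 0,
                     illumination_gradient_amp = 0, seed = 5)
  scn <- generate_scene(spec)
  n_truth <- sum(scn$truth_mask == 255L)
  expect_equal(scn$true_area_fraction, n_truth / (200 * 200))
  # body is a perturbed ellipse: nominal radius 20, axis ratio in [0.7, 1],
  # boundary modulation under 25% -> area within broad disk bounds
  expect_gt(n_truth, pi * 20^2 * 0.7 * 0.5)
  expect_lt(n_truth, pi * 20^2 * 1.6)
})

test_that("halo and debris pixels never overlap the truth mask", {
  scn <- clean_scene(13)
  expect_true(all(scn$truth_mask == 0L | scn$halo_mask == 0L))
  expect_true(all(scn$truth_mask == 0L | scn$debris_mask == 0L))
  expect_gt(sum(scn$halo_mask == 255L), 0)
  expect_gt(sum(scn$debris_mask == 255L), 0)
  # tones: bodies dark, background bright, debris bright
  body <- scn$image[scn$truth_mask == 255L]
  bg <- scn$image[scn$truth_mask == 0L & scn$halo_mask == 0L &
                    scn$debris_mask == 0L]
  expect_lt(mean(body), mean(bg))
})

test_that("corpus generation is deterministic and spans the jitter band", {
  spec <- scene_spec(width = 160, height = 120,
                     cell_radius_range = c(10, 18), n_debris = 4, seed = 3)
  c1 <- generate_corpus(spec, 8)
  c2 <- generate_corpus(spec, 8)
  for (i in seq_along(c1))
    expect_identical(c1[[i]]$image, c2[[i]]$image)
  expect_equal(length(unique(sapply(c1, function(s) s$spec$seed))), 8L)

  fracs <- sapply(c1, function(s) s$true_area_fraction)
  expect_lt(abs(mean(fracs) - spec$confluence_target), 0.1)
  # order-independent derived seeds: scene i does not depend on n
  c3 <- generate_corpus(spec, 3)
  expect_identical(c3[[2]]$image, c1[[2]]$image)
})

test_that("unreachable confluence raises a generation error", {
  spec <- scene_spec(width = 64, height = 64, confluence_target = 0.9,
                     cell_radius_range = c(3, 4), seed = 2)
  expect_error(generate_scene(spec, max_cells = 3), "unreachable")
  expect_error(generate_corpus(spec, 2, seed = 2), NA) # default cap is ample
})

test_that("spec validation rejects inconsistent tones and ranges", {
  expect_error(scene_spec(cell_intensity = 200, background_intensity = 150),
               "darker")
  expect_error(scene_spec(confluence_target = 1.2), "confluence_target")
  expect_error(scene_spec(cell_radius_range = c(10, 5)), "increasing")
  expect_error(scene_spec(halo_fraction = 2), "proportion")
})

test_that("artifact inclusion measures mask leakage onto halo and debris", {
  scn <- clean_scene(14)
  none <- matrix(0L, nrow(scn$image), ncol(scn$image))
  expect_equal(unname(artifact_inclusion(none, scn)), c(0, 0))
  all255 <- none + 255L
  expect_equal(unname(artifact_inclusion(as_int(all255), scn)), c(1, 1))
})

test_that("a written corpus has paired files and a faithful manifest", {
  dir <- withr::local_tempdir()
  spec <- scene_spec(width = 96, height = 64, cell_radius_range = c(8, 12),
                     n_debris = 2, seed = 21)
  corpus <- generate_corpus(spec, 3)
  write_corpus(corpus, dir)
  expect_true(all(file.exists(file.path(dir,
    c(sprintf("image_%04d.png", 1:3), sprintf("mask_%04d.png", 1:3),
      "manifest.json")))))
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(length(mf), 3L)
  expect_equal(mf[[2]]$true_area_fraction, corpus[[2]]$true_area_fraction)
  # masks round-trip exactly
  expect_identical(read_image(file.path(dir, "mask_0002.png")),
                   corpus[[2]]$truth_mask)
})
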