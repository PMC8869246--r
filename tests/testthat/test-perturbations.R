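# Robustness perturbations and the sweep driver.

test_that("blur perturbations match direct kernel arithmetic", {
  const <- matrix(90L, 8, 8)
  expect_identical(blur_perturb(const, "gaussian", 5), const)
  expect_identical(blur_perturb(const, "mean", 5), const)

  img <- matrix(0L, 7, 7); img[4, 4] <- 255L
  m3 <- blur_perturb(img, "mean", 3)
  expect_true(all(m3[3:5, 3:5] == round_up(255 / 9)))
  expect_true(all(m3[-(3:5), ] == 0L))

  # gaussian keeps a steeper step transition than mean at matched k
  step <- matrix(0L, 9, 20); step[, 11:20] <- 200L
  g <- blur_perturb(step, "gaussian", 3)
  m <- blur_perturb(step, "mean", 3)
  expect_gt(g[5, 11] - g[5, 9], m[5, 11] - m[5, 9])

  expect_error(blur_perturb(img, "mean", 4), "odd")
  expect_error(blur_perturb(img, "gaussian", 51), "3..49")
})

test_that("resize perturbation scales both dimensions, truth co-resizes", {
  img <- matrix(sample(0:255, 800 * 600, TRUE), 600, 800)
  half <- resize_perturb(img, 0.5)
  expect_equal(dim(half), c(300L, 400L))
  triple <- resize_perturb(img[1:60, 1:80], 3)
  expect_equal(dim(triple), c(180L, 240L))
  expect_identical(resize_perturb(img, 1), img)

  mask <- as_int((img > 128L) * 255L)
  rm <- resize_mask(mask, 0.5)
  expect_equal(dim(rm), c(300L, 400L))
  expect_true(all(rm == 0L | rm == 255L))
  expect_identical(resize_mask(mask, 1), mask)

  expect_error(resize_perturb(img, 0.4), "0.5")
  expect_error(resize_perturb(img, 3.5), "0.5")
})

test_that("illumination adjustments match their closed forms", {
  img <- matrix(c(0L, 100L, 200L, 255L), 2, 2)
  expect_identical(illum_normalize(img, 0), img)
  expect_identical(illum_subtract(img, 0), img)

  n150 <- illum_normalize(img, 150)
  expect_equal(n150[2, 2], 105L)
  expect_equal(n150[1, 1], 0L)
  expect_equal(n150, as_int(round_up(img / 255 * 105)))

  s150 <- illum_subtract(img, 150)
  expect_equal(s150[2, 2], 105L)
  expect_equal(s150[2, 1], 0L)   # 100 - 150 clamps at zero

  # normalization preserves full pixel ordering
  set.seed(70)
  r <- rand_gray(10, 10)
  rn <- illum_normalize(r, 75)
  expect_true(all(diff(rn[order(r)]) >= 0))

  expect_error(illum_normalize(img, 151), "0..150")
  expect_error(illum_subtract(img, 7), "steps of 5")
})

test_that("default sweep levels follow the protocol ranges", {
  expect_equal(sweep_levels("blur_gaussian"), seq(3, 49, 2))
  expect_equal(sweep_levels("blur_mean"), seq(3, 49, 2))
  expect_equal(range(sweep_levels("resize")), c(0.5, 3))
  expect_equal(sweep_levels("illum_subtract"), seq(0, 150, 5))
})

test_that("a degenerate one-level sweep equals direct corpus evaluation", {
  corpus <- lapply(c(31, 32), function(s) clean_scene(s, w = 200, h = 150))
  cfg <- seg_config(resize = FALSE)
  rep <- run_sweep(corpus, "illum_subtract", levels = 0, cfg)
  direct <- evaluate_corpus(
    lapply(corpus, function(s) segment_cells(s$image, cfg)$mask),
    lapply(corpus, function(s) s$truth_mask))
  expect_equal(rep$table$dice, direct$per_image$dice)
  expect_equal(rep$table$iou, direct$per_image$iou)
  expect_equal(rep$summary$dice, mean(direct$per_image$dice))
})

test_that("identity levels leave the pipeline output bit-identical", {
  scn <- clean_scene(33, w = 200, h = 150)
  cfg <- seg_config(resize = FALSE)
  base <- segment_cells(scn$image, cfg)
  expect_identical(segment_cells(illum_normalize(scn$image, 0), cfg)$mask,
                   base$mask)
  expect_identical(segment_cells(illum_subtract(scn$image, 0), cfg)$mask,
                   base$mask)
  expect_identical(segment_cells(resize_perturb(scn$image, 1), cfg)$mask,
                   base$mask)
})

test_that("resize-axis sweeps evaluate at the perturbed resolution", {
  corpus <- list(clean_scene(34, w = 200, h = 160))
  rep <- run_sweep(corpus, "resize", levels = c(0.5, 1), seg_config())
  expect_equal(nrow(rep$table), 2L)
  expect_true(all(is.finite(rep$table$dice)))
  expect_gte(min(rep$table$dice), 0)
  # at scalar 1 the truth is untouched, so metrics match a native run
  native <- segment_cells(corpus[[1]]$image, seg_config(resize = FALSE))
  expect_equal(rep$table$dice[rep$table$level == 1],
               dice(native$mask, corpus[[1]]$truth_mask))
})

test_that("sweep reports are deterministic and flag >100% errors", {
  corpus <- list(clean_scene(35, w = 160, h = 120))
  r1 <- run_sweep(corpus, "blur_gaussian", levels = c(3, 9),
                  seg_config(resize = FALSE))
  r2 <- run_sweep(corpus, "blur_gaussian", levels = c(3, 9),
                  seg_config(resize = FALSE))
  expect_identical(r1$table, r2$table)
  expect_type(r1$table$over_100pct, "logical")
  expect_output(print(r1), "blur_gaussian")
})
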