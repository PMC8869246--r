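# Dice, IoU, relative area error and corpus aggregation.

toy_332 <- function() {
  # |X| = 3, |Y| = 3, |X n Y| = 2 on a 4x4 grid
  x <- matrix(0L, 4, 4); x[c(1, 2, 3)] <- 255L
  y <- matrix(0L, 4, 4); y[c(2, 3, 9)] <- 255L
  list(x = x, y = y)
}

test_that("dice and IoU match the worked 3/3/2 example and identities", {
  t <- toy_332()
  expect_equal(dice(t$x, t$y), 2 * 2 / 6)
  expect_equal(iou(t$x, t$y), 0.5)
  expect_equal(dice(t$x, t$y) / (2 - dice(t$x, t$y)), iou(t$x, t$y))

  m <- rand_mask()
  expect_equal(dice(m, m), 1)
  expect_equal(iou(m, m), 1)

  a <- matrix(0L, 3, 3); a[1] <- 255L
  b <- matrix(0L, 3, 3); b[9] <- 255L
  expect_equal(dice(a, b), 0)
  expect_equal(iou(a, b), 0)
})

test_that("metric identities, symmetry and range hold on random pairs", {
  set.seed(50)
  for (i in 1:50) {
    x <- rand_mask(12, 12, runif(1, 0.1, 0.9))
    y <- rand_mask(12, 12, runif(1, 0.1, 0.9))
    d <- dice(x, y); j <- iou(x, y)
    expect_equal(j, d / (2 - d), tolerance = 1e-12)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_equal(d, dice(y, x))
    expect_equal(j, iou(y, x))
    expect_true(d >= 0 && d <= 1 && j >= 0 && j <= 1)
    expect_lte(j, d)
  }
})

test_that("empty-mask conventions: empty/empty is 1, empty/nonempty is 0", {
  e <- matrix(0L, 5, 5)
  m <- rand_mask(5, 5)
  m[1, 1] <- 255L
  expect_equal(dice(e, e), 1)
  expect_equal(iou(e, e), 1)
  expect_equal(dice(e, m), 0)
  expect_equal(iou(e, m), 0)
})

test_that("metrics are invariant to joint translation of both masks", {
  set.seed(51)
  x <- matrix(0L, 10, 10); x[3:5, 3:6] <- 255L
  y <- matrix(0L, 10, 10); y[4:6, 4:7] <- 255L
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  expect_equal(dice(shift(x, 2, 3), shift(y, 2, 3)), dice(x, y))
  expect_equal(iou(shift(x, 2, 3), shift(y, 2, 3)), iou(x, y))
})

test_that("relative area error follows its contract", {
  expect_equal(relative_area_error(0.4, 0.4), 0)
  expect_equal(relative_area_error(0.5, 0.4), 0.25)
  expect_gte(relative_area_error(0.01, 0.4), 0)
  expect_error(relative_area_error(0.5, 0), "positive")
})

test_that("corpus evaluation aggregates with population std by default", {
  m <- rand_mask(6, 6); m[1, 1] <- 255L
  rep1 <- evaluate_corpus(list(m, m), list(m, m))
  expect_equal(unname(rep1$mean), c(1, 1, 0))
  expect_equal(unname(rep1$std), c(0, 0, 0))

  single <- evaluate_corpus(list(m), list(m))
  expect_equal(single$n_images, 1L)
  expect_equal(unname(single$mean[["dice"]]), 1)

  # two pairs engineered to dice 0.8 and 1.0 -> mean 0.9, population std 0.1
  x1 <- matrix(0L, 2, 5); x1[1, 1:4] <- 255L   # |X| = 4
  y1 <- matrix(0L, 2, 5); y1[1, 2:5] <- 255L   # overlap 3: dice = 6/8
  # adjust to overlap giving dice exactly 0.8: |X|=|Y|=5, overlap 4
  x1 <- matrix(0L, 2, 5); x1[1, ] <- 255L
  y1 <- matrix(0L, 2, 5); y1[1, 1:4] <- 255L; y1[2, 5] <- 255L
  expect_equal(dice(x1, y1), 0.8)
  rep2 <- evaluate_corpus(list(x1, m), list(y1, m))
  expect_equal(unname(rep2$mean[["dice"]]), 0.9)
  expect_equal(unname(rep2$std[["dice"]]), 0.1)
  rep3 <- evaluate_corpus(list(x1, m), list(y1, m), std_mode = "sample")
  expect_equal(unname(rep3$std[["dice"]]), sd(c(0.8, 1)))

  expect_error(evaluate_corpus(list(), list()), "nonempty")
  expect_warning(evaluate_corpus(list(matrix(0L, 2, 2)),
                                 list(matrix(0L, 2, 2))), "empty reference")
})

test_that("report writers produce readable CSV and JSON", {
  m <- rand_mask(6, 6); m[2, 2] <- 255L
  rep <- evaluate_corpus(list(m), list(m))
  stem <- file.path(withr::local_tempdir(), "report")
  write_metrics_report(rep, stem)
  csv <- read.csv(paste0(stem, ".csv"))
  expect_equal(nrow(csv), 1L)
  js <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(js$mean$dice, 1)
})
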