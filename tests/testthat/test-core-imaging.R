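# Raster I/O, resizing, smoothing, sharpening, morphology primitives.

test_that("PNG round-trip preserves 8-bit grayscale exactly", {
  img <- rand_gray(12, 17)
  f <- withr::local_tempfile(fileext = ".png")
  write_image(img, f)
  expect_identical(read_image(f), as.matrix(img))
})

test_that("RGB input with equal channels converts to that gray value", {
  f <- withr::local_tempfile(fileext = ".png")
  arr <- array(200 / 255, dim = c(2, 2, 3))
  png::writePNG(arr, f)
  expect_true(all(read_image(f) == 200L))
})

test_that("16-bit input is rescaled to the 0..255 range", {
  f <- withr::local_tempfile(fileext = ".tif")
  x <- matrix(c(0, 0.25, 0.5, 1), 2, 2)  # writeTIFF stores [0,1] at 16 bit
  tiff::writeTIFF(x, f, bits.per.sample = 16L)
  img <- read_image(f)
  expect_equal(max(img), 255L)
  expect_equal(min(img), 0L)
})

test_that("unreadable inputs raise input errors naming the path", {
  expect_error(read_image("no/such/file.png"), "no/such/file.png")
  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(read_image(bad), "decode")
  expect_error(read_image(c("a.png", "b.png")), "single")
})

test_that("resize hits requested dimensions and preserves constants", {
  img <- matrix(sample(0:255, 1392 * 1040 %/% 16, TRUE), 1040 %/% 4, 1392 %/% 4)
  out <- resize_image(img, 800, 600)
  expect_equal(dim(out), c(600L, 800L))
  expect_true(all(out >= 0 & out <= 255))

  same <- resize_image(img, ncol(img), nrow(img))
  expect_identical(same, img)

  const <- matrix(77L, 33, 47)
  for (m in c("auto", "bilinear", "area", "nearest"))
    expect_true(all(resize_image(const, 20, 61, method = m) == 77L))

  expect_error(resize_image(img, 0, 10), "positive")
})

test_that("gaussian blur matches the discrete kernel definition", {
  expect_true(all(gaussian_blur(matrix(100L, 5, 5), 3) == 100L))

  # derived: single bright pixel against the 1-D kernel built from scratch
  sigma <- 0.3 * ((3 - 1) / 2 - 1) + 0.8
  w1 <- exp(-(-1:1)^2 / (2 * sigma^2)); w1 <- w1 / sum(w1)
  img <- matrix(0L, 7, 7); img[4, 4] <- 255L
  out <- gaussian_blur(img, 3)
  expect_equal(out[4, 4], round_up(255 * w1[2]^2))
  expect_equal(out[3, 4], round_up(255 * w1[1] * w1[2]))

  expect_equal(sum(gaussian_kernel(49)), 1, tolerance = 1e-9)
  expect_error(gaussian_blur(img, 4), "odd")

  scn <- clean_scene(3)
  expect_lt(var(as.vector(gaussian_blur(scn$image, 49))),
            var(as.vector(scn$image)))
})

test_that("sharpening is the saturating 3x3 Laplacian kernel", {
  expect_true(all(sharpen(matrix(128L, 4, 4)) == 128L))
  expect_true(all(sharpen(matrix(255L, 4, 4)) == 255L))

  img <- matrix(0L, 5, 5); img[3, 3] <- 100L
  out <- sharpen(img)
  expect_equal(out[3, 3], 255L)          # 5*100 clamped
  expect_equal(out[3, 2], 0L)            # -100 clamped
  expect_equal(out[2, 3], 0L)
  expect_equal(out[1, 1], 0L)
})

test_that("grayscale dilation/erosion match the worked examples", {
  f <- matrix(0L, 3, 3); f[2, 2] <- 9L
  expect_true(all(gray_dilate(f, 3) == 9L))

  g <- matrix(9L, 3, 3); g[2, 2] <- 0L
  expect_true(all(gray_erode(g, 3) == 0L))

  const <- matrix(42L, 6, 6)
  expect_identical(gray_dilate(const, 3), const)
  expect_identical(gray_erode(const, 3), const)

  img <- rand_gray()
  expect_identical(gray_dilate(img, 1), as.matrix(img))  # 1x1 SE
  expect_identical(gray_erode(img, 1), as.matrix(img))
})

test_that("extensivity sandwich holds on random images and SEs", {
  ses <- list(se_rect(3), se_rect(5, 3), as_se(matrix(c(0,1,0,1,1,1,0,1,0), 3)))
  set.seed(20)
  for (i in 1:10) {
    img <- rand_gray()
    for (se in ses) {
      expect_true(all(gray_erode(img, se) <= img))
      expect_true(all(img <= gray_dilate(img, se)))
    }
  }
})

test_that("binary morphology: worked examples, duality, idempotence", {
  z <- matrix(0L, 5, 5)
  expect_identical(binary_dilate(z, 3), z)
  one <- z; one[3, 3] <- 255L
  d <- binary_dilate(one, 3)
  expect_equal(sum(d == 255L), 9L)
  expect_true(all(d[2:4, 2:4] == 255L))
  full <- matrix(255L, 5, 5)
  expect_identical(binary_dilate(full, 3), full)
  expect_identical(binary_erode(full, 3), full)

  blk <- z; blk[2:4, 2:4] <- 255L
  e <- binary_erode(blk, 3)
  expect_equal(which(e == 255L), 13L)  # only the centre [3, 3] survives

  # De Morgan duality for a symmetric SE
  set.seed(21)
  for (i in 1:10) {
    m <- rand_mask()
    compl <- 255L - m
    expect_identical(binary_erode(m, 3), 255L - binary_dilate(compl, 3))
  }

  # open removes an isolated pixel; close fills a 1-px hole
  iso <- matrix(0L, 7, 7); iso[4, 4] <- 255L
  expect_true(all(binary_open(iso, 3) == 0L))
  holed <- matrix(0L, 9, 9); holed[3:7, 3:7] <- 255L; holed[5, 5] <- 0L
  expect_true(all(binary_close(holed, 3)[3:7, 3:7] == 255L))

  set.seed(22)
  for (i in 1:5) {
    m <- rand_mask()
    expect_identical(binary_open(binary_open(m, 3), 3), binary_open(m, 3))
    expect_identical(binary_close(binary_close(m, 3), 3), binary_close(m, 3))
  }
})

test_that("structuring element validation enforces odd sides and content", {
  expect_error(se_rect(4), "odd")
  expect_error(as_se(matrix(0, 3, 3)), "active")
  expect_s3_class(se_rect(9), "struct_el")
  expect_equal(sum(se_rect(9)$shape), 81)
})
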