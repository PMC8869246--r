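# Independent reference implementations ("oracles") the fast kernels are
# checked against, plus small fixture builders.  Everything here is written
# the slow, obvious way on purpose and shares no code with the package
# internals.

# round half away from zero (for nonnegative pixel values)
round_up <- function(x) floor(x + 0.5)

as_int <- function(x) {
  storage.mode(x) <- "integer"
  x
}

# Triple-loop window scan over an arbitrary SE with replicate-edge borders.
oracle_rank <- function(img, se_shape, fun) {
  h <- nrow(img); w <- ncol(img)
  ar <- (nrow(se_shape) - 1L) %/% 2L
  ac <- (ncol(se_shape) - 1L) %/% 2L
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      vals <- c()
      for (i in seq_len(nrow(se_shape))) {
        for (j in seq_len(ncol(se_shape))) {
          if (se_shape[i, j] != 0) {
            rr <- min(max(r + i - 1L - ar, 1L), h)
            cc <- min(max(c + j - 1L - ac, 1L), w)
            vals <- c(vals, img[rr, cc])
          }
        }
      }
      out[r, c] <- fun(vals)
    }
  }
  out
}

oracle_gray_dilate <- function(img, se_shape) oracle_rank(img, se_shape, max)
oracle_gray_erode <- function(img, se_shape) oracle_rank(img, se_shape, min)
oracle_bin_dilate <- function(m, se_shape)
  oracle_rank(m, se_shape, function(v) if (any(v == 255)) 255L else 0L)
oracle_bin_erode <- function(m, se_shape)
  oracle_rank(m, se_shape, function(v) if (any(v == 0)) 0L else 255L)

# Exhaustive Otsu search: per-candidate class statistics computed directly
# from the pixel values (no histogram recurrences).
oracle_otsu <- function(img) {
  v <- as.vector(img)
  n <- length(v)
  obj <- numeric(256)
  for (t in 0:255) {
    b <- v[v <= t]; f <- v[v > t]
    vb <- if (length(b)) mean((b - mean(b))^2) else 0
    vf <- if (length(f)) mean((f - mean(f))^2) else 0
    obj[t + 1] <- (length(b) / n) * vb + (length(f) / n) * vf
  }
  list(threshold = which.min(obj) - 1L, objective = obj)
}

# between-class variance for the duality check
oracle_between_class <- function(img) {
  v <- as.vector(img)
  n <- length(v); mu <- mean(v)
  sapply(0:255, function(t) {
    b <- v[v <= t]; f <- v[v > t]
    wb <- length(b) / n; wf <- length(f) / n
    mb <- if (length(b)) mean(b) else 0
    mf <- if (length(f)) mean(f) else 0
    wb * (mb - mu)^2 + wf * (mf - mu)^2
  })
}

rand_gray <- function(h = 16, w = 16) {
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

rand_mask <- function(h = 16, w = 16, p = 0.4) {
  matrix(sample(c(0L, 255L), h * w, replace = TRUE, prob = c(1 - p, p)), h, w)
}

# a clean small scene shared by several tests
clean_scene <- function(seed = 101, w = 320, h = 240) {
  generate_scene(scene_spec(width = w, height = h,
                            cell_radius_range = c(14, 26),
                            n_debris = 6, illumination_gradient_amp = 15,
                            noise_sigma = 4, seed = seed))
}
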