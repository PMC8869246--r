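# Raster I/O and the internal image conventions.
#
# A grayscale image ("GrayImage") is an integer matrix, values 0..255.
# A binary mask is the same but restricted to {0, 255}.  PNG and TIFF are the
# canonical on-disk formats, 8-bit grayscale for images and masks.

# round() in R rounds half to even; image arithmetic conventionally rounds
# half away from zero, which for nonnegative pixels is floor(x + 0.5).
round_px <- function(x) floor(x + 0.5)

clamp255 <- function(x) pmin(pmax(x, 0), 255)

assert_gray <- function(img, arg = deparse(substitute(img))) {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop(sprintf("`%s` must have at least one row and one column", arg),
         call. = FALSE)
  rng <- range(img)
  if (is.na(rng[1L]) || rng[1L] < 0 || rng[2L] > 255)
    stop(sprintf("`%s` must contain values in [0, 255] without NAs", arg),
         call. = FALSE)
  invisible(img)
}

assert_mask <- function(mask, arg = deparse(substitute(mask))) {
  assert_gray(mask, arg)
  if (!all(mask == 0L | mask == 255L))
    stop(sprintf("`%s` must contain only the values 0 and 255", arg),
         call. = FALSE)
  invisible(mask)
}

assert_same_dim <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images must share dimensions (", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"), ")", call. = FALSE)
  invisible(NULL)
}

as_int_img <- function(img) {
  storage.mode(img) <- "integer"
  img
}

#' Read a micrograph as an 8-bit grayscale image
#'
#' Decodes a PNG or TIFF file into the package's working representation: an
#' integer matrix with values 0..255.  RGB(A) inputs are converted to
#' luminance with the ITU-R BT.601 weights (0.299, 0.587, 0.114); 16-bit
#' inputs are rescaled to the 0..255 range.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An integer matrix (rows = image rows) with values in 0..255.
#' @examples
#' f <- tempfile(fileext = ".png")
#' write_image(matrix(0:255, 16, 16), f)
#' img <- read_image(f)
#' range(img)
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("`path` must be a single file path", call. = FALSE)
  if (!file.exists(path))
    stop("cannot read image: file does not exist: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop("unsupported image format '.", ext, "' for: ", path, call. = FALSE)
    ),
    error = function(e) stop("cannot decode image: ", path, " (",
                             conditionMessage(e), ")", call. = FALSE)
  )
  # png/tiff return values normalised to [0, 1] for 8- and 16-bit data alike.
  if (length(dim(x)) == 3L) {
    nc <- dim(x)[3L]
    if (nc %in% c(3L, 4L)) {
      x <- 0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
    } else if (nc == 1L) {
      x <- x[, , 1L]
    } else if (nc == 2L) {  # gray + alpha
      x <- x[, , 1L]
    } else {
      stop("unsupported channel layout (", nc, " channels) in: ", path,
           call. = FALSE)
    }
  }
  if (!is.matrix(x))
    stop("unsupported image layout in: ", path, call. = FALSE)
  as_int_img(clamp255(round_px(x * 255)))
}

#' Write a grayscale image or binary mask to disk
#'
#' Images are written as 8-bit grayscale; masks keep their exact \{0, 255\}
#' values.  The format is chosen from the file extension (`.png`, `.tif`,
#' `.tiff`).
#'
#' @param img Integer matrix with values in 0..255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_gray(img)
  ext <- tolower(tools::file_ext(path))
  x <- img / 255
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported output format '.", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' @rdname write_image
#' @export
write_mask <- function(img, path) {
  assert_mask(img)
  write_image(img, path)
}

#' Resize a grayscale image
#'
#' The pipeline's working resolution is 800 wide by 600 tall (the conventional
#' 4:3 phase-contrast frame).  Shrinking uses area averaging (each output
#' pixel integrates its source footprint, which suppresses aliasing);
#' enlarging uses bilinear interpolation; `"nearest"` is provided for binary
#' masks, where interpolation would create intermediate values.
#'
#' @param img Integer matrix, values 0..255.
#' @param width,height Target dimensions in pixels (positive integers).
#' @param method `"auto"` (area when both dimensions shrink, bilinear
#'   otherwise), `"bilinear"`, `"area"` or `"nearest"`.
#' @return Resized integer matrix of dimension `height` x `width`.
#' @examples
#' img <- matrix(sample(0:255, 64 * 48, TRUE), 48, 64)
#' dim(resize_image(img, 32, 24))
#' @export
resize_image <- function(img, width, height,
                         method = c("auto", "bilinear", "area", "nearest")) {
  assert_gray(img)
  method <- match.arg(method)
  if (length(width) != 1L || length(height) != 1L ||
      is.na(width) || is.na(height) || width < 1 || height < 1)
    stop("target dimensions must be positive integers", call. = FALSE)
  width <- as.integer(width)
  height <- as.integer(height)
  if (width == ncol(img) && height == nrow(img) && method != "nearest")
    return(as_int_img(img))
  m <- switch(method,
    auto = if (width <= ncol(img) && height <= nrow(img)) 2L else 1L,
    nearest = 0L,
    bilinear = 1L,
    area = 2L
  )
  cpp_resize(as_int_img(img), height, width, m)
}
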