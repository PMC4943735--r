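# Imaging calibration: loading photographs, white-standard color
# calibration, cropping to the body extent, luminance, and the
# pixels-to-length conversion used for body measurements from scaled
# photographs.
#
# Conventions used throughout the package:
#   * pixel arrays are H x W x 3 numeric arrays of gamma-encoded sRGB
#     values in [0, 1], row-major (row 1 = top of the image);
#   * all rectangles are 0-based, half-open: rows row0 <= r < row1,
#     columns col0 <= c < col1.

MIN_IMAGE_SIDE <- 32L

#' Construct a raw image from a pixel array
#'
#' Wraps an in-memory H x W x 3 array as the package's raw-image type.
#' Grayscale matrices are replicated across the three channels.
#'
#' @param pixels Numeric H x W x 3 array (or H x W matrix) with values in
#'   \[0, 1\].
#' @param source_path Provenance string recorded on the object.
#' @return An object of class `raw_image` with fields `pixels`, `height`,
#'   `width`, `source_path`.
#' @export
new_raw_image <- function(pixels, source_path = "<in-memory>") {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_validation("pixels must be an H x W x 3 array or an H x W matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop_validation("pixel values must lie in [0, 1] with no missing values")
  d <- dim(pixels)
  if (d[1] < MIN_IMAGE_SIDE || d[2] < MIN_IMAGE_SIDE)
    stop_validation("image too small: both sides must be >= ", MIN_IMAGE_SIDE, " pixels")
  structure(
    list(pixels = pixels, height = as.integer(d[1]), width = as.integer(d[2]),
         source_path = source_path),
    class = "raw_image")
}

#' Load a photograph from disk
#'
#' Reads a PNG, TIFF or JPEG raster and returns pixels scaled to \[0, 1\]
#' regardless of the source bit depth. Single-channel sources are
#' replicated to three channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a decodable raster file.
#' @return A [new_raw_image()] object.
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop_validation("path must be a single file path")
  if (!file.exists(path))
    stop("cannot read image: file does not exist: ", path, call. = FALSE)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot read image '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  px <- EBImage::imageData(img)   # x (columns) first in EBImage
  if (length(dim(px)) == 2L) {
    px <- t(px)
  } else {
    if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(px)[3] == 1L) px <- px[, , 1L]
    px <- if (length(dim(px)) == 2L) t(px) else aperm(px, c(2L, 1L, 3L))
  }
  px <- pmin(pmax(px, 0), 1)
  new_raw_image(px, source_path = path)
}

#' Write an image to an 8-bit PNG file
#'
#' @param img A `raw_image` or `calibrated_image`.
#' @param path Output path (".png").
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  px <- image_pixels(img)
  EBImage::writeImage(EBImage::Image(aperm(px, c(2L, 1L, 3L)), colormode = "Color"),
                      path, type = "png", bits.per.sample = 8L)
  invisible(path)
}

image_pixels <- function(img) {
  if (inherits(img, c("raw_image", "calibrated_image"))) return(img$pixels)
  stop_validation("expected a raw_image or calibrated_image")
}

#' Rectangular regions (0-based, half-open)
#'
#' `ref_region()` marks the in-frame white standard used for calibration
#' (area of at least 16 px); `crop_box()` marks the body extent for
#' cropping. Both use 0-based half-open coordinates: the rectangle covers
#' rows `row0 <= r < row1` and columns `col0 <= c < col1`.
#'
#' @param row0,col0,row1,col1 Integer corners.
#' @return An object of class `ref_region` or `crop_box`.
#' @export
ref_region <- function(row0, col0, row1, col1) {
  r <- validate_rect(row0, col0, row1, col1)
  if ((r$row1 - r$row0) * (r$col1 - r$col0) < 16L)
    stop_validation("reference region must cover at least 16 pixels")
  class(r) <- "ref_region"
  r
}

#' @rdname ref_region
#' @export
crop_box <- function(row0, col0, row1, col1) {
  r <- validate_rect(row0, col0, row1, col1)
  class(r) <- "crop_box"
  r
}

validate_rect <- function(row0, col0, row1, col1) {
  v <- c(row0, col0, row1, col1)
  if (anyNA(v) || !is.numeric(v) || any(v != round(v)))
    stop_validation("rectangle corners must be integers")
  if (row1 <= row0 || col1 <= col0)
    stop_validation("rectangle must be non-empty (half-open: row1 > row0, col1 > col0)")
  if (row0 < 0 || col0 < 0)
    stop_validation("rectangle corners must be non-negative")
  list(row0 = as.integer(row0), col0 = as.integer(col0),
       row1 = as.integer(row1), col1 = as.integer(col1))
}

check_rect_inside <- function(rect, img) {
  if (rect$row1 > img$height || rect$col1 > img$width)
    stop_validation("rectangle [", rect$row0, ",", rect$row1, ") x [",
                    rect$col0, ",", rect$col1, ") lies outside the ",
                    img$height, " x ", img$width, " image")
  invisible(rect)
}

rect_rows <- function(rect) (rect$row0 + 1L):rect$row1
rect_cols <- function(rect) (rect$col0 + 1L):rect$col1

#' White-standard color calibration
#'
#' Standardizes image colors against an in-frame white reference (the
#' "white standard", e.g. a white ruler photographed with the animal). A
#' per-channel linear gain `g_c = reference_white_c / mean_c(reference
#' region)` is applied to every pixel, then values are clipped to \[0, 1\].
#' After calibration (before clipping) the mean over the reference region
#' equals `reference_white` exactly, making colors comparable across
#' photographs taken under different illumination.
#'
#' @param img A `raw_image` or `calibrated_image`.
#' @param ref A [ref_region()] inside the image covering the white standard.
#' @param reference_white Length-3 target value for the reference region
#'   (default white, `c(1, 1, 1)`).
#' @return A `calibrated_image`: fields `pixels` (clipped to \[0,1\]),
#'   `gains` (the 3 per-channel gains), `reference_white`, `height`,
#'   `width`.
#' @export
calibrate_white <- function(img, ref, reference_white = c(1, 1, 1)) {
  px <- image_pixels(img)
  if (!inherits(ref, "ref_region")) stop_validation("ref must be a ref_region")
  if (!is.numeric(reference_white) || length(reference_white) != 3L ||
      any(reference_white <= 0) || any(reference_white > 1))
    stop_validation("reference_white must be 3 values in (0, 1]")
  check_rect_inside(ref, img)
  means <- vapply(1:3, function(ch)
    mean(px[rect_rows(ref), rect_cols(ref), ch]), numeric(1))
  if (any(means <= 0))
    stop_validation("degenerate reference: a channel mean over the reference region is 0")
  gains <- reference_white / means
  out <- px
  for (ch in 1:3) out[, , ch] <- pmin(pmax(px[, , ch] * gains[ch], 0), 1)
  structure(
    list(pixels = out, gains = gains, reference_white = reference_white,
         height = img$height, width = img$width),
    class = "calibrated_image")
}

#' Wrap a pixel array as an already-calibrated image
#'
#' Used when pixels are produced directly in calibrated units (e.g. by the
#' synthetic generator's reflectance model) or when calibration is not
#' applicable.
#'
#' @inheritParams new_raw_image
#' @param gains Per-channel gains to record (default `c(1, 1, 1)`).
#' @return A `calibrated_image`.
#' @export
as_calibrated_image <- function(pixels, gains = c(1, 1, 1)) {
  raw <- new_raw_image(pixels)
  structure(
    list(pixels = raw$pixels, gains = gains, reference_white = c(1, 1, 1),
         height = raw$height, width = raw$width),
    class = "calibrated_image")
}

#' Crop a calibrated image to the body extent
#'
#' @param img A `calibrated_image`.
#' @param box A [crop_box()] (0-based, half-open) inside the image.
#' @return The sub-image as a `calibrated_image`; calibration gains are
#'   preserved.
#' @export
crop_body <- function(img, box) {
  if (!inherits(img, "calibrated_image"))
    stop_validation("img must be a calibrated_image (calibrate before cropping)")
  if (!inherits(box, "crop_box")) stop_validation("box must be a crop_box")
  check_rect_inside(box, img)
  px <- img$pixels[rect_rows(box), rect_cols(box), , drop = FALSE]
  structure(
    list(pixels = px, gains = img$gains, reference_white = img$reference_white,
         height = nrow(px), width = ncol(px)),
    class = "calibrated_image")
}

#' Compose two crop rectangles
#'
#' `compose_crops(a, b)` returns the single box such that cropping with it
#' equals cropping with `a` and then cropping the result with `b`.
#'
#' @param a,b [crop_box()] objects; `b` is interpreted in the coordinate
#'   system of the image cropped by `a`.
#' @return A `crop_box`.
#' @export
compose_crops <- function(a, b) {
  crop_box(a$row0 + b$row0, a$col0 + b$col0, a$row0 + b$row1, a$col0 + b$col1)
}

#' Luminance image
#'
#' Collapses a calibrated RGB image to the achromatic luminance channel
#' using the ITU-R BT.601 weights, `L = 0.299 R + 0.587 G + 0.114 B`.
#' This is the input of the grayscale (pattern-only) pathway and the
#' white/black opponent pair.
#'
#' @param img A `calibrated_image` (or `raw_image`).
#' @return An H x W numeric matrix in \[0, 1\].
#' @export
to_luminance <- function(img) {
  px <- image_pixels(img)
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

#' Convert a pixel span to physical length
#'
#' Given a span measured in pixels and the image scale (from an in-frame
#' ruler of known tick spacing), returns the physical length
#' `pixel_span / scale_pixels_per_unit`. Landmark placement itself is
#' manual and outside the package.
#'
#' @param pixel_span Measured span, pixels (> 0).
#' @param scale_pixels_per_unit Image scale, pixels per physical unit (> 0).
#' @return Length in the ruler's unit.
#' @export
pixels_to_length <- function(pixel_span, scale_pixels_per_unit) {
  if (!is_scalar_number(pixel_span) || pixel_span <= 0)
    stop_validation("pixel_span must be a positive number")
  if (!is_scalar_number(scale_pixels_per_unit) || scale_pixels_per_unit <= 0)
    stop_validation("scale_pixels_per_unit must be a positive number")
  pixel_span / scale_pixels_per_unit
}

#' Area-averaging downscale
#'
#' Resizes an image so that its longer side is at most `max_side`, using
#' exact area averaging (each output pixel is the area-weighted mean of the
#' input pixels it covers). Full-resolution photographs are reduced to a
#' desk-scale working size before feature extraction; images already within
#' the limit are returned unchanged.
#'
#' @param img A `calibrated_image`.
#' @param max_side Maximum allowed longer side, pixels (default 256).
#' @return A `calibrated_image`.
#' @export
resize_max_side <- function(img, max_side = 256L) {
  if (!inherits(img, "calibrated_image")) stop_validation("img must be a calibrated_image")
  if (!is_scalar_number(max_side) || max_side < MIN_IMAGE_SIDE)
    stop_validation("max_side must be >= ", MIN_IMAGE_SIDE)
  long <- max(img$height, img$width)
  if (long <= max_side) return(img)
  s <- max_side / long
  hout <- max(MIN_IMAGE_SIDE, round(img$height * s))
  wout <- max(MIN_IMAGE_SIDE, round(img$width * s))
  Wr <- area_weights(img$height, hout)
  Wc <- area_weights(img$width, wout)
  px <- array(0, dim = c(hout, wout, 3L))
  for (ch in 1:3) px[, , ch] <- Wr %*% img$pixels[, , ch] %*% t(Wc)
  structure(
    list(pixels = pmin(pmax(px, 0), 1), gains = img$gains,
         reference_white = img$reference_white, height = hout, width = wout),
    class = "calibrated_image")
}

# n_out x n_in matrix of fractional-overlap weights: row i holds the
# fraction of each input pixel covered by output pixel i; rows sum to 1.
area_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1
    j1 <- min(ceiling(hi), n_in)
    for (j in j0:j1) {
      overlap <- min(hi, j) - max(lo, j - 1)
      if (overlap > 0) W[i, j] <- overlap / scale
    }
  }
  W
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat("calibrated_image:", x$height, "x", x$width,
      " gains =", paste(signif(x$gains, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.raw_image <- function(x, ...) {
  cat("raw_image:", x$height, "x", x$width, " from", x$source_path, "\n")
  invisible(x)
}
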