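#' Image containers
#'
#' Light S3 containers used throughout the pipeline. All images are stored as
#' base R numeric matrices/arrays indexed `[row, col]` with 1-based indices
#' and pixel centers at integer coordinates; this convention is used
#' consistently by every module.
#'
#' * `color_image()` — an H x W x 3 array of nonnegative intensities
#'   (R, G, B planes) in camera counts; `bit_depth` gives the effective bit
#'   depth (default 12 bits carried in a 16-bit container) and
#'   `resolution_px_per_mm` the spatial sampling (default 18 px/mm).
#' * `mono_image()` — a single extracted channel or any intermediate plane.
#' * `boll_mask()` — a binary H x W matrix, 1 on the boll and 0 on background.
#' * `ratio_image()` — the masked pixel-wise green/red ratio, 0 on background.
#'
#' @param pixels numeric array (H x W x 3) or matrix (H x W).
#' @param bit_depth effective bits per channel; values must be < 2^bit_depth.
#' @param resolution_px_per_mm spatial resolution in pixels per millimetre.
#' @param mask a `boll_mask` for `ratio_image`.
#' @return An object of the corresponding class.
#' @name image-containers
NULL

#' @rdname image-containers
#' @export
color_image <- function(pixels, bit_depth = 12L, resolution_px_per_mm = 18) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 2L || d[2] < 2L)
    stop("degenerate image: need at least 2 x 2 pixels")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("image contains non-finite pixels")
  if (any(pixels < 0))
    stop("image contains negative pixels")
  if (any(pixels >= 2^bit_depth))
    stop("pixel values exceed the stated bit depth (", bit_depth, " bits)")
  if (resolution_px_per_mm <= 0)
    stop("`resolution_px_per_mm` must be positive")
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 resolution_px_per_mm = resolution_px_per_mm),
            class = "color_image")
}

#' @rdname image-containers
#' @export
mono_image <- function(pixels, resolution_px_per_mm = 18) {
  pixels <- as.matrix(pixels)
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("image contains non-finite pixels")
  structure(list(pixels = pixels, resolution_px_per_mm = resolution_px_per_mm),
            class = "mono_image")
}

#' @rdname image-containers
#' @export
boll_mask <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (!all(pixels %in% c(0, 1)))
    stop("mask values must be 0 or 1")
  structure(list(pixels = pixels), class = "boll_mask")
}

#' @rdname image-containers
#' @export
ratio_image <- function(pixels, mask, resolution_px_per_mm = 18) {
  pixels <- as.matrix(pixels)
  stopifnot(inherits(mask, "boll_mask"),
            all(dim(pixels) == dim(mask$pixels)))
  if (any(!is.finite(pixels)))
    stop("ratio image contains non-finite pixels")
  if (any(pixels[mask$pixels == 0] != 0))
    stop("ratio image must be exactly 0 outside the mask")
  structure(list(pixels = pixels, mask = mask,
                 resolution_px_per_mm = resolution_px_per_mm),
            class = "ratio_image")
}

#' @export
print.color_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<color_image> %d x %d x 3, %d-bit, %.3g px/mm\n",
              d[1], d[2], x$bit_depth, x$resolution_px_per_mm))
  invisible(x)
}

#' @export
print.ratio_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<ratio_image> %d x %d, %.3g px/mm, %d boll px\n",
              d[1], d[2], x$resolution_px_per_mm, sum(x$mask$pixels)))
  invisible(x)
}

#' Extract one channel of a color image
#'
#' @param img a `color_image`.
#' @param channel `"red"`, `"green"` or `"blue"`.
#' @return a `mono_image`.
#' @export
extract_channel <- function(img, channel = c("red", "green", "blue")) {
  stopifnot(inherits(img, "color_image"))
  channel <- match.arg(channel)
  k <- match(channel, c("red", "green", "blue"))
  mono_image(img$pixels[, , k], img$resolution_px_per_mm)
}

#' Read a boll photograph from a TIFF file
#'
#' Reads a single RGB TIFF. 16-bit containers are assumed to carry 12-bit
#' camera data (values are validated against `bit_depth`); 8-bit files are
#' accepted with a warning and promoted to the 12-bit scale.
#'
#' @param path TIFF file path.
#' @param bit_depth effective bit depth of the camera data (default 12).
#' @param resolution_px_per_mm spatial resolution of the raw photograph
#'   (default 36 px/mm; the pipeline's 2 x 2 binning brings this to the
#'   18 px/mm working resolution all mark thresholds are stated at).
#' @return a `color_image`.
#' @export
read_boll_tiff <- function(path, bit_depth = 12L, resolution_px_per_mm = 36) {
  raw <- tiff::readTIFF(path, info = TRUE)
  if (length(dim(raw)) == 2L)
    stop("expected an RGB TIFF, got a single-channel image: ", path)
  bps <- attr(raw, "bits.per.sample")
  if (is.null(bps)) bps <- 16L
  raw <- raw[, , 1:3, drop = FALSE] * (2^bps - 1)  # back to integer counts
  if (bps == 8) {
    warning("8-bit TIFF promoted to ", bit_depth, "-bit scale: ", path)
    raw <- raw * (2^bit_depth - 1) / 255
  }
  color_image(raw, bit_depth = bit_depth,
              resolution_px_per_mm = resolution_px_per_mm)
}

#' Write an image to TIFF
#'
#' Color images are written as 16-bit RGB; mono and ratio images as 32-bit
#' float single-plane TIFFs (used for `--save-intermediates` debugging).
#' Float planes are stored divided by 8 because the TIFF writer only stores
#' \[0,1\] data; green/red ratios and normalized intermediates stay well
#' below 8, so the stored plane is `value / 8` at full float precision.
#'
#' @param img a `color_image`, `mono_image` or `ratio_image`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  if (inherits(img, "color_image")) {
    tiff::writeTIFF(img$pixels / (2^16 - 1), path, bits.per.sample = 16L)
  } else if (inherits(img, c("mono_image", "ratio_image"))) {
    if (max(img$pixels) > 8 || min(img$pixels) < 0)
      stop("float TIFF output expects values in [0, 8]")
    tiff::writeTIFF(img$pixels / 8, path, bits.per.sample = 32L)
  } else stop("unsupported image class")
  invisible(path)
}
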