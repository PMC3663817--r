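#' Center-weighted median filter
#'
#' Per-channel windowed median in which the center pixel is entered
#' `center_weight` times into the window's multiset before the median is
#' taken, so that fine detail is better preserved than with a plain median.
#' Borders are handled by edge replication.
#'
#' @param img a `color_image` or `mono_image`.
#' @param window odd window side length, >= 3.
#' @param center_weight how many times the center pixel is counted (>= 1).
#'   `center_weight = 1` is the ordinary median filter.
#' @return filtered image of the same class and size.
#' @export
center_weighted_median <- function(img, window = 3L, center_weight = 3L) {
  window <- as.integer(window); center_weight <- as.integer(center_weight)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be odd and >= 3")
  if (center_weight < 1L) stop("`center_weight` must be >= 1")
  if (inherits(img, "color_image")) {
    out <- img$pixels
    for (k in 1:3)
      out[, , k] <- .cw_median_plane(img$pixels[, , k], window, center_weight)
    color_image(out, img$bit_depth, img$resolution_px_per_mm)
  } else if (inherits(img, "mono_image")) {
    mono_image(.cw_median_plane(img$pixels, window, center_weight),
               img$resolution_px_per_mm)
  } else stop("`img` must be a color_image or mono_image")
}

.bin2x2_plane <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  nr2 <- nr %/% 2L; nc2 <- nc %/% 2L
  m <- m[seq_len(2L * nr2), seq_len(2L * nc2), drop = FALSE]
  0.25 * (m[seq(1, 2 * nr2, 2), seq(1, 2 * nc2, 2), drop = FALSE] +
          m[seq(2, 2 * nr2, 2), seq(1, 2 * nc2, 2), drop = FALSE] +
          m[seq(1, 2 * nr2, 2), seq(2, 2 * nc2, 2), drop = FALSE] +
          m[seq(2, 2 * nr2, 2), seq(2, 2 * nc2, 2), drop = FALSE])
}

#' 2 x 2 binning
#'
#' Halves the image resolution by replacing each 2 x 2 block with its mean,
#' per channel. An odd trailing row/column is dropped with a warning. The
#' stored resolution in px/mm is halved accordingly.
#'
#' @param img a `color_image` or `mono_image`.
#' @return binned image of the same class.
#' @export
bin2x2 <- function(img) {
  px <- if (inherits(img, "color_image")) img$pixels else img$pixels
  d <- dim(px)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    warning("odd image dimension: trailing row/column dropped before binning")
  if (inherits(img, "color_image")) {
    out <- vapply(1:3, function(k) .bin2x2_plane(img$pixels[, , k]),
                  matrix(0, d[1] %/% 2L, d[2] %/% 2L))
    color_image(out, img$bit_depth, img$resolution_px_per_mm / 2)
  } else {
    mono_image(.bin2x2_plane(img$pixels), img$resolution_px_per_mm / 2)
  }
}

#' Frequency-domain Butterworth low-pass filter
#'
#' Filters a single-channel image in the frequency domain with the standard
#' Butterworth amplitude response
#' `H(f) = 1 / sqrt(1 + (f/f_c)^(2 * order))`, where `f` is the radial
#' spatial frequency in cycles/pixel and `f_c = 1/cutoff_px`, i.e. the
#' cutoff is expressed as a spatial wavelength in pixels. The gain is 1 at
#' DC (the image mean is preserved) and 1/sqrt(2) (-3 dB) at the cutoff.
#'
#' @param img a `mono_image`.
#' @param order filter order (default 2, i.e. a second-order Butterworth).
#' @param cutoff_px cutoff wavelength in pixels (default 10).
#' @return filtered `mono_image`.
#' @export
butterworth_lowpass <- function(img, order = 2L, cutoff_px = 10) {
  stopifnot(inherits(img, "mono_image"))
  if (cutoff_px <= 0) stop("`cutoff_px` must be positive")
  m <- img$pixels
  if (any(!is.finite(m))) stop("non-finite pixels in input")
  nr <- nrow(m); nc <- ncol(m)
  fr <- .fft_freq(nr); fc <- .fft_freq(nc)
  f <- sqrt(outer(fr^2, fc^2, `+`))
  H <- 1 / sqrt(1 + (f * cutoff_px)^(2 * order))
  out <- Re(fft(fft(m) * H, inverse = TRUE)) / (nr * nc)
  mono_image(out, img$resolution_px_per_mm)
}

# DFT sample frequencies in cycles/pixel (unshifted layout, like fftfreq)
.fft_freq <- function(n) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / n
}

#' Build the boll mask by thresholding a blurred channel
#'
#' The black cloth backdrop makes background separation possible with a fixed
#' threshold on a low-pass-filtered channel. The mask is 1 where the blurred
#' image is >= `threshold`; only the largest connected foreground component is
#' retained and small specks (backdrop fluff) below `min_speck_px` are
#' removed.
#'
#' @param blurred a `mono_image`, typically the Butterworth-blurred red channel.
#' @param threshold intensity threshold. The pipeline default is 5% of the
#'   blurred channel's maximum.
#' @param min_speck_px connected components smaller than this are dropped.
#' @return a `boll_mask`. An empty foreground yields an all-zero mask with a
#'   warning, not an error.
#' @export
make_boll_mask <- function(blurred, threshold, min_speck_px = 100L) {
  stopifnot(inherits(blurred, "mono_image"))
  fg <- blurred$pixels >= threshold
  if (!any(fg)) {
    warning("no foreground above threshold; returning empty mask")
    return(boll_mask(matrix(0, nrow(blurred$pixels), ncol(blurred$pixels))))
  }
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  labm <- EBImage::imageData(lab)
  sizes <- tabulate(labm[labm > 0])
  keep <- which(sizes == max(sizes))[1]  # largest component; specks implied out
  m <- (labm == keep) * 1
  if (sizes[keep] < min_speck_px) {
    warning("largest foreground component is below min_speck_px; empty mask")
    m[] <- 0
  }
  boll_mask(m)
}

#' Masked ratiometric (green/red) image
#'
#' Divides the green channel by the red channel pixel-by-pixel with a guard
#' against division by values below `eps`, then multiplies by the boll mask so
#' that background pixels are exactly zero.
#'
#' @param green,red `mono_image`s of the two channels (same size).
#' @param mask a `boll_mask` of the same size.
#' @param eps division guard; default 1, i.e. one least-significant unit of
#'   the 12-bit intensity scale.
#' @return a `ratio_image`.
#' @export
ratiometric_image <- function(green, red, mask, eps = 1) {
  stopifnot(inherits(green, "mono_image"), inherits(red, "mono_image"),
            inherits(mask, "boll_mask"))
  if (eps <= 0) stop("`eps` must be positive")
  if (!all(dim(green$pixels) == dim(red$pixels)) ||
      !all(dim(green$pixels) == dim(mask$pixels)))
    stop("green, red and mask must share dimensions")
  r <- mask$pixels * green$pixels / pmax(red$pixels, eps)
  ratio_image(r, mask, green$resolution_px_per_mm)
}

#' Default imaging configuration
#'
#' @return named list of the imaging-stage parameters with their defaults.
#' @export
imaging_config <- function() {
  list(median = list(window = 3L, center_weight = 3L),
       mask = list(channel = "red", butterworth_order = 2L,
                   cutoff_px = 10, threshold = NA_real_,  # NA: 5% of max
                   min_threshold = 50,  # counts; floor for the automatic rule
                   min_speck_px = 100L, erode_px = 6L),
       eps = 1,
       resolution_px_per_mm = 36)  # raw frame; binning halves it to 18
}

#' Run the full imaging chain on a color photograph
#'
#' Fixed stage order: center-weighted median filter, 2 x 2 binning, then two
#' parallel branches — mask creation (channel extraction, Butterworth
#' low-pass, fixed threshold, largest-component cleanup) and the green/red
#' ratio — joined by multiplying the ratio with the mask.
#'
#' @param img a `color_image`.
#' @param cfg configuration list as from [imaging_config()]; missing entries
#'   take their defaults.
#' @return list with elements `ratio` (a `ratio_image`), `mask`
#'   (a `boll_mask`), and `binned` (the filtered, binned `color_image`).
#' @export
ratio_pipeline <- function(img, cfg = imaging_config()) {
  cfg <- utils::modifyList(imaging_config(), cfg)
  med <- center_weighted_median(img, cfg$median$window, cfg$median$center_weight)
  binned <- bin2x2(med)
  ch <- extract_channel(binned, cfg$mask$channel)
  blur <- butterworth_lowpass(ch, cfg$mask$butterworth_order, cfg$mask$cutoff_px)
  thr <- cfg$mask$threshold
  # automatic rule: 5% of the blurred channel's maximum, floored at an
  # absolute count level so that a frame with no boll at all (maximum set by
  # backdrop noise) yields an empty mask rather than a full-frame one
  if (is.na(thr)) thr <- max(0.05 * max(blur$pixels), cfg$mask$min_threshold)
  mask <- make_boll_mask(blur, thr, cfg$mask$min_speck_px)
  if (cfg$mask$erode_px > 0 && any(mask$pixels == 1)) {
    # the low fixed threshold on a heavily blurred channel overhangs the true
    # boll edge by a few pixels of background; erode by the overhang so the
    # masked ratio never mixes backdrop pixels into the boll region
    er <- EBImage::erode(EBImage::Image(mask$pixels),
                         EBImage::makeBrush(2L * cfg$mask$erode_px + 1L, "disc"))
    mask <- boll_mask(EBImage::imageData(er))
  }
  green <- extract_channel(binned, "green")
  red <- extract_channel(binned, "red")
  ratio <- ratiometric_image(green, red, mask, cfg$eps)
  list(ratio = ratio, mask = mask, binned = binned)
}
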