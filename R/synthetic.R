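#' Class calibration constants for the mark-feature generator
#'
#' Median area (mm^2) and median donut intensity ratio I1/I2 per mark class,
#' with log-normal dispersions (sdlog). Medians reproduce the published
#' group medians: area 0.35 / 0.6 / 0.27 mm^2 and I1/I2 0.96 / 1.2 / 0.86
#' for stink-bug (infested), control false-positive and needle-puncture
#' marks respectively. The area dispersion is larger for false positives,
#' whose sizes vary much more than puncture marks.
#'
#' @return named list of per-class calibrations, each with `area_median`,
#'   `area_sdlog`, `ratio_median`, `ratio_sdlog`.
#' @export
class_calibration <- function() {
  list(
    infested = list(area_median = 0.35, area_sdlog = 0.25,
                    ratio_median = 0.96, ratio_sdlog = 0.25),
    control  = list(area_median = 0.60, area_sdlog = 0.40,
                    ratio_median = 1.20, ratio_sdlog = 0.25),
    needle   = list(area_median = 0.27, area_sdlog = 0.25,
                    ratio_median = 0.86, ratio_sdlog = 0.25)
  )
}

#' Sample a synthetic mark feature table
#'
#' Draws per-class (area, I1/I2) pairs from log-normal distributions whose
#' medians are the class calibration constants. Log-normals are used because
#' both features are positive and right-skewed. With `sdlog = 0` all draws
#' equal the median exactly.
#'
#' @param n_per_class named integer vector, e.g.
#'   `c(infested = 169, control = 49, needle = 81)` (the published group
#'   sizes); names must appear in `calib`.
#' @param calib calibration list as from [class_calibration()].
#' @param seed integer seed fixing all randomness.
#' @return labeled mark table (data.frame with `label`, `area_mm2`, `ratio`).
#' @export
sample_mark_table <- function(n_per_class = c(infested = 169, control = 49,
                                              needle = 81),
                              calib = class_calibration(), seed = 1L) {
  stopifnot(all(n_per_class >= 1), !is.null(names(n_per_class)))
  set.seed(seed)
  rows <- lapply(names(n_per_class), function(cl) {
    cc <- calib[[cl]]
    if (is.null(cc)) stop("no calibration for class '", cl, "'")
    n <- n_per_class[[cl]]
    data.frame(label = cl,
               area_mm2 = stats::rlnorm(n, log(cc$area_median), cc$area_sdlog),
               ratio = stats::rlnorm(n, log(cc$ratio_median), cc$ratio_sdlog))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Scene specification for the synthetic boll image generator
#'
#' Describes one synthetic photograph: image size, the elliptical boll
#' region, channel intensity levels (12-bit counts), the list of planted
#' marks, spatial resolution and the seed controlling the noise. Intensity
#' defaults emulate a boll whose intact surface fluoresces red
#' (chlorophyll) with a weak green baseline, photographed against a black
#' cloth backdrop.
#'
#' Defaults describe the raw camera frame at 36 px/mm, so that after the
#' pipeline's 2 x 2 binning the working resolution is the usual 18 px/mm.
#'
#' @param size `(rows, cols)` image size.
#' @param boll_center,boll_axes ellipse center and semi-axes in pixels.
#' @param background_level backdrop intensity in counts.
#' @param red_mean red-channel intensity on the boll.
#' @param green_baseline_frac green baseline as a fraction of `red_mean`.
#' @param noise_sd_frac Gaussian noise sd as a fraction of `red_mean`
#'   (default 1%), applied to both channels.
#' @param marks data.frame with columns `class`
#'   (`true_positive`/`false_positive`/`needle`), `row`, `col`,
#'   `outer_radius_px`, `attenuation` (central dip, 0-1; ignored for
#'   false positives), `gain` (peak green excess in counts). May be empty.
#' @param resolution_px_per_mm spatial resolution (default 18).
#' @param seed integer seed.
#' @return a `scene_spec` (validated list). Marks closer than 15 px or
#'   outside the boll ellipse are rejected with an error.
#' @export
scene_spec <- function(size = c(400L, 400L),
                       boll_center = c(200, 200), boll_axes = c(160, 136),
                       background_level = 15, red_mean = 2500,
                       green_baseline_frac = 0.5, noise_sd_frac = 0.01,
                       marks = empty_marks(), resolution_px_per_mm = 36,
                       seed = 1L) {
  if (nrow(marks) > 0) {
    if (any(marks$outer_radius_px < 2)) stop("mark radii must be >= 2 px")
    e <- ((marks$row - boll_center[1]) / boll_axes[1])^2 +
         ((marks$col - boll_center[2]) / boll_axes[2])^2
    if (any(e > 0.85^2))
      stop("marks must lie well inside the boll ellipse")
    if (nrow(marks) > 1) {
      d <- as.matrix(stats::dist(marks[, c("row", "col")]))
      if (any(d[upper.tri(d)] < 15))
        stop("marks closer than 15 px are not resolvable; adjust the spec")
    }
  }
  structure(list(size = as.integer(size), boll_center = boll_center,
                 boll_axes = boll_axes, background_level = background_level,
                 red_mean = red_mean, green_baseline_frac = green_baseline_frac,
                 noise_sd_frac = noise_sd_frac, marks = marks,
                 resolution_px_per_mm = resolution_px_per_mm,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' @rdname scene_spec
#' @export
empty_marks <- function() {
  data.frame(class = character(), row = numeric(), col = numeric(),
             outer_radius_px = numeric(), attenuation = numeric(),
             gain = numeric())
}

# smooth radial profiles: logistic edge roll-off, Gaussian central dip
.edge_profile <- function(r, R, scale = 0.5) 1 / (1 + exp((r - R) / scale))
.center_dip <- function(r, R, att) 1 - att * exp(-r^2 / (2 * (0.45 * R)^2))

#' Generate a synthetic boll photograph with ground truth
#'
#' Renders the scene: near-black backdrop, an elliptical boll with red
#' (chlorophyll-like) emission and a weak green baseline, and planted
#' fluorescent marks in the green channel — true-positive and needle marks
#' as annuli with an attenuated (dark) center where the puncture removed
#' tissue, false positives as center-bright irregular blobs (a sum of 2-4
#' offset Gaussians). Additive Gaussian noise on both channels; the noise
#' realization is fixed by the spec seed, while mark geometry is part of
#' the spec itself.
#'
#' The ground truth records, per planted mark, the nominal circular area and
#' the I1/I2 value measured on the noiseless ratio profile with the same
#' equal-area-circle definition used by the pipeline.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (a `color_image`) and `truth` (data.frame:
#'   `class`, `row`, `col`, `outer_radius_px`, `area_px`, `area_mm2`,
#'   `planted_ratio`).
#' @export
generate_boll_image <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$size[1]; W <- spec$size[2]
  rw <- matrix(seq_len(H), H, W)
  cl <- matrix(seq_len(W), H, W, byrow = TRUE)
  inboll <- ((rw - spec$boll_center[1]) / spec$boll_axes[1])^2 +
            ((cl - spec$boll_center[2]) / spec$boll_axes[2])^2 <= 1

  red0 <- matrix(spec$background_level, H, W)
  red0[inboll] <- spec$red_mean
  green0 <- matrix(spec$background_level, H, W)
  green0[inboll] <- spec$green_baseline_frac * spec$red_mean

  truth <- NULL
  if (nrow(spec$marks) > 0) {
    for (i in seq_len(nrow(spec$marks))) {
      mk <- spec$marks[i, ]
      r <- sqrt((rw - mk$row)^2 + (cl - mk$col)^2)
      if (mk$class %in% c("true_positive", "needle")) {
        prof <- .edge_profile(r, mk$outer_radius_px) *
          .center_dip(r, mk$outer_radius_px, mk$attenuation)
      } else if (mk$class == "false_positive") {
        # blob sub-structure is part of the mark geometry: seed it from the
        # mark itself so two noise seeds render identical geometry
        set.seed((round(1000 * mk$row) * 31 + round(1000 * mk$col) + 7 * i) %%
                   .Machine$integer.max)
        k <- sample(2:4, 1)
        blob <- exp(-r^2 / (2 * (0.7 * mk$outer_radius_px)^2))
        for (j in seq_len(k - 1)) {
          off <- stats::runif(2, -0.35, 0.35) * mk$outer_radius_px
          rj <- sqrt((rw - mk$row - off[1])^2 + (cl - mk$col - off[2])^2)
          blob <- blob + stats::runif(1, 0.3, 0.6) *
            exp(-rj^2 / (2 * (0.5 * mk$outer_radius_px)^2))
        }
        blob <- blob / max(blob)
        # center-bright interior on a plateau, with a definite rim at the
        # nominal radius so the mark is segmentable like a real lesion
        prof <- (0.35 + 0.65 * blob) * .edge_profile(r, mk$outer_radius_px, 0.6)
      } else stop("unknown mark class: ", mk$class)
      green0 <- green0 + mk$gain * prof * inboll
    }
    # planted I1/I2 from the noiseless ratio profile, pipeline definition
    ratio0 <- inboll * green0 / pmax(red0, 1)
    rimg0 <- ratio_image(ratio0, boll_mask(inboll * 1),
                         spec$resolution_px_per_mm)
    # the 4-px inner circle of I1 is defined at the 18 px/mm working
    # resolution; convert it to this scene's (raw) resolution
    inner_r <- 4 * spec$resolution_px_per_mm / 18
    truth <- do.call(rbind, lapply(seq_len(nrow(spec$marks)), function(i) {
      mk <- spec$marks[i, ]
      area_px <- sum((rw - mk$row)^2 + (cl - mk$col)^2 <= mk$outer_radius_px^2)
      ir <- intensity_ratio(c(mk$row, mk$col), area_px, rimg0, inner_r)
      data.frame(class = mk$class, row = mk$row, col = mk$col,
                 outer_radius_px = mk$outer_radius_px, area_px = area_px,
                 area_mm2 = area_mm2(area_px, spec$resolution_px_per_mm),
                 planted_ratio = ir$ratio)
    }))
  } else {
    truth <- data.frame(class = character(), row = numeric(), col = numeric(),
                        outer_radius_px = numeric(), area_px = integer(),
                        area_mm2 = numeric(), planted_ratio = numeric())
  }

  set.seed(spec$seed)
  sd_n <- spec$noise_sd_frac * spec$red_mean
  red <- pmin(pmax(red0 + stats::rnorm(H * W, 0, sd_n), 0), 4095)
  green <- pmin(pmax(green0 + stats::rnorm(H * W, 0, sd_n), 0), 4095)
  blue <- pmin(pmax(matrix(spec$background_level, H, W) +
                      stats::rnorm(H * W, 0, sd_n), 0), 4095)
  img <- color_image(array(c(red, green, blue), dim = c(H, W, 3)),
                     bit_depth = 12L,
                     resolution_px_per_mm = spec$resolution_px_per_mm)
  list(image = img, truth = truth)
}

#' Randomly placed scene specification
#'
#' Draws a scene with the requested number of marks per class: outer radii
#' are drawn so that nominal circular areas follow the class-calibration
#' log-normals, centers are placed uniformly inside the boll ellipse with a
#' minimum pairwise distance of 45 raw px, and central attenuations are
#' drawn around class defaults (true positives 0.6, needle 0.85).
#'
#' @param n_tp,n_fp,n_needle number of marks per class.
#' @param seed integer seed (controls placement, sizes and, through the
#'   returned spec, the noise realization).
#' @param calib calibration list as from [class_calibration()].
#' @param ... further arguments passed to [scene_spec()].
#' @return a `scene_spec`.
#' @export
random_scene_spec <- function(n_tp = 3, n_fp = 0, n_needle = 0, seed = 1L,
                              calib = class_calibration(), ...) {
  set.seed(seed)
  res <- 36  # raw camera scale; the pipeline bins to 18 px/mm
  classes <- rep(c("true_positive", "false_positive", "needle"),
                 c(n_tp, n_fp, n_needle))
  cal_of <- c(true_positive = "infested", false_positive = "control",
              needle = "needle")
  n <- length(classes)
  # rejection-sample centers >= 45 raw px apart, well inside the ellipse
  centers <- matrix(numeric(), 0, 2)
  guard <- 0
  while (nrow(centers) < n && guard < 10000) {
    guard <- guard + 1
    p <- c(200 + stats::runif(1, -0.6, 0.6) * 160,
           200 + stats::runif(1, -0.6, 0.6) * 136)
    if (nrow(centers) == 0 ||
        all((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 >= 45^2))
      centers <- rbind(centers, p)
  }
  if (nrow(centers) < n) stop("could not place ", n, " marks; reduce the count")
  marks <- do.call(rbind, lapply(seq_len(n), function(i) {
    cc <- calib[[cal_of[classes[i]]]]
    a <- stats::rlnorm(1, log(cc$area_median), cc$area_sdlog)
    data.frame(class = classes[i], row = centers[i, 1], col = centers[i, 2],
               outer_radius_px = max(3, sqrt(a / pi) * res),
               attenuation = switch(classes[i],
                 true_positive = min(0.95, max(0.3, stats::rnorm(1, 0.6, 0.1))),
                 needle = min(0.98, max(0.6, stats::rnorm(1, 0.85, 0.05))),
                 0),
               gain = stats::runif(1, 1500, 2000))
  }))
  scene_spec(marks = marks, seed = seed, ...)
}
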