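#' Convert a pixel area to mm^2
#'
#' @param area_px number of pixels.
#' @param resolution_px_per_mm spatial resolution (default 18 px/mm, under
#'   which the 28-px minimum area corresponds to 0.0864 mm^2, printed
#'   rounded as 0.09).
#' @return area in mm^2.
#' @export
area_mm2 <- function(area_px, resolution_px_per_mm = 18) {
  if (any(resolution_px_per_mm <= 0)) stop("resolution must be positive")
  area_px / resolution_px_per_mm^2
}

# solidity denominator: pixel count of the filled convex hull of the pixel
# centers (hull polygon over the centers, rasterized boundary-inclusive) —
# the convention scikit-image calls solidity. The region's pixels are always
# a subset of the filled hull, so the quotient area_px / hull_px is in
# (0, 1], and a rasterized disk scores exactly 1 at any radius (a
# polygon-area or corner-point denominator would penalize small disks by
# their O(perimeter) rim stair-steps).
.hull_px <- function(region) {
  h <- grDevices::chull(region[, 2], region[, 1])
  poly <- region[h, , drop = FALSE]
  rr <- seq(min(region[, 1]), max(region[, 1]))
  cc <- seq(min(region[, 2]), max(region[, 2]))
  grid <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
  sum(.points_in_polygon(grid, poly))
}

#' Shape features of a segmented region
#'
#' `aspect_ratio` is the major/minor axis ratio of the region's
#' second-moment (inertia-equivalent) ellipse; `convexity` is the solidity:
#' the pixel area divided by the pixel area of the region's filled convex
#' hull. Elongated regions
#' (abrasion marks) have high aspect ratio; ragged or branched regions have
#' low convexity, whereas puncture marks are nearly circular and convex.
#'
#' @param region n x 2 matrix of pixel (row, col) coordinates, n >= 3.
#' @return list with `aspect_ratio` (>= 1, `Inf` for collinear regions) and
#'   `convexity` (in (0, 1\]).
#' @export
shape_features <- function(region) {
  if (nrow(region) < 3L) stop("region must contain at least 3 pixels")
  cv <- stats::cov(region) * (nrow(region) - 1) / nrow(region)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  aspect <- if (ev[2] <= 0) Inf else sqrt(ev[1] / ev[2])
  list(aspect_ratio = aspect,
       convexity = nrow(region) / .hull_px(region))
}

#' Donut intensity ratio I1/I2
#'
#' The segmented boundary is converted to its equal-area circle centered at
#' the region centroid (radius `sqrt(area_px / pi)`). `I2` is the mean ratio
#' intensity over pixels whose centers fall inside this circle; `I1` is the
#' mean over a concentric circle of radius `inner_radius_px` (default 4 px).
#' Puncture marks have an attenuated center, so `I1/I2 < 1`; center-bright
#' false positives have `I1/I2 > 1`.
#'
#' @param centroid numeric `(row, col)` region centroid.
#' @param area_px region pixel area (defines the equal-area circle).
#' @param ratio_img a `ratio_image`.
#' @param inner_radius_px radius of the central circle (default 4).
#' @return list with `I1`, `I2`, `ratio` and logical `valid` (`FALSE` when
#'   `I2` is 0 or the equivalent radius does not exceed `inner_radius_px`).
#' @export
intensity_ratio <- function(centroid, area_px, ratio_img, inner_radius_px = 4) {
  r_eq <- sqrt(area_px / pi)
  I2 <- .circle_mean(ratio_img$pixels, centroid, r_eq)
  I1 <- .circle_mean(ratio_img$pixels, centroid, inner_radius_px)
  valid <- is.finite(I1) && is.finite(I2) && I2 > 0 && r_eq > inner_radius_px
  list(I1 = I1, I2 = I2,
       ratio = if (valid) I1 / I2 else NA_real_, valid = valid)
}

# mean of matrix values at integer pixel centers within distance <= radius
# of `center`; pixels outside the matrix are ignored
.circle_mean <- function(m, center, radius) {
  rr <- max(1L, floor(center[1] - radius)):min(nrow(m), ceiling(center[1] + radius))
  cc <- max(1L, floor(center[2] - radius)):min(ncol(m), ceiling(center[2] + radius))
  pr <- rep(rr, times = length(cc)); pc <- rep(cc, each = length(rr))
  sel <- (pr - center[1])^2 + (pc - center[2])^2 <= radius^2
  if (!any(sel)) return(NA_real_)
  mean(m[cbind(pr[sel], pc[sel])])
}

#' Mark filter configuration
#'
#' Inclusion thresholds for segmented marks: minimum area 28 px (0.09 mm^2
#' at 18 px/mm), minimum integrated intensity 0.04 mm^-2 (sum of ratio
#' values over the region divided by its area in mm^2), maximum aspect ratio
#' 2, minimum convexity 0.9, and the 4-px inner-circle radius for I1.
#'
#' @param min_area_px,min_integrated_intensity,max_aspect_ratio,min_convexity,inner_radius_px
#'   threshold overrides.
#' @return named list.
#' @export
filter_config <- function(min_area_px = 28L, min_integrated_intensity = 0.04,
                          max_aspect_ratio = 2, min_convexity = 0.9,
                          inner_radius_px = 4L) {
  stopifnot(min_area_px > 0, min_integrated_intensity > 0,
            max_aspect_ratio > 0, min_convexity > 0, inner_radius_px > 0)
  list(min_area_px = as.integer(min_area_px),
       min_integrated_intensity = min_integrated_intensity,
       max_aspect_ratio = max_aspect_ratio,
       min_convexity = min_convexity,
       inner_radius_px = as.integer(inner_radius_px))
}

#' Measure all features of segmented marks
#'
#' Builds the per-mark feature table: pixel and mm^2 area, integrated
#' intensity, shape features, and the I1/I2 donut ratio.
#'
#' @param segmarks list of `segmented_mark` objects.
#' @param ratio_img the `ratio_image` the marks were segmented from.
#' @param cfg a [filter_config()] (supplies `inner_radius_px`).
#' @param label class label for all marks (`infested`, `control`, `needle`
#'   or `unknown`).
#' @param image_id identifier recorded in the table.
#' @return data.frame with one row per mark (a mark table).
#' @export
measure_marks <- function(segmarks, ratio_img, cfg = filter_config(),
                          label = "unknown", image_id = "image") {
  res <- ratio_img$resolution_px_per_mm
  if (length(segmarks) == 0L)
    return(data.frame(image_id = character(), mark_id = integer(),
                      label = character(), peak_row = numeric(),
                      peak_col = numeric(), area_px = integer(),
                      area_mm2 = numeric(), integrated_intensity = numeric(),
                      aspect_ratio = numeric(), convexity = numeric(),
                      I1 = numeric(), I2 = numeric(), ratio = numeric(),
                      valid = logical()))
  rows <- lapply(seq_along(segmarks), function(i) {
    sm <- segmarks[[i]]
    n <- nrow(sm$region)
    if (sm$degenerate || n < 3L) {
      return(data.frame(image_id = image_id, mark_id = i, label = label,
                        peak_row = sm$centroid[1], peak_col = sm$centroid[2],
                        area_px = n, area_mm2 = area_mm2(n, res),
                        integrated_intensity = 0, aspect_ratio = Inf,
                        convexity = 0, I1 = NA_real_, I2 = NA_real_,
                        ratio = NA_real_, valid = FALSE))
    }
    sf <- shape_features(sm$region)
    ii <- sum(ratio_img$pixels[sm$region]) / area_mm2(n, res)
    ir <- intensity_ratio(sm$centroid, n, ratio_img, cfg$inner_radius_px)
    data.frame(image_id = image_id, mark_id = i, label = label,
               peak_row = sm$centroid[1], peak_col = sm$centroid[2],
               area_px = n, area_mm2 = area_mm2(n, res),
               integrated_intensity = ii, aspect_ratio = sf$aspect_ratio,
               convexity = sf$convexity, I1 = ir$I1, I2 = ir$I2,
               ratio = ir$ratio, valid = ir$valid)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Apply the mark inclusion filters
#'
#' A mark is kept iff `area_px >= min_area_px` (a 28-px mark is kept, 27 is
#' excluded), `integrated_intensity >= min_integrated_intensity`,
#' `aspect_ratio <= max_aspect_ratio` (exactly 2 is kept, greater than 2 is
#' excluded) and `convexity >= min_convexity`. Each rejected mark carries the
#' first failed rule as its reason.
#'
#' @param marks a mark table from [measure_marks()].
#' @param cfg a [filter_config()].
#' @return list with `kept` and `rejected` mark tables; both carry logical
#'   column `kept` and character `reject_reason` (`""` for kept marks).
#' @export
apply_filters <- function(marks, cfg = filter_config()) {
  if (nrow(marks) == 0L) {
    marks$kept <- logical(0); marks$reject_reason <- character(0)
    return(list(kept = marks, rejected = marks))
  }
  reason <- character(nrow(marks))
  reason[reason == "" & marks$area_px < cfg$min_area_px] <- "area"
  reason[reason == "" &
           marks$integrated_intensity < cfg$min_integrated_intensity] <- "intensity"
  reason[reason == "" & marks$aspect_ratio > cfg$max_aspect_ratio] <- "aspect_ratio"
  reason[reason == "" & marks$convexity < cfg$min_convexity] <- "convexity"
  marks$kept <- reason == ""
  marks$reject_reason <- reason
  list(kept = marks[marks$kept, , drop = FALSE],
       rejected = marks[!marks$kept, , drop = FALSE])
}
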