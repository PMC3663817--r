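test_that("pixel areas convert to mm^2 at the working resolution", {
  expect_equal(area_mm2(28, 18), 28 / 324)        # prints rounded as 0.09
  expect_equal(round(area_mm2(28, 18), 2), 0.09)
  expect_equal(area_mm2(324, 18), 1)
  expect_equal(area_mm2(0, 18), 0)
  expect_error(area_mm2(10, 0), "positive")
})

test_that("shape features match closed-form moment and hull oracles", {
  # rasterized disk: symmetric and convex
  dm <- disk_matrix(41, 41, c(21, 21), 10)
  reg <- which(dm == 1, arr.ind = TRUE)
  sf <- shape_features(reg)
  expect_lt(abs(sf$aspect_ratio - 1), 0.05)
  expect_gte(sf$convexity, 0.95)
  expect_lte(sf$convexity, 1)

  # 4 x 20 rectangle: discrete second-moment ellipse aspect
  rect <- as.matrix(expand.grid(row = 1:4, col = 1:20))
  sf2 <- shape_features(rect)
  expect_equal(sf2$aspect_ratio, sqrt((20^2 - 1) / (4^2 - 1)), tolerance = 1e-9)
  expect_equal(sf2$convexity, 1)  # hull of a rectangle is the rectangle

  # L of two 10x4 arms: union 64 px; the filled center hull is bounded by
  # the chord row + col = 14 through (4,10) and (10,4), so it holds the
  # lattice points of [1,10]^2 with row + col <= 14: 79 pixels
  Lr <- unique(rbind(as.matrix(expand.grid(row = 1:10, col = 1:4)),
                     as.matrix(expand.grid(row = 1:4, col = 1:10))))
  sfL <- shape_features(Lr)
  hull_oracle <- sum(outer(1:10, 1:10, `+`) <= 14)
  expect_equal(sfL$convexity, 64 / hull_oracle, tolerance = 1e-9)
  expect_lt(sfL$convexity, 0.9)  # well below the inclusion threshold

  # collinear region: infinite aspect ratio
  line <- cbind(1:5, rep(2, 5))
  expect_equal(shape_features(line)$aspect_ratio, Inf)
})

test_that("inclusion filters use the published boundary semantics", {
  base <- data.frame(image_id = "t", mark_id = 1, label = "unknown",
                     peak_row = 1, peak_col = 1, area_px = 100,
                     area_mm2 = 100 / 324, integrated_intensity = 300,
                     aspect_ratio = 1.2, convexity = 0.95,
                     I1 = 1, I2 = 1, ratio = 1, valid = TRUE)
  variant <- function(...) utils::modifyList(base, list(...))

  marks <- rbind(variant(mark_id = 1, area_px = 27),   # below 28: excluded
                 variant(mark_id = 2, area_px = 28),   # exactly 28: kept
                 variant(mark_id = 3, aspect_ratio = 2.0),   # kept
                 variant(mark_id = 4, aspect_ratio = 2.01),  # excluded
                 variant(mark_id = 5))
  out <- apply_filters(marks)
  expect_equal(out$kept$mark_id, c(2, 3, 5))
  expect_equal(out$rejected$mark_id, c(1, 4))
  expect_equal(out$rejected$reject_reason, c("area", "aspect_ratio"))
  expect_true(all(out$kept$reject_reason == ""))

  low <- variant(integrated_intensity = 0.01)
  expect_equal(apply_filters(low)$rejected$reject_reason, "intensity")
  conc <- variant(convexity = 0.5)
  expect_equal(apply_filters(conc)$rejected$reject_reason, "convexity")
})

test_that("relaxing any single filter threshold never shrinks the kept set", {
  set.seed(9)
  n <- 120
  marks <- data.frame(image_id = "t", mark_id = 1:n, label = "unknown",
                      peak_row = 0, peak_col = 0,
                      area_px = sample(5:200, n, TRUE),
                      area_mm2 = 0, integrated_intensity = runif(n, 0, 400),
                      aspect_ratio = runif(n, 1, 4),
                      convexity = runif(n, 0.5, 1),
                      I1 = 1, I2 = 1, ratio = 1, valid = TRUE)
  marks$area_mm2 <- marks$area_px / 324
  cfg <- filter_config()
  kept0 <- apply_filters(marks, cfg)$kept$mark_id
  relaxed <- list(
    filter_config(min_area_px = 10),
    filter_config(min_integrated_intensity = 1e-6),
    filter_config(max_aspect_ratio = 5),
    filter_config(min_convexity = 0.5))
  for (cfg2 in relaxed)
    expect_true(all(kept0 %in% apply_filters(marks, cfg2)$kept$mark_id))
})

test_that("donut intensity ratio equals brute-force pixel averaging", {
  # uniform disk: I1 = I2, ratio exactly 1
  h <- 41
  vals <- matrix(0, h, h)
  d <- sqrt((row(vals) - 21)^2 + (col(vals) - 21)^2)
  vals[d <= 10] <- 0.8
  rim <- ratio_image(vals * (d <= 10), boll_mask((d <= 10) * 1), 18)
  ir <- intensity_ratio(c(21, 21), sum(d <= 10), rim)
  expect_true(ir$valid)
  expect_equal(ir$ratio, 1)

  # donut: 0.3 inside r <= 4, 1.0 in the annulus; direct averaging oracle
  vals2 <- matrix(0, h, h)
  vals2[d <= 4] <- 0.3
  vals2[d > 4 & d <= 10] <- 1
  rim2 <- ratio_image(vals2, boll_mask((d <= 10) * 1), 18)
  area <- sum(d <= 10)
  ir2 <- intensity_ratio(c(21, 21), area, rim2)
  I1_oracle <- mean(vals2[d <= 4])
  I2_oracle <- mean(vals2[d <= sqrt(area / pi)])
  expect_equal(ir2$I1, I1_oracle, tolerance = 1e-12)
  expect_equal(ir2$I2, I2_oracle, tolerance = 1e-12)
  expect_equal(ir2$I1, 0.3)
  expect_lt(ir2$ratio, 1)

  # center-bright Gaussian blob: the false-positive signature, ratio > 1
  vals3 <- exp(-d^2 / (2 * 5^2))
  rim3 <- ratio_image(vals3 * (d <= 15), boll_mask((d <= 15) * 1), 18)
  ir3 <- intensity_ratio(c(21, 21), sum(d <= 10), rim3)
  expect_gt(ir3$ratio, 1)

  # invariance under positive rescaling of the ratio image
  rim4 <- ratio_image(2.9 * vals2, boll_mask((d <= 10) * 1), 18)
  ir4 <- intensity_ratio(c(21, 21), area, rim4)
  expect_equal(ir4$ratio, ir2$ratio, tolerance = 1e-12)

  # equivalent radius not exceeding the inner radius: invalid
  small <- intensity_ratio(c(21, 21), 40, rim2)  # r_eq = 3.57 < 4
  expect_false(small$valid)
})

test_that("planted donuts with >= 50% attenuation give ratio < 1 almost surely", {
  set.seed(21)
  n_below <- 0; n_draws <- 200
  for (k in seq_len(n_draws)) {
    h <- 51
    ctr <- c(26, 26) + runif(2, -2, 2)
    R <- runif(1, 8, 14)
    dd <- sqrt((row(matrix(0, h, h)) - ctr[1])^2 +
               (col(matrix(0, h, h)) - ctr[2])^2)
    att <- runif(1, 0.5, 0.9)
    prof <- (1 / (1 + exp((dd - R) / 0.5))) *
      (1 - att * exp(-dd^2 / (2 * (0.45 * R)^2)))
    vals <- 0.5 + prof + rnorm(h * h, 0, 0.02)
    msk <- (dd <= R + 5) * 1
    rim <- ratio_image(pmax(vals, 0) * msk, boll_mask(msk), 18)
    ir <- intensity_ratio(ctr, round(pi * R^2), rim)
    if (isTRUE(ir$valid) && ir$ratio < 1) n_below <- n_below + 1
  }
  expect_gte(n_below / n_draws, 0.95)
})
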