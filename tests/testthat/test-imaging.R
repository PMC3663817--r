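test_that("center-weighted median matches the sorted-multiset oracle", {
  # constant image is a fixed point
  const <- mono_image(matrix(7, 5, 5))
  expect_equal(center_weighted_median(const, 3, 3)$pixels, matrix(7, 5, 5))

  # lone bright center is removed: median of {0 x 8, 100 x 3} is 0
  m <- matrix(0, 3, 3); m[2, 2] <- 100
  out <- center_weighted_median(mono_image(m), 3, 3)
  expect_equal(out$pixels[2, 2], 0)

  # center_weight 1 equals a plain median; brute-force per-pixel oracle with
  # edge replication
  set.seed(11)
  r <- matrix(runif(25), 5, 5)
  out <- center_weighted_median(mono_image(r), 3, 1)
  oracle <- matrix(NA_real_, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    win <- r[pmin(pmax(i + (-1:1), 1), 5), pmin(pmax(j + (-1:1), 1), 5)]
    oracle[i, j] <- median(win)
  }
  expect_equal(out$pixels, oracle, tolerance = 1e-12)

  # weighted case against an explicit multiset oracle
  out3 <- center_weighted_median(mono_image(r), 3, 3)
  for (idx in list(c(3, 3), c(1, 1), c(5, 2))) {
    i <- idx[1]; j <- idx[2]
    win <- r[pmin(pmax(i + (-1:1), 1), 5), pmin(pmax(j + (-1:1), 1), 5)]
    expect_equal(out3$pixels[i, j], median(c(win, rep(r[i, j], 2))))
  }

  expect_error(center_weighted_median(const, 4, 1), "odd")
  expect_error(center_weighted_median(const, 1, 1), "odd|>= 3")
})

test_that("2x2 binning averages blocks and halves the resolution", {
  cimg <- color_image(array(100, dim = c(4, 4, 3)), resolution_px_per_mm = 36)
  b <- bin2x2(cimg)
  expect_equal(dim(b$pixels), c(2, 2, 3))
  expect_true(all(b$pixels == 100))
  expect_equal(b$resolution_px_per_mm, 18)

  set.seed(2)
  m <- matrix(runif(16), 4, 4)
  b2 <- bin2x2(mono_image(m))
  oracle <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    oracle[i, j] <- mean(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_equal(b2$pixels, oracle, tolerance = 1e-12)

  # the camera frame size reduces to the published working size
  big <- bin2x2(mono_image(matrix(0, 3016, 2008)))
  expect_equal(dim(big$pixels), c(1508, 1004))

  expect_warning(bin2x2(mono_image(matrix(1, 5, 4))), "odd")
})

test_that("Butterworth low-pass has unit DC gain and 1/sqrt(2) cutoff gain", {
  const <- mono_image(matrix(3.7, 32, 32))
  out <- butterworth_lowpass(const)
  expect_equal(out$pixels, const$pixels, tolerance = 1e-9)

  # pure sinusoid at exactly f_c = 1/cutoff: amplitude scaled by 1/sqrt(2)
  n <- 100; fc <- 0.1
  s <- matrix(cos(2 * pi * fc * (0:(n - 1))), n, n, byrow = TRUE)
  out <- butterworth_lowpass(mono_image(s), order = 2, cutoff_px = 10)
  amp <- sum(out$pixels[1, ] * s[1, ]) / sum(s[1, ]^2)
  expect_equal(amp, 1 / sqrt(2), tolerance = 1e-6)

  # lowpass removes energy from white noise but preserves the mean
  set.seed(3)
  wn <- matrix(rnorm(64^2), 64, 64)
  outn <- butterworth_lowpass(mono_image(wn))
  expect_lt(var(as.vector(outn$pixels)), var(as.vector(wn)))
  expect_equal(mean(outn$pixels), mean(wn), tolerance = 1e-6 * abs(mean(wn)) + 1e-9)

  expect_error(butterworth_lowpass(const, cutoff_px = 0), "positive")
})

test_that("boll mask thresholds the blurred channel and keeps the main blob", {
  m <- disk_matrix(80, 80, c(40, 40), 25, value = 1000, background = 10)
  mask <- make_boll_mask(mono_image(m), 100)
  truth <- disk_matrix(80, 80, c(40, 40), 25)
  # agreement within a 1-px boundary band
  inner <- disk_matrix(80, 80, c(40, 40), 24)
  outer <- disk_matrix(80, 80, c(40, 40), 26)
  expect_true(all(mask$pixels[inner == 1] == 1))
  expect_true(all(mask$pixels[outer == 0] == 0))

  expect_warning(mk0 <- make_boll_mask(mono_image(matrix(1, 20, 20)), 50),
                 "empty|foreground")
  expect_true(all(mk0$pixels == 0))

  mk1 <- make_boll_mask(mono_image(m), 0)
  expect_true(all(mk1$pixels == 1))

  # specks below min_speck_px are dropped, the boll is kept
  m2 <- m; m2[3:4, 3:4] <- 5000
  mask2 <- make_boll_mask(mono_image(m2), 100)
  expect_equal(mask2$pixels[3, 3], 0)
  expect_equal(mask2$pixels[40, 40], 1)
})

test_that("ratiometric image is the masked guarded channel quotient", {
  g <- mono_image(matrix(10, 6, 6)); r <- mono_image(matrix(10, 6, 6))
  full <- boll_mask(matrix(1, 6, 6))
  expect_true(all(ratiometric_image(g, r, full)$pixels == 1))

  none <- boll_mask(matrix(0, 6, 6))
  expect_true(all(ratiometric_image(g, r, none)$pixels == 0))

  g2 <- matrix(10, 6, 6); g2[, 1:3] <- 20
  out <- ratiometric_image(mono_image(g2), r, full)
  expect_true(all(out$pixels[, 1:3] == 2) && all(out$pixels[, 4:6] == 1))

  expect_error(ratiometric_image(g, mono_image(matrix(1, 5, 5)), full),
               "dimensions")

  # ratio invariance under joint rescaling of both channels
  set.seed(4)
  gr <- matrix(runif(36, 10, 50), 6, 6); rr <- matrix(runif(36, 10, 50), 6, 6)
  r1 <- ratiometric_image(mono_image(gr), mono_image(rr), full)
  r2 <- ratiometric_image(mono_image(3.7 * gr), mono_image(3.7 * rr), full)
  expect_equal(r1$pixels, r2$pixels, tolerance = 1e-12)

  # mask multiplication is idempotent
  expect_equal(r1$pixels * full$pixels, r1$pixels)
})

test_that("imaging chain is order-sensitive and mask-threshold insensitive", {
  sc <- generate_boll_image(three_tp_spec(seed = 5))
  std <- ratio_pipeline(sc$image)

  # reordering stages (binning before the median filter) changes the output
  cfg <- imaging_config()
  med_after <- center_weighted_median(bin2x2(sc$image),
                                      cfg$median$window, cfg$median$center_weight)
  binned_std <- std$binned
  expect_false(isTRUE(all.equal(med_after$pixels, binned_std$pixels)))

  # the black backdrop makes the mask threshold uncritical: boll area stable
  # over a wide threshold range
  areas <- sapply(c(0.02, 0.05, 0.1, 0.2), function(f) {
    cfg2 <- imaging_config()
    ch <- extract_channel(std$binned, "red")
    bl <- butterworth_lowpass(ch)
    sum(make_boll_mask(bl, f * max(bl$pixels))$pixels)
  })
  expect_lt(diff(range(areas)) / mean(areas), 0.2)
})
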