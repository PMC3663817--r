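test_that("local-maximum filter finds well-separated prominent peaks only", {
  # flat boll: nothing to find
  flat <- full_ratio(matrix(0.5, 120, 120))
  expect_equal(nrow(find_local_maxima(flat)), 0L)

  gauss_pair <- function(sep) {
    m <- matrix(0.5, 120, 120)
    c1 <- c(60, 60 - sep / 2); c2 <- c(60, 60 + sep / 2)
    d1 <- (row(m) - c1[1])^2 + (col(m) - c1[2])^2
    d2 <- (row(m) - c2[1])^2 + (col(m) - c2[2])^2
    m <- m + 0.8 * exp(-d1 / (2 * 2^2)) + 0.7 * exp(-d2 / (2 * 2^2))
    list(r = full_ratio(m), c1 = c1, c2 = c2)
  }

  two <- gauss_pair(25)
  pk <- find_local_maxima(two$r)
  expect_equal(nrow(pk), 2L)
  d_to <- function(p, ctr) sqrt((p["row"] - ctr[1])^2 + (p["col"] - ctr[2])^2)
  found <- cbind(pk$row, pk$col)
  expect_true(all(apply(found, 1, function(p)
    min(sqrt(sum((p - two$c1)^2)), sqrt(sum((p - two$c2)^2))) <= 1)))
  # sorted by descending value
  expect_true(all(diff(pk$value) <= 0))

  # distance rule: same spots 10 px apart collapse to the higher one
  one <- gauss_pair(10)
  pk1 <- find_local_maxima(one$r)
  expect_equal(nrow(pk1), 1L)

  # returned peaks are pairwise >= min_distance apart and prominent
  sc <- generate_boll_image(three_tp_spec(seed = 3))
  ratio <- ratio_pipeline(sc$image)$ratio
  pk3 <- find_local_maxima(ratio)
  if (nrow(pk3) > 1) {
    dd <- as.matrix(dist(cbind(pk3$row, pk3$col)))
    expect_true(all(dd[upper.tri(dd)] >= 15))
  }
  expect_true(all(pk3$value - pk3$local_mean >= 10))
})

test_that("snake initialization lays equally spaced vertices on the circle", {
  s <- init_snake(c(50, 50), 10)
  expect_equal(nrow(s$vertices), 32L)
  d <- sqrt(rowSums(sweep(s$vertices, 2, c(50, 50))^2))
  expect_equal(d, rep(10, 32), tolerance = 1e-9)
  expect_false(s$converged)

  # 4 vertices: square of side r * sqrt(2)
  s4 <- init_snake(c(0, 0), 5, n_vertices = 4)
  side <- sqrt(sum((s4$vertices[1, ] - s4$vertices[2, ])^2))
  expect_equal(side, 5 * sqrt(2), tolerance = 1e-9)

  expect_error(init_snake(c(50, 50), 1), ">= 2")
})

test_that("snake energy matches closed-form polygon geometry", {
  zero <- mono_image(matrix(0, 100, 100))
  r <- 10; n <- 32
  s <- init_snake(c(50, 50), r, n)

  # stretching: n chords of length 2 r sin(pi/n)
  stretch <- n * 2 * r * sin(pi / n)
  expect_equal(snake_energy(s, zero, alpha = 1, beta = 0, gamma = 0),
               stretch, tolerance = 1e-9)

  # bending: n second differences of magnitude 2 r (1 - cos(2 pi / n))
  bend <- n * 2 * r * (1 - cos(2 * pi / n))
  expect_equal(snake_energy(s, zero, alpha = 0, beta = 1, gamma = 0),
               bend, tolerance = 1e-9)
  expect_equal(snake_energy(s, zero, alpha = 1, beta = 0.5, gamma = 2),
               stretch + 0.5 * bend, tolerance = 1e-9)

  # with gamma = 0 internal energy scales linearly with radius: shrinking
  # the polygon uniformly strictly reduces it
  s_half <- init_snake(c(50, 50), r / 2, n)
  expect_lt(snake_energy(s_half, zero, 1, 0.5, 0),
            snake_energy(s, zero, 1, 0.5, 0))

  # snake on a high-gradient circle has lower energy than 5 px off it
  g <- gradient_magnitude(mono_image(disk_matrix(100, 100, c(50, 50), 10)))
  on_circle <- init_snake(c(50, 50), 10)
  off_circle <- init_snake(c(50, 50), 15)
  expect_lt(snake_energy(on_circle, g, 1, 0.5, 2),
            snake_energy(off_circle, g, 1, 0.5, 2))
})

test_that("greedy evolution locks onto a disk boundary and never raises energy", {
  m <- disk_matrix(100, 100, c(50, 50), 10)
  g <- gradient_magnitude(mono_image(m))
  s0 <- init_snake(c(50, 50), 18)
  s1 <- evolve_snake_greedy(s0, g)
  expect_true(s1$converged)
  d <- sqrt(rowSums(sweep(s1$vertices, 2, c(50, 50))^2))
  expect_true(all(abs(d - 10) <= 1.5))
  expect_true(abs(mean(d) - 10) <= 1)
  # energy non-increasing end to end
  expect_lte(s1$energy, snake_energy(s0, g, 1, 0.5, 2) + 1e-9)

  # a snake initialized on the gradient ridge barely moves
  s_on <- init_snake(c(50, 50), mean(d))
  s_on2 <- evolve_snake_greedy(s_on, g)
  disp <- sqrt(rowSums((s_on2$vertices - s_on$vertices)^2))
  expect_lte(mean(disp), 0.5)

  # zero gradient: monotone contraction toward the centroid
  z <- mono_image(matrix(0, 100, 100))
  p <- snake_params(); p$max_iters <- 60L
  s2 <- suppressWarnings(evolve_snake_greedy(init_snake(c(50, 50), 15), z, p))
  expect_lt(snake_radius(s2, c(50, 50)), 15 / 2)
  ctr <- colMeans(s2$vertices)
  expect_lt(sqrt(sum((ctr - c(50, 50))^2)), 1.5)
})

test_that("segmentation is rotation-covariant on synthetic disks", {
  m <- disk_matrix(100, 120, c(30, 80), 9)
  g <- gradient_magnitude(mono_image(m))
  s <- evolve_snake_greedy(init_snake(c(30, 80), 15), g)
  reg <- snake_to_region(s)

  # rotate the image by 90 degrees: (r, c) -> (c, H + 1 - r)
  m90 <- t(m)[, nrow(m):1]
  g90 <- gradient_magnitude(mono_image(m90))
  s90 <- evolve_snake_greedy(init_snake(c(80, 100 + 1 - 30), 15), g90)
  reg90 <- snake_to_region(s90)

  expect_lt(abs(nrow(reg$region) - nrow(reg90$region)) / nrow(reg$region), 0.03)
  mapped <- c(reg$centroid[2], 100 + 1 - reg$centroid[1])
  expect_lt(sqrt(sum((mapped - reg90$centroid)^2)), 1)
})

test_that("snake rasterization counts pixel centers inside the polygon", {
  sq <- structure(list(vertices = cbind(c(1, 1, 5, 5), c(1, 5, 5, 1)),
                       energy = NA_real_, converged = TRUE), class = "snake")
  reg <- snake_to_region(sq)
  expect_equal(nrow(reg$region), 25L)

  s <- init_snake(c(50, 50), 10)
  reg2 <- snake_to_region(s)
  expect_lt(abs(nrow(reg2$region) - pi * 100) / (pi * 100), 0.03)
  expect_false(reg2$degenerate)

  collapsed <- structure(list(vertices = matrix(5, 32, 2), energy = NA_real_,
                              converged = TRUE), class = "snake")
  expect_true(snake_to_region(collapsed)$degenerate)
})

test_that("planted peak count is recovered on clean well-separated scenes", {
  spec <- three_tp_spec(seed = 6)
  spec$noise_sd_frac <- 0.001
  sc <- generate_boll_image(spec)
  ratio <- ratio_pipeline(sc$image)$ratio
  pk <- find_local_maxima(ratio)
  expect_equal(nrow(pk), 3L)
  # each peak sits on its mark's bright annulus: within outer radius + 1 px
  # of a planted center (the ratio maximum of a donut lies on the ring)
  for (i in seq_len(3)) {
    d <- sqrt((pk$row - sc$truth$row[i] / 2)^2 +
              (pk$col - sc$truth$col[i] / 2)^2)
    expect_lte(min(d), sc$truth$outer_radius_px[i] / 2 + 1)
  }
})
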