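#' Rescale a ratio image to 12-bit counts for detection
#'
#' The detection thresholds (a minimum intensity difference of 10) are
#' expressed in camera-like counts, while the green/red ratio is an O(1)
#' quantity. Detection therefore operates on the ratio image rescaled so its
#' maximum maps to 4095 (the 12-bit ceiling).
#'
#' @param ratio a `ratio_image`.
#' @return a `mono_image` with values in \[0, 4095\].
#' @export
scale_ratio_12bit <- function(ratio) {
  stopifnot(inherits(ratio, "ratio_image"))
  mx <- max(ratio$pixels)
  s <- if (mx > 0) ratio$pixels * (4095 / mx) else ratio$pixels
  mono_image(s, ratio$resolution_px_per_mm)
}

.disc_kernel <- function(radius) {
  b <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  b / sum(b)
}

#' Find candidate fluorescent marks by local-maximum filtering
#'
#' A pixel is a candidate peak when it attains the maximum of its
#' neighborhood (disc of radius `min_distance_px`), lies inside the boll
#' mask, and exceeds the mean intensity inside a disc of radius
#' `neighborhood_radius_px` around it by at least `min_difference`. Surviving
#' peaks are pruned greedily so that all returned peaks are pairwise at least
#' `min_distance_px` apart, keeping the higher-valued peak of any conflicting
#' pair (ties broken in row-major order).
#'
#' @param ratio a `ratio_image`.
#' @param min_distance_px minimum pairwise peak distance (default 15 px).
#' @param min_difference minimum excess over the local mean, in 12-bit scaled
#'   counts (default 10).
#' @param neighborhood_radius_px radius of the local-mean disc (default 15).
#' @return data.frame with columns `row`, `col`, `value` (scaled counts),
#'   `local_mean`; sorted by descending `value`. Empty on flat images.
#' @export
find_local_maxima <- function(ratio, min_distance_px = 15L, min_difference = 10,
                              neighborhood_radius_px = 15L) {
  scaled <- scale_ratio_12bit(ratio)$pixels
  inmask <- ratio$mask$pixels == 1
  if (!any(inmask)) return(.empty_peaks())

  # filter kernels cannot exceed the image; shrink radii on tiny images
  max_r <- (min(dim(scaled)) - 1L) %/% 2L
  min_distance_px <- min(as.integer(min_distance_px), max_r)
  neighborhood_radius_px <- min(as.integer(neighborhood_radius_px), max_r)

  brush <- EBImage::makeBrush(2L * as.integer(min_distance_px) + 1L, "disc")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(scaled), brush))
  # local mean restricted to in-mask pixels (normalized convolution): the
  # plain disc average would mix in background zeros near the boll edge and
  # give every edge pixel a spurious prominence of the full baseline height
  k <- .disc_kernel(as.integer(neighborhood_radius_px))
  num <- EBImage::imageData(EBImage::filter2(EBImage::Image(scaled * inmask),
                                             k, boundary = "replicate"))
  den <- EBImage::imageData(EBImage::filter2(EBImage::Image(inmask * 1),
                                             k, boundary = "replicate"))
  locmean <- ifelse(den > 0, num / pmax(den, 1e-12), 0)

  cand <- which(inmask & scaled >= dil & (scaled - locmean) >= min_difference,
                arr.ind = TRUE)
  if (nrow(cand) == 0L) return(.empty_peaks())
  v <- scaled[cand]
  lm <- locmean[cand]
  # sort by descending value, row-major on ties
  ord <- order(-v, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]; v <- v[ord]; lm <- lm[ord]
  keep <- logical(length(v))
  for (i in seq_along(v)) {
    if (i == 1L) { keep[1] <- TRUE; next }
    kept <- which(keep)
    d2 <- (cand[kept, 1] - cand[i, 1])^2 + (cand[kept, 2] - cand[i, 2])^2
    keep[i] <- all(d2 >= min_distance_px^2)
  }
  data.frame(row = as.integer(cand[keep, 1]), col = as.integer(cand[keep, 2]),
             value = v[keep], local_mean = lm[keep])
}

.empty_peaks <- function() {
  data.frame(row = integer(), col = integer(),
             value = numeric(), local_mean = numeric())
}

#' Initialize a circular snake
#'
#' Places a closed contour of `n_vertices` equally spaced vertices on a
#' circle. The circle is intended to be larger than the mark it will
#' segment; its exact placement is uncritical because the contour contracts
#' until it locks onto the boundary gradient.
#'
#' @param center numeric `(row, col)` of the circle center.
#' @param radius_px circle radius in pixels (>= 2).
#' @param n_vertices number of vertices (default 32).
#' @return a `snake` object (fields `vertices`, `energy`, `converged`).
#' @export
init_snake <- function(center, radius_px, n_vertices = 32L) {
  if (radius_px < 2) stop("`radius_px` must be >= 2")
  th <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  v <- cbind(row = center[1] + radius_px * sin(th),
             col = center[2] + radius_px * cos(th))
  structure(list(vertices = v, energy = NA_real_, converged = FALSE),
            class = "snake")
}

#' @export
print.snake <- function(x, ...) {
  cat(sprintf("<snake> %d vertices, energy %.4g, converged: %s\n",
              nrow(x$vertices), x$energy, x$converged))
  invisible(x)
}

# bilinear sampling of a matrix at real-valued (row, col); out-of-range
# coordinates are clamped to the border
.bilinear <- function(m, rc) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(rc[, 1], 1), nr); c <- pmin(pmax(rc[, 2], 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Snake energy
#'
#' Total energy of a closed contour: stretching (sum of vertex-to-vertex
#' distances), bending (sum of second-difference magnitudes along the closed
#' path) and external energy (negative image gradient magnitude sampled
#' bilinearly at the vertices):
#' `E = alpha * sum |v(i+1) - v(i)| + beta * sum |v(i+1) - 2 v(i) + v(i-1)|
#'  - gamma * sum g(v(i))` with cyclic indexing.
#'
#' @param s a `snake`.
#' @param grad_mag `mono_image` of gradient magnitude (normalized to \[0,1\]).
#' @param alpha,beta,gamma nonnegative energy weights.
#' @return scalar energy.
#' @export
snake_energy <- function(s, grad_mag, alpha = 1, beta = 0.5, gamma = 2) {
  v <- s$vertices
  g <- grad_mag$pixels
  if (any(v[, 1] < 1 | v[, 1] > nrow(g) | v[, 2] < 1 | v[, 2] > ncol(g)))
    warning("snake vertex outside image; clamped to border for sampling")
  vn <- v[c(2:nrow(v), 1), , drop = FALSE]
  vp <- v[c(nrow(v), 1:(nrow(v) - 1)), , drop = FALSE]
  stretch <- sum(sqrt(rowSums((vn - v)^2)))
  bend <- sum(sqrt(rowSums((vn - 2 * v + vp)^2)))
  ext <- sum(.bilinear(g, v))
  alpha * stretch + beta * bend - gamma * ext
}

# TRUE if segment p1-p2 properly intersects segment q1-q2 (shared endpoints
# do not count); vectorized over rows of q1/q2
.seg_intersects <- function(p1, p2, q1, q2) {
  d1 <- (p2[1] - p1[1]) * (q1[, 2] - p1[2]) - (p2[2] - p1[2]) * (q1[, 1] - p1[1])
  d2 <- (p2[1] - p1[1]) * (q2[, 2] - p1[2]) - (p2[2] - p1[2]) * (q2[, 1] - p1[1])
  d3 <- (q2[, 1] - q1[, 1]) * (p1[2] - q1[, 2]) -
        (q2[, 2] - q1[, 2]) * (p1[1] - q1[, 1])
  d4 <- (q2[, 1] - q1[, 1]) * (p2[2] - q1[, 2]) -
        (q2[, 2] - q1[, 2]) * (p2[1] - q1[, 1])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

# would moving vertex i to `pos` make the polygon self-intersecting?
.move_crosses <- function(v, i, pos) {
  n <- nrow(v)
  ip <- if (i == 1L) n else i - 1L
  inx <- if (i == n) 1L else i + 1L
  # polygon edges excluding the two being replaced; proper-intersection test
  # already ignores touching at shared endpoints
  alle <- cbind(seq_len(n), c(2:n, 1L))
  nonadj <- alle[alle[, 1] != ip & alle[, 1] != i, , drop = FALSE]
  q1 <- v[nonadj[, 1], , drop = FALSE]; q2 <- v[nonadj[, 2], , drop = FALSE]
  any(.seg_intersects(v[ip, ], pos, q1, q2)) ||
    any(.seg_intersects(pos, v[inx, ], q1, q2))
}

#' Evolve a snake by greedy energy minimization
#'
#' Vertices are visited in order; each vertex is moved to the position
#' within its `search_radius_px` neighborhood (candidate grid spaced
#' `search_step_px` apart) that minimizes its own energy terms — stretch to
#' both neighbors, its curvature, and its image energy — one vertex at a
#' time, the classic greedy-snake scheme. The candidate grid is sub-pixel
#' because the internal-energy optimum of a densely sampled contour moves by
#' less than a pixel per iteration — with whole-pixel steps the contour
#' would freeze instead of contracting. Moves that would make the polygon
#' self-intersecting are rejected (the next-best position is taken). The
#' iteration stops when fewer than `min_moved_fraction` of the vertices
#' moved, or after `max_iters` iterations (then `converged = FALSE` with a
#' warning). The full three-term energy ([snake_energy()]) is monitored per
#' iteration and never increases: an iteration that would raise it is
#' reverted and ends the evolution.
#'
#' @param s a `snake` (typically from [init_snake()]).
#' @param grad_mag gradient-magnitude `mono_image`, normalized to \[0,1\]
#'   (see [gradient_magnitude()]).
#' @param params list of `alpha`, `beta`, `gamma`, `search_radius_px`,
#'   `max_iters`, `min_moved_fraction`; see [snake_params()].
#' @return the evolved `snake` with `energy` and `converged` set.
#' @export
evolve_snake_greedy <- function(s, grad_mag, params = snake_params()) {
  p <- utils::modifyList(snake_params(), params)
  g <- grad_mag$pixels
  nr <- nrow(g); nc <- ncol(g)
  v <- s$vertices
  n <- nrow(v)
  sr <- p$search_radius_px
  stp <- p$search_step_px
  g1 <- seq(-sr, sr, by = stp)
  g1 <- g1[order(abs(g1))]  # current position first among ties
  off <- as.matrix(expand.grid(dr = g1, dc = g1))
  gam <- p$gamma; alp <- p$alpha; bet <- p$beta

  esnake <- function(vv) snake_energy(structure(list(vertices = vv),
                                                class = "snake"),
                                      grad_mag, alp, bet, gam)
  E <- esnake(v)
  converged <- FALSE
  for (iter in seq_len(p$max_iters)) {
    moved <- 0L
    v_prev <- v
    for (i in seq_len(n)) {
      ip <- if (i == 1L) n else i - 1L
      inx <- if (i == n) 1L else i + 1L
      cand <- cbind(pmin(pmax(v[i, 1] + off[, 1], 1), nr),
                    pmin(pmax(v[i, 2] + off[, 2], 1), nc))
      # the vertex's own energy terms: its stretch to both neighbors, its own
      # curvature, its image energy. The neighbors' curvature terms are
      # deliberately excluded from the move criterion (classic greedy-snake
      # formulation): they pull symmetrically outward and would exactly
      # cancel the inward curvature pull, freezing the contour instead of
      # letting it contract onto the mark boundary.
      d_prev <- sqrt((cand[, 1] - v[ip, 1])^2 + (cand[, 2] - v[ip, 2])^2)
      d_next <- sqrt((cand[, 1] - v[inx, 1])^2 + (cand[, 2] - v[inx, 2])^2)
      b_at <- sqrt((v[inx, 1] - 2 * cand[, 1] + v[ip, 1])^2 +
                   (v[inx, 2] - 2 * cand[, 2] + v[ip, 2])^2)
      e_loc <- alp * (d_prev + d_next) + bet * b_at -
        gam * .bilinear(g, cand)
      cur <- which(off[, 1] == 0 & off[, 2] == 0)
      ord <- order(e_loc)
      for (k in ord) {
        if (e_loc[k] >= e_loc[cur]) break  # no improving move
        if (!.move_crosses(v, i, cand[k, ])) {
          v[i, ] <- cand[k, ]
          moved <- moved + 1L
          break
        }
      }
    }
    # monitor the full three-term energy per iteration: an iteration that
    # would raise it (possible near lock-on, where per-vertex moves trade
    # against the neighbors' curvature terms) is reverted and ends evolution
    E_new <- esnake(v)
    if (E_new > E + 1e-9) { v <- v_prev; converged <- TRUE; break }
    E <- E_new
    if (moved < p$min_moved_fraction * n) { converged <- TRUE; break }
  }
  if (!converged)
    warning("snake did not converge within max_iters = ", p$max_iters)
  out <- structure(list(vertices = v, energy = NA_real_, converged = converged),
                   class = "snake")
  out$energy <- snake_energy(out, grad_mag, alp, bet, gam)
  out
}

#' Default snake evolution parameters
#'
#' Energy weights assume a gradient image normalized to \[0,1\]: `alpha = 1`
#' (stretching), `beta = 0.5` (bending), `gamma = 2` (gradient attraction),
#' a +/-0.5 px greedy search neighborhood on a 0.1-px candidate grid, at
#' most 200 iterations, and termination when fewer than 5% of vertices move
#' in an iteration. The fine candidate grid matters: for a 32-vertex polygon
#' of radius r the internal-energy optimum lies only r(1 - cos(2 pi / 32))
#' (about 0.02 r) inside the current vertex, so coarse candidate steps
#' freeze small contours instead of letting them contract onto the mark.
#'
#' @return named list of parameters.
#' @export
snake_params <- function() {
  list(alpha = 1, beta = 0.5, gamma = 2, search_radius_px = 0.5,
       search_step_px = 0.1, max_iters = 200L, min_moved_fraction = 0.05)
}

#' Sobel gradient magnitude
#'
#' The image is lightly Gaussian-smoothed before the Sobel operator
#' (standard practice for active contours): pixel noise otherwise produces
#' a jagged gradient ridge that the snake locks onto vertex by vertex,
#' giving ragged boundaries.
#'
#' @param img a `mono_image` or `ratio_image`.
#' @param normalize scale so the maximum is 1 (default TRUE); the snake
#'   energy weights assume this normalization.
#' @param smooth_sigma Gaussian pre-smoothing in pixels (default 1; 0
#'   disables).
#' @return a `mono_image`.
#' @export
gradient_magnitude <- function(img, normalize = TRUE, smooth_sigma = 0) {
  m <- img$pixels
  if (smooth_sigma > 0)
    m <- EBImage::imageData(EBImage::gblur(EBImage::Image(m),
                                           sigma = smooth_sigma))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::imageData(EBImage::filter2(EBImage::Image(m), kx,
                                            boundary = "replicate"))
  gy <- EBImage::imageData(EBImage::filter2(EBImage::Image(m), t(kx),
                                            boundary = "replicate"))
  gm <- sqrt(gx^2 + gy^2)
  if (normalize && max(gm) > 0) gm <- gm / max(gm)
  mono_image(gm, img$resolution_px_per_mm)
}

.polygon_area <- function(v) {
  x <- v[, 2]; y <- v[, 1]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# distance from points (n x 2) to a segment
.point_seg_dist <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((pts[, 1] - (a[1] + t * ab[1]))^2 + (pts[, 2] - (a[2] + t * ab[2]))^2)
}

#' Rasterize a snake into a pixel region
#'
#' Returns the set of pixels whose centers lie inside the closed polygon
#' (even-odd rule; centers exactly on the boundary are included) together
#' with the region centroid. A polygon enclosing less than one pixel of area
#' is flagged degenerate.
#'
#' @param s a `snake`.
#' @return a `segmented_mark`: list with `region` (n x 2 matrix of pixel
#'   (row, col)), `boundary` (the snake), `centroid`, `degenerate`.
#' @export
snake_to_region <- function(s) {
  v <- s$vertices
  if (.polygon_area(v) < 1) {
    return(structure(list(region = matrix(numeric(), 0, 2), boundary = s,
                          centroid = c(mean(v[, 1]), mean(v[, 2])),
                          degenerate = TRUE), class = "segmented_mark"))
  }
  rr <- seq(floor(min(v[, 1])), ceiling(max(v[, 1])))
  cc <- seq(floor(min(v[, 2])), ceiling(max(v[, 2])))
  pts <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
  inside <- .points_in_polygon(pts, v)
  region <- pts[inside, , drop = FALSE]
  colnames(region) <- c("row", "col")
  structure(list(region = region, boundary = s,
                 centroid = c(mean(region[, 1]), mean(region[, 2])),
                 degenerate = nrow(region) == 0L),
            class = "segmented_mark")
}

# even-odd rule with boundary-inclusive semantics
.points_in_polygon <- function(pts, v, eps = 1e-9) {
  n <- nrow(v)
  px <- pts[, 2]; py <- pts[, 1]
  crossings <- integer(nrow(pts))
  onb <- logical(nrow(pts))
  for (j in seq_len(n)) {
    a <- v[j, ]; b <- v[if (j == n) 1L else j + 1L, ]
    onb <- onb | (.point_seg_dist(pts, a, b) <= eps)
    y1 <- a[1]; y2 <- b[1]; x1 <- a[2]; x2 <- b[2]
    straddles <- (y1 > py) != (y2 > py)
    if (any(straddles)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      crossings <- crossings + as.integer(straddles & px < xint)
    }
  }
  (crossings %% 2L == 1L) | onb
}
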