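# helpers to build small synthetic images for unit tests

# ratio image with full mask from a plain matrix
full_ratio <- function(m, res = 18) {
  ratio_image(m, boll_mask(matrix(1, nrow(m), ncol(m))), res)
}

# binary step-edge disk in an h x w image
disk_matrix <- function(h, w, center, radius, value = 1, background = 0) {
  m <- matrix(background, h, w)
  d2 <- (row(m) - center[1])^2 + (col(m) - center[2])^2
  m[d2 <= radius^2] <- value
  m
}

# mean recovered radius of a snake's vertices around a center
snake_radius <- function(s, center) {
  mean(sqrt((s$vertices[, 1] - center[1])^2 + (s$vertices[, 2] - center[2])^2))
}

# deterministic scene spec with three well-separated donut marks
three_tp_spec <- function(seed = 1L, attenuation = 0.7, radius_px = 12,
                          gain = 1800) {
  scene_spec(marks = data.frame(
    class = "true_positive",
    row = c(140, 220, 260), col = c(150, 260, 140),
    outer_radius_px = radius_px, attenuation = attenuation, gain = gain),
    seed = seed)
}
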