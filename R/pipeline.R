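#' Detect and segment all candidate marks in a ratio image
#'
#' Runs the local-maximum filter, then for every candidate places a circular
#' snake and evolves it to the mark boundary. The initial circle is centered
#' on a refined center (intensity-weighted centroid of above-local-mean
#' pixels near the peak — on donut-shaped marks the raw peak sits on the
#' bright annulus) with radius 1.5 times the radius at which the radial
#' intensity profile first drops below the peak's local mean, capped at
#' `max_init_radius_px`.
#'
#' @param ratio a `ratio_image`.
#' @param min_distance_px,min_difference,neighborhood_radius_px see
#'   [find_local_maxima()].
#' @param params snake evolution parameters ([snake_params()]).
#' @param max_init_radius_px cap on the initial snake radius (default 40).
#' @return list with `peaks` (candidate table) and `marks` (list of
#'   `segmented_mark`).
#' @export
detect_marks <- function(ratio, min_distance_px = 15L, min_difference = 10,
                         neighborhood_radius_px = 15L,
                         params = snake_params(), max_init_radius_px = 40) {
  peaks <- find_local_maxima(ratio, min_distance_px, min_difference,
                             neighborhood_radius_px)
  if (nrow(peaks) == 0L) return(list(peaks = peaks, marks = list()))
  scaled <- scale_ratio_12bit(ratio)$pixels
  grad <- gradient_magnitude(ratio)
  marks <- lapply(seq_len(nrow(peaks)), function(i) {
    ctr <- .refine_center(scaled, c(peaks$row[i], peaks$col[i]),
                          peaks$local_mean[i], neighborhood_radius_px)
    r0 <- .profile_radius(scaled, ctr, peaks$local_mean[i],
                          max_r = max_init_radius_px)
    s <- init_snake(ctr, max(4, min(1.5 * r0, max_init_radius_px)))
    s <- suppressWarnings(evolve_snake_greedy(s, grad, params))
    snake_to_region(s)
  })
  list(peaks = peaks, marks = marks)
}

# intensity-weighted centroid of pixels exceeding the local mean near a peak
.refine_center <- function(scaled, peak, local_mean, radius) {
  rr <- max(1L, peak[1] - radius):min(nrow(scaled), peak[1] + radius)
  cc <- max(1L, peak[2] - radius):min(ncol(scaled), peak[2] + radius)
  pr <- rep(rr, times = length(cc)); pc <- rep(cc, each = length(rr))
  near <- (pr - peak[1])^2 + (pc - peak[2])^2 <= radius^2
  w <- pmax(scaled[cbind(pr, pc)] - local_mean, 0) * near
  if (sum(w) == 0) return(as.numeric(peak))
  c(sum(pr * w), sum(pc * w)) / sum(w)
}

# first radius at which the mean intensity on the ring [r-0.5, r+0.5)
# drops below the local mean
.profile_radius <- function(scaled, center, local_mean, max_r = 40) {
  rr <- max(1L, floor(center[1] - max_r)):min(nrow(scaled), ceiling(center[1] + max_r))
  cc <- max(1L, floor(center[2] - max_r)):min(ncol(scaled), ceiling(center[2] + max_r))
  pr <- rep(rr, times = length(cc)); pc <- rep(cc, each = length(rr))
  d <- sqrt((pr - center[1])^2 + (pc - center[2])^2)
  v <- scaled[cbind(pr, pc)]
  for (r in seq_len(max_r)) {
    ring <- d >= r - 0.5 & d < r + 0.5
    if (any(ring) && mean(v[ring]) < local_mean) return(r)
  }
  max_r
}

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline in one nested list: imaging
#' (median filter, binning is fixed, mask construction), detection (peak
#' finding and snake evolution), mark filters, the rectangle criterion, and
#' the per-boll decision rule across rotation views.
#'
#' @return nested named list.
#' @export
pipeline_config <- function() {
  list(imaging = imaging_config(),
       detect = list(min_distance_px = 15L, min_difference = 10,
                     neighborhood_radius_px = 15L, max_init_radius_px = 40),
       snake = snake_params(),
       filters = filter_config(),
       criterion = list(a_max = 0.6, r_max = 1.2),
       boll_positive_min_marks = 1L,
       seed = 1L)
}

#' Validate a pipeline configuration
#'
#' Unknown keys anywhere in the nested list are rejected; known keys are
#' merged over the defaults.
#'
#' @param cfg possibly partial configuration list.
#' @return complete validated configuration.
#' @export
validate_config <- function(cfg) {
  def <- pipeline_config()
  check <- function(given, ref, path = "") {
    bad <- setdiff(names(given), names(ref))
    if (length(bad))
      stop("unknown config key(s): ", paste0(path, bad, collapse = ", "))
    for (nm in names(given))
      if (is.list(ref[[nm]]) && !is.data.frame(ref[[nm]]))
        check(given[[nm]], ref[[nm]], paste0(path, nm, "."))
  }
  check(cfg, def)
  utils::modifyList(def, cfg)
}

#' Hash of a configuration
#'
#' MD5 over the canonical YAML serialization; recorded in run reports so
#' that any threshold change is visible in the output artifacts.
#'
#' @param cfg configuration list.
#' @return character MD5 hash.
#' @export
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(cfg), f)
  unname(tools::md5sum(f))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run the full pipeline on one or more boll images
#'
#' For each image: imaging chain (median filter, binning, mask, ratio),
#' detection and snake segmentation, mark measurement and filtering, and
#' rectangle classification. Unreadable images are skipped with a warning;
#' an empty boll mask is reported as "no boll detected". A boll (image
#' group) is flagged infested when at least
#' `cfg$boll_positive_min_marks` of its marks classify positive.
#'
#' @param images list of `color_image` objects, or character paths to TIFF
#'   files; names are used as image ids.
#' @param cfg configuration list (see [pipeline_config()]); partial lists
#'   are merged over the defaults.
#' @param labels optional character vector of group labels per image
#'   (recorded in the mark table).
#' @return a `run_report`: list with `marks` (all measured marks with filter
#'   verdicts and classification), `images` (per-image status summary),
#'   `config`, `config_hash`, `version`, `timestamp`.
#' @export
run_pipeline <- function(images, cfg = list(), labels = NULL) {
  cfg <- validate_config(cfg)
  if (!is.list(images) || inherits(images, "color_image")) images <- list(images)
  ids <- names(images)
  if (is.null(ids)) ids <- paste0("image_", seq_along(images))
  if (is.null(labels)) labels <- rep("unknown", length(images))
  crit <- rectangle_criterion(cfg$criterion$a_max, cfg$criterion$r_max)

  all_marks <- list(); status <- character(length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (is.character(img)) {
      img <- tryCatch(read_boll_tiff(img,
                        resolution_px_per_mm = cfg$imaging$resolution_px_per_mm),
                      error = function(e) {
                        warning("skipping unreadable image ", ids[i], ": ",
                                conditionMessage(e))
                        NULL
                      })
      if (is.null(img)) { status[i] <- "unreadable"; next }
    }
    stages <- ratio_pipeline(img, cfg$imaging)
    if (sum(stages$mask$pixels) == 0) { status[i] <- "no boll detected"; next }
    det <- detect_marks(stages$ratio, cfg$detect$min_distance_px,
                        cfg$detect$min_difference,
                        cfg$detect$neighborhood_radius_px,
                        cfg$snake, cfg$detect$max_init_radius_px)
    mt <- measure_marks(det$marks, stages$ratio, cfg$filters,
                        label = labels[i], image_id = ids[i])
    flt <- apply_filters(mt, cfg$filters)
    tab <- rbind(flt$kept, flt$rejected)
    if (nrow(flt$rejected) > 0)
      for (j in seq_len(nrow(flt$rejected)))
        message("rejected mark ", flt$rejected$mark_id[j], " in ", ids[i],
                ": ", flt$rejected$reject_reason[j])
    tab$positive <- tab$kept & !is.na(tab$ratio) & classify_marks(tab, crit)
    all_marks[[length(all_marks) + 1L]] <- tab
    status[i] <- "ok"
  }
  marks <- if (length(all_marks)) do.call(rbind, all_marks) else
    cbind(measure_marks(list(), ratio_image(matrix(0, 2, 2),
                                            boll_mask(matrix(0, 2, 2)))),
          data.frame(kept = logical(), reject_reason = character(),
                     positive = logical()))
  n_pos <- sum(marks$positive)
  structure(list(
    marks = marks,
    images = data.frame(image_id = ids, status = status),
    boll_infested = n_pos >= cfg$boll_positive_min_marks,
    n_positive = n_pos,
    config = cfg, config_hash = config_hash(cfg),
    version = as.character(utils::packageVersion("bollmark")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d image(s), %d mark(s), %d positive; infested: %s\n",
              nrow(x$images), nrow(x$marks), x$n_positive, x$boll_infested))
  cat("config hash:", x$config_hash, "\n")
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes `marks.csv` (the full mark table) and `report.json` (image status,
#' counts, config hash, version, timestamp) into `dir`.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$marks, file.path(dir, "marks.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    images = report$images, n_positive = report$n_positive,
    boll_infested = report$boll_infested, config_hash = report$config_hash,
    version = report$version, timestamp = report$timestamp),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
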