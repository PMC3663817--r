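#' Two-threshold rectangle criterion
#'
#' A mark is called a puncture (positive) when its area and donut intensity
#' ratio both fall strictly inside the rectangle `A < a_max` and
#' `I1/I2 < r_max`. Defaults are the published operating point
#' (`a_max = 0.6` mm^2, `r_max = 1.2`).
#'
#' @param a_max area threshold in mm^2.
#' @param r_max I1/I2 threshold.
#' @return a `rectangle_criterion`.
#' @export
rectangle_criterion <- function(a_max = 0.6, r_max = 1.2) {
  stopifnot(a_max >= 0, r_max >= 0)  # 0 and Inf allowed for ROC end points
  structure(list(a_max = a_max, r_max = r_max), class = "rectangle_criterion")
}

#' Classify marks with the rectangle criterion
#'
#' @param marks mark table with columns `area_mm2` and `ratio`.
#' @param criterion a [rectangle_criterion()].
#' @return logical vector, `TRUE` for marks classified as puncture-positive
#'   (strict inequalities; a mark exactly on the boundary is negative).
#' @export
classify_marks <- function(marks, criterion = rectangle_criterion()) {
  marks$area_mm2 < criterion$a_max & marks$ratio < criterion$r_max
}

#' Contingency table for the area, intensity-ratio and combined criteria
#'
#' For the infested and control groups, counts marks passing/failing the
#' area rule (`A < a_max`), the ratio rule (`I1/I2 < r_max`), and the
#' combined rule (both). Percentages are reported in two conventions: pooled
#' (each cell as a percentage of all marks in both groups, the convention of
#' the published table, where the infested row sums to n_infested / n_total)
#' and per-group.
#'
#' @param marks labeled mark table (labels `infested` and `control`).
#' @param criterion a [rectangle_criterion()].
#' @return a `contingency_table`: list with `counts`, `pct_pooled`,
#'   `pct_group` (data.frames with rows infested/control and columns
#'   `area_pass`, `area_fail`, `ratio_pass`, `ratio_fail`, `both_pass`,
#'   `both_fail`), plus `n` per group and `n_total`.
#' @export
contingency <- function(marks, criterion = rectangle_criterion()) {
  groups <- c("infested", "control")
  if (!all(groups %in% marks$label))
    stop("mark table must contain both an infested and a control group")
  marks <- marks[marks$label %in% groups, , drop = FALSE]
  n_total <- nrow(marks)
  cell <- function(g) {
    m <- marks[marks$label == g, , drop = FALSE]
    a <- m$area_mm2 < criterion$a_max
    r <- m$ratio < criterion$r_max
    c(area_pass = sum(a), area_fail = sum(!a),
      ratio_pass = sum(r), ratio_fail = sum(!r),
      both_pass = sum(a & r), both_fail = sum(!(a & r)))
  }
  counts <- t(vapply(groups, cell, numeric(6)))
  n <- rowSums(counts[, c("area_pass", "area_fail")])
  structure(list(counts = as.data.frame(counts),
                 pct_pooled = as.data.frame(100 * counts / n_total),
                 pct_group = as.data.frame(100 * counts / n),
                 n = n, n_total = n_total, criterion = criterion),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("Contingency table (A < %g mm^2, I1/I2 < %g), n = %d\n",
              x$criterion$a_max, x$criterion$r_max, x$n_total))
  cat("Percent of pooled total:\n")
  print(round(x$pct_pooled, 1))
  invisible(x)
}

#' Published ROC sweep corner points
#'
#' The six rectangle corners `(a_max, r_max)` lying on a diagonal through
#' the origin and the operating point (0.6, 1.2), from the largest (1) to
#' the smallest rectangle (6).
#'
#' @return data.frame with columns `corner`, `a_max`, `r_max`.
#' @export
default_roc_corners <- function() {
  data.frame(corner = 1:6,
             a_max = c(1.5, 1.0, 0.8, 0.65, 0.5, 0.4),
             r_max = c(1.4, 1.2, 1.1, 1.05, 1.0, 0.98))
}

#' ROC rectangle sweep
#'
#' Sweeps the rectangle criterion over a list of corner points and computes,
#' for each, sensitivity (fraction of infested marks classified positive)
#' and specificity (fraction of control marks classified negative,
#' i.e. 1 - false positive rate). Axes follow the standard definitions.
#'
#' @param marks labeled mark table with at least one infested and one
#'   control mark.
#' @param corners data.frame of `(a_max, r_max)` corner points; defaults to
#'   the six published corners ([default_roc_corners()]).
#' @return data.frame with columns `a_max`, `r_max`, `sensitivity`,
#'   `specificity`, class `roc_curve`.
#' @export
roc_sweep <- function(marks, corners = default_roc_corners()) {
  inf <- marks[marks$label == "infested", , drop = FALSE]
  ctl <- marks[marks$label == "control", , drop = FALSE]
  if (nrow(inf) == 0L || nrow(ctl) == 0L)
    stop("need at least one mark in each of the infested and control groups")
  out <- do.call(rbind, lapply(seq_len(nrow(corners)), function(i) {
    cr <- rectangle_criterion(corners$a_max[i], corners$r_max[i])
    data.frame(a_max = cr$a_max, r_max = cr$r_max,
               sensitivity = mean(classify_marks(inf, cr)),
               specificity = mean(!classify_marks(ctl, cr)))
  }))
  class(out) <- c("roc_curve", class(out))
  out
}
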