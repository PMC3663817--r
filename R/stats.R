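#' Group samples container
#'
#' @param ... named numeric vectors (e.g. `infested =`, `control =`,
#'   `needle =`), or a single named list.
#' @return a `group_samples` object (validated named list).
#' @export
group_samples <- function(...) {
  g <- list(...)
  if (length(g) == 1L && is.list(g[[1]]) && is.null(names(g)[1])) g <- g[[1]]
  if (is.null(names(g)) || any(names(g) == ""))
    stop("all groups must be named")
  for (nm in names(g)) {
    if (length(g[[nm]]) == 0L) stop("group '", nm, "' is empty")
    if (any(!is.finite(g[[nm]]))) stop("group '", nm, "' has non-finite values")
  }
  structure(g, class = "group_samples")
}

#' Kruskal-Wallis rank test
#'
#' Nonparametric k-group location test used to compare the area and
#' intensity-ratio metrics across the infested, control and needle-puncture
#' groups (chosen over one-way ANOVA because the feature distributions are
#' skewed). Wraps [stats::kruskal.test()]: tie-corrected H statistic, p-value
#' from the chi-square approximation with k - 1 degrees of freedom.
#'
#' With `exact = TRUE` (only for total n <= 12) the p-value is computed by
#' full enumeration of all assignments of the pooled observations to groups
#' of the given sizes, `P(H* >= H)`, instead of the chi-square
#' approximation — the approximation is poor at such sample sizes.
#'
#' @param g a [group_samples()].
#' @param exact use the exact permutation null distribution (n <= 12).
#' @return list with `H`, `p`, `df`, `exact`.
#' @export
kruskal_wallis <- function(g, exact = FALSE) {
  stopifnot(inherits(g, "group_samples"))
  if (length(g) < 2L) stop("need at least 2 groups")
  x <- unlist(g, use.names = FALSE)
  if (length(x) < 3L) stop("need total n >= 3")
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, df = length(g) - 1L, exact = FALSE))
  grp <- factor(rep(names(g), lengths(g)), levels = names(g))
  kt <- stats::kruskal.test(x, grp)
  H <- unname(kt$statistic)
  p <- kt$p.value
  if (exact) {
    if (length(x) > 12L)
      stop("exact mode enumerates all group assignments; use n <= 12")
    p <- .kw_exact_p(x, lengths(g), H)
  }
  list(H = H, p = p, df = unname(kt$parameter), exact = exact)
}

# tie-corrected H statistic from pooled ranks and a group assignment
.kw_stat <- function(rk, grp_sizes, idx_list) {
  N <- length(rk)
  S <- vapply(idx_list, function(ix) sum(rk[ix]), numeric(1))
  H <- 12 / (N * (N + 1)) * sum(S^2 / grp_sizes) - 3 * (N + 1)
  tie <- table(rk)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (C > 0) H / C else 0
}

# exact permutation p-value: enumerate all partitions of 1..N into groups of
# the given sizes and count H* >= H_obs
.kw_exact_p <- function(x, sizes, H_obs) {
  N <- length(x)
  rk <- rank(x)
  count <- 0L; total <- 0L
  recurse <- function(avail, remaining_sizes, acc) {
    if (length(remaining_sizes) == 1L) {
      H <- .kw_stat(rk, sizes, c(acc, list(avail)))
      total <<- total + 1L
      if (H >= H_obs - 1e-12) count <<- count + 1L
      return(invisible())
    }
    # groups are labeled (distinguishable), so enumerate all combinations
    cmb <- utils::combn(avail, remaining_sizes[1], simplify = FALSE)
    for (ix in cmb)
      recurse(setdiff(avail, ix), remaining_sizes[-1], c(acc, list(ix)))
  }
  recurse(seq_len(N), sizes, list())
  count / total
}

#' Dunn's multiple-comparison post test
#'
#' Pairwise follow-up to the Kruskal-Wallis test on the pooled ranks:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with the
#' tie correction `T = sum(t^3 - t) / (12 (N - 1))`, and a family-wise
#' adjustment of the two-sided p-values over all pairs (Bonferroni by
#' default, the classic form of the test; Holm available).
#'
#' @param g a [group_samples()].
#' @param alpha significance level for the `significant` flags.
#' @param method p-value adjustment, `"bonferroni"` (default) or `"holm"`.
#' @return data.frame with one row per pair: `group1`, `group2`, `z`, `p`
#'   (unadjusted, two-sided), `p_adj`, `significant`, `testable` (`FALSE`
#'   when a group has fewer than 2 observations).
#' @export
dunn_posthoc <- function(g, alpha = 0.05, method = c("bonferroni", "holm")) {
  stopifnot(inherits(g, "group_samples"))
  method <- match.arg(method)
  x <- unlist(g, use.names = FALSE)
  grp <- rep(names(g), lengths(g))
  N <- length(x)
  rk <- rank(x)
  tie <- table(x)
  Tcorr <- sum(tie^3 - tie) / (12 * (N - 1))
  rbar <- tapply(rk, grp, mean)
  ns <- tapply(rk, grp, length)
  pairs <- utils::combn(names(g), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    testable <- ns[a] >= 2 && ns[b] >= 2
    sigma <- sqrt(max(N * (N + 1) / 12 - Tcorr, 0) * (1 / ns[a] + 1 / ns[b]))
    z <- if (sigma > 0) (rbar[a] - rbar[b]) / sigma
         else if (rbar[a] == rbar[b]) 0 else NA_real_  # fully tied data
    data.frame(group1 = a, group2 = b, z = unname(z),
               p = unname(2 * stats::pnorm(-abs(z))), testable = testable)
  }))
  out$p_adj <- stats::p.adjust(out$p, method = method)
  out$significant <- out$testable & !is.na(out$p_adj) & out$p_adj < alpha
  out[, c("group1", "group2", "z", "p", "p_adj", "significant", "testable")]
}

#' Wilcoxon signed rank test against a hypothetical median
#'
#' Tests whether a sample's median differs from `mu0` (used to test whether
#' each group's median I1/I2 differs from 1). Wraps [stats::wilcox.test()]:
#' values exactly equal to `mu0` are dropped, the p-value is exact for n <=
#' 25 without ties and a normal approximation (with continuity correction)
#' otherwise; two-sided by default.
#'
#' @param x numeric sample.
#' @param mu0 hypothesized median.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with `V` (signed-rank statistic), `p`, `n_used` (after
#'   dropping exact ties with `mu0`), `exact` (whether the exact null
#'   distribution was used).
#' @export
wilcoxon_signed_rank <- function(x, mu0 = 1,
                                 alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  d <- x[x != mu0]
  if (length(d) == 0L) stop("all values equal mu0; test not applicable")
  if (length(d) < 5L)
    warning("fewer than 5 non-tied observations; test has little power")
  exact <- length(d) <= 25L && !any(duplicated(abs(d - mu0)))
  wt <- suppressWarnings(stats::wilcox.test(d, mu = mu0, exact = exact,
                                            alternative = alternative))
  list(V = unname(wt$statistic), p = wt$p.value,
       n_used = length(d), exact = exact)
}

#' Compare a mark-table feature across label groups
#'
#' Convenience wrapper running the Kruskal-Wallis test, Dunn's post test and
#' per-group Wilcoxon signed rank tests against a reference value on one
#' feature column of a labeled mark table.
#'
#' @param marks labeled mark table.
#' @param feature column name, `"area_mm2"` or `"ratio"`.
#' @param mu0 reference value for the signed-rank tests (default 1, the
#'   flat-profile value of I1/I2).
#' @param alpha significance level.
#' @return list with `feature`, `medians`, `kruskal`, `dunn`, `wilcoxon`.
#' @export
compare_groups <- function(marks, feature = c("ratio", "area_mm2"), mu0 = 1,
                           alpha = 0.05) {
  feature <- match.arg(feature)
  labs <- unique(marks$label)
  g <- group_samples(stats::setNames(
    lapply(labs, function(l) marks[[feature]][marks$label == l]), labs))
  wx <- lapply(g, function(x) {
    if (all(x == mu0)) return(NULL)
    wilcoxon_signed_rank(x, mu0)
  })
  list(feature = feature,
       medians = vapply(g, stats::median, numeric(1)),
       kruskal = kruskal_wallis(g),
       dunn = if (length(g) >= 2) dunn_posthoc(g, alpha) else NULL,
       wilcoxon = wx)
}
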