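# Immunohistochemistry scoring arithmetic: the immunoreactive score
# (IRS), per-high-power-field means, hot-spot region selection, and the
# Mann-Whitney comparison between treatment groups.

#' Positivity bin of the immunoreactive score
#'
#' Percent positive cells binned as 0 (0%), 1 (1--10%), 2 (11--50%),
#' 3 (51--80%), 4 (>80%). Fractional percentages in (0, 10] map to bin 1
#' (the scheme bins integers; the bin edges are taken inclusive as
#' printed).
#'
#' @param percent_positive Numeric vector in `[0, 100]`.
#' @return Integer bin score 0--4.
#' @export
irs_bin <- function(percent_positive) {
  if (any(percent_positive < 0 | percent_positive > 100, na.rm = TRUE)) {
    stop("percent_positive must lie in [0, 100]", call. = FALSE)
  }
  as.integer(cut(percent_positive, breaks = c(-Inf, 0, 10, 50, 80, Inf),
                 labels = FALSE)) - 1L
}

#' Immunoreactive score (IRS)
#'
#' Product of the binned percent-positive score (0--4, see [irs_bin()])
#' and the staining intensity (0 = none, 1 = weak, 2 = moderate,
#' 3 = strong); range 0--12.
#'
#' @param percent_positive Percent positive cells in `[0, 100]`.
#' @param intensity Integer staining intensity in `{0, 1, 2, 3}`.
#' @return Integer IRS in `{0, ..., 12}`.
#' @examples
#' irs(85, 3) # 12, the maximal score
#' irs(30, 2) # 4
#' @export
irs <- function(percent_positive, intensity) {
  if (any(!intensity %in% 0:3)) {
    stop("intensity must be one of 0, 1, 2, 3", call. = FALSE)
  }
  irs_bin(percent_positive) * as.integer(intensity)
}

#' Mean positive-cell count per high-power field
#'
#' @param counts Numeric vector of per-HPF positive-cell counts.
#' @param n_expected Number of fields expected (default 5, the standard
#'   five representative HPF at 200x); a different length is a format
#'   error.
#' @return Arithmetic mean.
#' @export
mean_per_hpf <- function(counts, n_expected = 5) {
  if (length(counts) != n_expected) {
    stop(sprintf("expected %d per-HPF counts, got %d", n_expected,
                 length(counts)), call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  mean(counts)
}

#' Hot-spot region selection
#'
#' Returns the `k` regions with the highest positive-cell counts
#' (descending), ties broken by input order -- the computational analogue
#' of picking the visually most positive areas on a slide.
#'
#' @param region_counts Numeric vector of per-region counts.
#' @param k Number of regions to select (default 3).
#' @return Tibble with `region` (input index) and `count`, sorted by
#'   descending count. When fewer than `k` regions are supplied, all are
#'   returned with a warning.
#' @export
hotspot_select <- function(region_counts, k = 3) {
  n <- length(region_counts)
  if (n < k) {
    warning(sprintf("only %d regions available for k = %d: returning all",
                    n, k), call. = FALSE)
    k <- n
  }
  ord <- order(-region_counts, seq_len(n))
  idx <- ord[seq_len(k)]
  tibble::tibble(region = idx, count = region_counts[idx])
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided Mann-Whitney U test. For small samples (both groups at most
#' `exact_max` observations, no ties) the exact permutation distribution
#' is used; otherwise the normal approximation with continuity
#' correction.
#'
#' @param values_a,values_b Numeric vectors (both non-empty).
#' @param exact_max Largest per-group size for the exact distribution
#'   (default 8).
#' @param alpha Significance threshold reported alongside (default 0.05).
#' @return Tibble with `u_statistic` (U of the first group), `p_value`,
#'   `method` (`"exact"` or `"normal_approx"`), `significant`.
#' @export
compare_groups <- function(values_a, values_b, exact_max = 8,
                           alpha = 0.05) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  has_ties <- anyDuplicated(c(values_a, values_b)) > 0
  use_exact <- length(values_a) <= exact_max &&
    length(values_b) <= exact_max && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(
    values_a, values_b, alternative = "two.sided",
    exact = use_exact, correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1 # zero rank variance (all observations tied)
  tibble::tibble(
    u_statistic = unname(wt$statistic),
    p_value = p,
    method = if (use_exact) "exact" else "normal_approx",
    significant = wt$p.value < alpha)
}

#' Compare an IHC marker between treatment groups
#'
#' Convenience wrapper: summarises per-patient values (mean per HPF when
#' `hpf_counts` is a list column) and runs [compare_groups()] between the
#' two groups.
#'
#' @param data Tibble with columns `group` (two levels), `value`
#'   (per-patient summary value, e.g. mean positive cells per HPF or an
#'   IRS).
#' @return One-row tibble: group medians plus the [compare_groups()]
#'   columns.
#' @export
compare_ihc_groups <- function(data) {
  stopifnot(all(c("group", "value") %in% names(data)))
  groups <- sort(unique(data$group))
  if (length(groups) != 2) {
    stop("exactly two groups are required", call. = FALSE)
  }
  a <- data$value[data$group == groups[1]]
  b <- data$value[data$group == groups[2]]
  res <- compare_groups(a, b)
  tibble::tibble(
    group_a = groups[1], group_b = groups[2],
    median_a = stats::median(a), median_b = stats::median(b)) |>
    dplyr::bind_cols(res)
}

#' Plot per-group IHC values
#'
#' @param data Tibble with columns `group` and `value`.
#' @return A ggplot dot-and-box plot of the two groups.
#' @export
plot_ihc_groups <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "positive cells / HPF (mean)") +
    ggplot2::theme_minimal()
}
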