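# Intracellular cytokine staining (ICS) response calling. Activation
# markers (IFNG, TNF, IL2, CD107a, CD154) are measured as positive event
# counts within the CD4+ or CD8+ subset against a DMSO negative control.
# A marker is positive when its percentage is at least `min_fold` times
# the control percentage AND the background-subtracted event count is at
# least `min_excess`; a stimulus response requires at least two positive
# markers. Longitudinal calls classify a stimulus as absent, induced,
# pre-existing (not enhanced), or enhanced.

ICS_MARKERS <- c("IFNG", "TNF", "IL2", "CD107a", "CD154")

#' Percentage of marker-positive cells within a subset
#'
#' @param positive_events,subset_total Event counts; `subset_total` must
#'   be positive.
#' @return `100 * positive_events / subset_total`.
#' @export
marker_percentage <- function(positive_events, subset_total) {
  if (any(subset_total <= 0)) {
    stop("subset total must be positive", call. = FALSE)
  }
  100 * positive_events / subset_total
}

#' Positivity call for one marker against its negative control
#'
#' Implements the two per-marker criteria: (I) the stimulated percentage
#' is at least `min_fold` times the control percentage (inclusive `>=`),
#' and (II) the stimulated event count minus the control event count is
#' at least `min_excess` cells (inclusive `>=`). Both must hold.
#'
#' @param sample_pos,sample_total Stimulated-well positive and subset
#'   total event counts.
#' @param control_pos,control_total Matched negative-control counts.
#' @param min_fold Fold-over-background threshold (default 2).
#' @param min_excess Minimum background-subtracted cell count (default
#'   20).
#' @return Logical vector.
#' @export
call_marker <- function(sample_pos, sample_total, control_pos,
                        control_total, min_fold = 2, min_excess = 20) {
  sp <- marker_percentage(sample_pos, sample_total)
  cp <- marker_percentage(control_pos, control_total)
  (sp >= min_fold * cp) & ((sample_pos - control_pos) >= min_excess)
}

#' Overall response call from per-marker calls
#'
#' @param marker_calls Logical vector of per-marker positivity, normally
#'   all five panel markers.
#' @param min_markers Minimum number of positive markers (default 2).
#' @param allow_partial Permit fewer than five marker calls (with a
#'   warning); otherwise an incomplete panel is an error.
#' @return `TRUE` when at least `min_markers` markers are positive.
#' @export
call_response <- function(marker_calls, min_markers = 2,
                          allow_partial = FALSE) {
  if (length(marker_calls) < 5) {
    if (!allow_partial) {
      stop("expected calls for all 5 markers; set allow_partial = TRUE ",
           "to apply the rule to the available markers", call. = FALSE)
    }
    warning("response called on ", length(marker_calls),
            " of 5 markers", call. = FALSE)
  }
  sum(marker_calls, na.rm = TRUE) >= min_markers
}

#' Longitudinal response classification
#'
#' Given per-timepoint overall calls and response magnitudes (sum of
#' background-subtracted percentages over positive markers), classifies
#' the stimulus as:
#' \describe{
#'   \item{`absent`}{never positive;}
#'   \item{`induced`}{negative before treatment, positive at >= 1
#'     post-treatment timepoint;}
#'   \item{`enhanced`}{positive before treatment and the maximal
#'     post-treatment magnitude is at least `enhancement_fold` times the
#'     pre-treatment magnitude;}
#'   \item{`pre_existing_not_enhanced`}{positive before treatment without
#'     that magnitude increase.}
#' }
#'
#' @param positive Logical vector of overall calls, in timepoint order.
#' @param magnitude Numeric vector of response magnitudes, same order.
#' @param is_pre Logical vector flagging pre-treatment timepoint(s);
#'   exactly the baseline visits. An error when none is flagged.
#' @param enhancement_fold Fold increase in magnitude required to call
#'   `enhanced` (default 2; the boundary is inclusive `>=`).
#' @return One of `"absent"`, `"induced"`, `"enhanced"`,
#'   `"pre_existing_not_enhanced"`.
#' @export
classify_timecourse <- function(positive, magnitude, is_pre,
                                enhancement_fold = 2) {
  stopifnot(length(positive) == length(magnitude),
            length(positive) == length(is_pre))
  if (!any(is_pre)) {
    stop("no pre-treatment timepoint flagged", call. = FALSE)
  }
  if (!any(!is_pre)) {
    stop("at least one post-treatment timepoint is required", call. = FALSE)
  }
  pre_pos <- any(positive[is_pre])
  post_pos <- any(positive[!is_pre])
  if (!pre_pos && !post_pos) return("absent")
  if (!pre_pos && post_pos) return("induced")
  pre_mag <- max(magnitude[is_pre & positive])
  post_mag <- if (post_pos) max(magnitude[!is_pre & positive]) else -Inf
  if (post_pos && pre_mag > 0 && post_mag >= enhancement_fold * pre_mag) {
    "enhanced"
  } else {
    "pre_existing_not_enhanced"
  }
}

#' Call ICS responses from a long-format event-count table
#'
#' Joins every stimulated observation to its matched DMSO negative
#' control (same patient, timepoint, subset, marker), applies the
#' per-marker criteria, aggregates to per-(stimulus, timepoint) overall
#' calls with magnitudes, and classifies each stimulus's timecourse.
#'
#' @param data Tibble with one row per (patient, timepoint, stimulus,
#'   subset, marker): columns `patient_id`, `timepoint`, `is_pre`
#'   (logical), `stimulus` (`"DMSO"` marks the negative control),
#'   `subset` (`"CD4"`/`"CD8"`), `marker`, `pos_events`, `total_events`.
#' @param min_fold,min_excess Per-marker thresholds (see
#'   [call_marker()]).
#' @param min_markers Markers required for an overall call (default 2).
#' @param enhancement_fold Passed to [classify_timecourse()].
#' @return List with `timepoint_calls` (per stimulus x timepoint:
#'   `n_markers_positive`, `positive`, `magnitude`) and `stimulus_calls`
#'   (per stimulus x subset: `timecourse_class`, positive timepoints
#'   collapsed into a label).
#' @export
call_ics <- function(data, min_fold = 2, min_excess = 20,
                     min_markers = 2, enhancement_fold = 2) {
  req <- c("patient_id", "timepoint", "is_pre", "stimulus", "subset",
           "marker", "pos_events", "total_events")
  missing <- setdiff(req, names(data))
  if (length(missing) > 0) {
    stop("ICS table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ctrl <- data |>
    dplyr::filter(.data$stimulus == "DMSO") |>
    dplyr::select("patient_id", "timepoint", "subset", "marker",
                  ctrl_pos = "pos_events", ctrl_total = "total_events")
  stim <- data |>
    dplyr::filter(.data$stimulus != "DMSO") |>
    dplyr::inner_join(ctrl,
                      by = c("patient_id", "timepoint", "subset", "marker"))
  if (nrow(stim) < nrow(data[data$stimulus != "DMSO", ])) {
    stop("every stimulated observation needs a matched DMSO control",
         call. = FALSE)
  }
  per_marker <- stim |>
    dplyr::mutate(
      marker_positive = call_marker(
        .data$pos_events, .data$total_events, .data$ctrl_pos,
        .data$ctrl_total, min_fold = min_fold, min_excess = min_excess),
      bg_sub_pct = marker_percentage(.data$pos_events, .data$total_events) -
        marker_percentage(.data$ctrl_pos, .data$ctrl_total))

  timepoint_calls <- per_marker |>
    dplyr::group_by(.data$patient_id, .data$stimulus, .data$subset,
                    .data$timepoint, .data$is_pre) |>
    dplyr::summarise(
      n_markers = dplyr::n(),
      n_markers_positive = sum(.data$marker_positive),
      positive = call_response(.data$marker_positive,
                               min_markers = min_markers,
                               allow_partial = TRUE) |>
        suppressWarnings(),
      magnitude = sum(.data$bg_sub_pct[.data$marker_positive]),
      .groups = "drop")

  stimulus_calls <- timepoint_calls |>
    dplyr::group_by(.data$patient_id, .data$stimulus, .data$subset) |>
    dplyr::arrange(.data$is_pre == FALSE, .by_group = TRUE) |>
    dplyr::summarise(
      timecourse_class = classify_timecourse(
        .data$positive, .data$magnitude, .data$is_pre,
        enhancement_fold = enhancement_fold),
      positive_timepoints = paste(
        .data$timepoint[.data$positive], collapse = ", "),
      .groups = "drop")
  list(timepoint_calls = timepoint_calls, stimulus_calls = stimulus_calls)
}

#' Plot ICS timepoint calls
#'
#' @param timepoint_calls The `timepoint_calls` tibble from [call_ics()].
#' @return A ggplot of response magnitude over timepoints, faceted by
#'   stimulus, with positive calls highlighted.
#' @export
plot_ics_timecourse <- function(timepoint_calls) {
  ggplot2::ggplot(
    timepoint_calls,
    ggplot2::aes(x = .data$timepoint, y = .data$magnitude,
                 fill = .data$positive)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$stimulus, .data$subset)) +
    ggplot2::labs(x = "timepoint",
                  y = "background-subtracted % (positive markers)",
                  fill = "positive") +
    ggplot2::theme_minimal()
}
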