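# Expression-based curation of candidate peptides: CPM normalization,
# log2 fold change, cohort identification frequency (length variants for
# class II), and the deterministic ranking/capping of the per-patient
# candidate list.

#' Counts-per-million normalization
#'
#' @param counts Non-negative numeric vector of per-gene read counts.
#' @return `counts * 1e6 / sum(counts)`; an error when the library size
#'   is zero.
#' @export
cpm_normalize <- function(counts) {
  if (any(counts < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  lib <- sum(counts, na.rm = TRUE)
  if (lib <= 0) stop("zero library size", call. = FALSE)
  counts * 1e6 / lib
}

#' Log2 fold change with pseudocount
#'
#' @param tumor_cpm,normal_cpm Non-negative CPM values (vectors recycle).
#' @param pseudocount Added to both sides before the ratio (default 1).
#' @return `log2((tumor_cpm + pseudocount) / (normal_cpm + pseudocount))`.
#' @export
log2_fold_change <- function(tumor_cpm, normal_cpm, pseudocount = 1) {
  if (any(tumor_cpm < 0, na.rm = TRUE) || any(normal_cpm < 0, na.rm = TRUE)) {
    stop("CPM values must be non-negative", call. = FALSE)
  }
  log2((tumor_cpm + pseudocount) / (normal_cpm + pseudocount))
}

#' Tumor/normal expression profile
#'
#' CPM-normalizes the two libraries and computes the per-gene log2 fold
#' change used as a curation criterion.
#'
#' @param counts Tibble with columns `gene`, `tumor_counts`,
#'   `normal_counts`.
#' @param pseudocount Passed to [log2_fold_change()].
#' @return Input tibble with added `tumor_cpm`, `normal_cpm`, `log2_fc`.
#' @export
expression_profile <- function(counts, pseudocount = 1) {
  stopifnot(all(c("gene", "tumor_counts", "normal_counts") %in%
                  names(counts)))
  counts |>
    dplyr::mutate(
      tumor_cpm = cpm_normalize(.data$tumor_counts),
      normal_cpm = cpm_normalize(.data$normal_counts),
      log2_fc = log2_fold_change(.data$tumor_cpm, .data$normal_cpm,
                                 pseudocount = pseudocount))
}

#' Cohort identification frequency of a peptide
#'
#' Fraction of cohort samples presenting the peptide. For class I only
#' exact sequence matches count; for class II any nested length variant
#' counts ([is_nested()]).
#'
#' @param peptide Single peptide sequence.
#' @param cohort List of ligand sets (or character vectors), one per
#'   cohort sample.
#' @param hla_class `"I"` or `"II"`.
#' @return Fraction in `[0, 1]`.
#' @export
cohort_frequency <- function(peptide, cohort, hla_class = c("I", "II")) {
  hla_class <- match.arg(hla_class)
  stopifnot(length(peptide) == 1, length(cohort) >= 1)
  peptide <- toupper(peptide)
  hits <- vapply(cohort, function(sample) {
    seqs <- ligand_sequences(sample)
    if (length(seqs) == 0) return(FALSE)
    if (hla_class == "I") peptide %in% seqs else any(is_nested(peptide, seqs))
  }, logical(1))
  mean(hits)
}

#' Rank and cap the per-patient candidate list
#'
#' Mutation- and fusion-derived candidates are placed first (preferential
#' selection), each block sorted by a weighted score of log2 fold change,
#' cohort frequency, and the user-supplied tumor-association flag; ties
#' break lexicographically on the sequence. The list is truncated at
#' `cap` peptides (the per-patient testing budget, typically 6--9).
#'
#' @param records Tibble with columns `sequence`, `origin` (`"mutation"`
#'   / `"fusion"` / `"ligandome"`), `log2_fc`, `cohort_frequency`,
#'   `tumor_association` (numeric or logical).
#' @param weights Named numeric vector with entries `log2_fc`,
#'   `cohort_frequency`, `tumor_association` (default all 1).
#' @param cap Maximum number of candidates returned (default 9); values
#'   outside `1..nrow(records)` are clamped with a warning.
#' @return The ranked, capped tibble with a `rank` column.
#' @export
rank_candidates <- function(records,
                            weights = c(log2_fc = 1, cohort_frequency = 1,
                                        tumor_association = 1),
                            cap = 9) {
  req <- c("sequence", "origin", "log2_fc", "cohort_frequency",
           "tumor_association")
  missing <- setdiff(req, names(records))
  if (length(missing) > 0) {
    stop("candidate records missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0) {
    return(dplyr::mutate(records, score = numeric(0), rank = integer(0)))
  }
  if (cap < 1) {
    warning("cap below 1: clamped to 1", call. = FALSE)
    cap <- 1
  }
  if (cap > nrow(records)) cap <- nrow(records)
  out <- records |>
    dplyr::mutate(
      score = weights[["log2_fc"]] * .data$log2_fc +
        weights[["cohort_frequency"]] * .data$cohort_frequency +
        weights[["tumor_association"]] * as.numeric(.data$tumor_association),
      .preferred = .data$origin %in% c("mutation", "fusion")) |>
    dplyr::arrange(dplyr::desc(.data$.preferred), dplyr::desc(.data$score),
                   .data$sequence) |>
    dplyr::select(-".preferred") |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::slice_head(n = cap)
  out
}
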