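# Per-patient orchestration: runs both selection cascades, neoepitope
# prediction, candidate curation and ICS calling from one configuration,
# and writes a deterministic plain-text report bundle. Also the
# sample-level ligandomics summary (peptide yields, binder percentages).

#' Run the full per-patient analysis
#'
#' Composes the pipeline stages from a single configuration list. Every
#' stage is optional: a stage whose inputs are absent from `config` is
#' skipped and its slot in the result is `NULL`. All outputs are
#' deterministic given the configuration.
#'
#' @param config Named list. Recognised entries:
#' \describe{
#'   \item{`patient_id`}{identifier carried through all outputs.}
#'   \item{`alleles`, `matrices`, `predictor`}{binding model (see
#'     [classify_binder()]).}
#'   \item{`tumor_class1`, `refs_class1`}{class I cascade inputs
#'     ([run_class1_cascade()]); `class1_steps` optionally overrides the
#'     step list.}
#'   \item{`tumor_class2`, `refs_class2`}{class II cascade inputs
#'     ([run_class2_cascade()]); `class2_steps`, `nested_variants`
#'     optional.}
#'   \item{`variants`, `proteins`, `fusions`}{neoepitope inputs
#'     ([filter_somatic_variants()], [filter_fusions()],
#'     [predict_neoepitopes()]); `gene_whitelist` optional.}
#'   \item{`expression_counts`}{gene counts for [expression_profile()].}
#'   \item{`annotations`}{tibble `sequence`, `gene`,
#'     `tumor_association` used to attach curation metadata.}
#'   \item{`cohort`}{list of ligand sets for [cohort_frequency()].}
#'   \item{`ics_data`}{event-count table for [call_ics()].}
#'   \item{`thresholds`}{named list overriding defaults: `syf_binder`
#'     (50), `syf_final` (60), `ic50` (500), `min_depth` (25),
#'     `min_split` (10), `min_prob` (0.8), `ics_fold` (2), `ics_excess`
#'     (20), `enhancement_fold` (2).}
#'   \item{`cap`}{candidate list cap (default 9).}
#' }
#' @return A list of class `patient_report` with elements `patient_id`,
#'   `class1` and `class2` (`cascade_result`s), `neoepitopes`,
#'   `candidates` (ranked curation table), `ics` (from [call_ics()]),
#'   and `config_thresholds`.
#' @export
run_patient <- function(config) {
  th <- utils::modifyList(
    list(syf_binder = 50, syf_final = 60, ic50 = 500, min_depth = 25,
         min_split = 10, min_prob = 0.8, ics_fold = 2, ics_excess = 20,
         enhancement_fold = 2),
    config$thresholds %||% list())
  pid <- config$patient_id %||% NA_character_

  class1 <- NULL
  if (!is.null(config$tumor_class1)) {
    args <- list(
      tumor = config$tumor_class1, alleles = config$alleles,
      refs = config$refs_class1 %||% list(),
      matrices = config$matrices, predictor = config$predictor,
      syf_binder = th$syf_binder, syf_final = th$syf_final,
      ic50_threshold = th$ic50, patient_id = pid)
    if (!is.null(config$class1_steps)) args$steps <- config$class1_steps
    class1 <- do.call(run_class1_cascade, args)
  }

  class2 <- NULL
  if (!is.null(config$tumor_class2)) {
    args <- list(
      tumor = config$tumor_class2, refs = config$refs_class2 %||% list(),
      nested_variants = config$nested_variants %||% TRUE,
      patient_id = pid)
    if (!is.null(config$class2_steps)) args$steps <- config$class2_steps
    class2 <- do.call(run_class2_cascade, args)
  }

  neo <- NULL
  if (!is.null(config$variants) || !is.null(config$fusions)) {
    kept_var <- if (is.null(config$variants)) NULL else
      filter_somatic_variants(config$variants, min_depth = th$min_depth,
                              gene_whitelist = config$gene_whitelist)
    kept_fus <- if (is.null(config$fusions)) NULL else
      filter_fusions(config$fusions, min_split = th$min_split,
                     min_prob = th$min_prob,
                     gene_whitelist = config$gene_whitelist)
    neo <- predict_neoepitopes(kept_var, config$proteins, config$alleles,
                               config$matrices,
                               rel_threshold = th$syf_final,
                               fusions = kept_fus)
  }

  expr <- if (is.null(config$expression_counts)) NULL else
    expression_profile(config$expression_counts)

  candidates <- build_candidates(class1, class2, neo, expr,
                                 config$annotations, config$cohort,
                                 cap = config$cap %||% 9)

  ics <- if (is.null(config$ics_data)) NULL else
    call_ics(config$ics_data, min_fold = th$ics_fold,
             min_excess = th$ics_excess,
             enhancement_fold = th$enhancement_fold)

  structure(
    list(patient_id = pid, class1 = class1, class2 = class2,
         neoepitopes = neo, candidates = candidates, ics = ics,
         config_thresholds = th),
    class = "patient_report")
}

# Merge cascade finals and neoepitopes into one curation table, attach
# expression / annotation / cohort-frequency metadata, and rank.
build_candidates <- function(class1, class2, neo, expr, annotations,
                             cohort, cap = 9) {
  blocks <- list()
  if (!is.null(class1) && nrow(class1$final_candidates) > 0) {
    blocks$c1 <- tibble::tibble(
      sequence = class1$final_candidates$sequence, origin = "ligandome",
      hla_class = "I")
  }
  if (!is.null(class2) && nrow(class2$final_candidates) > 0) {
    blocks$c2 <- tibble::tibble(
      sequence = class2$final_candidates$sequence, origin = "ligandome",
      hla_class = "II")
  }
  if (!is.null(neo) && nrow(neo) > 0) {
    blocks$neo <- tibble::tibble(
      sequence = neo$sequence, origin = neo$origin, hla_class = "I+II")
  }
  if (length(blocks) == 0) return(NULL)
  recs <- dplyr::bind_rows(blocks) |>
    dplyr::distinct(.data$sequence, .keep_all = TRUE)

  if (!is.null(annotations)) {
    recs <- dplyr::left_join(recs, annotations, by = "sequence")
  }
  if (!"gene" %in% names(recs)) recs$gene <- NA_character_
  if (!"tumor_association" %in% names(recs)) recs$tumor_association <- 0

  recs$log2_fc <- 0
  if (!is.null(expr)) {
    m <- match(recs$gene, expr$gene)
    recs$log2_fc <- ifelse(is.na(m), 0, expr$log2_fc[m])
  }
  recs$cohort_frequency <- 0
  if (!is.null(cohort) && length(cohort) > 0) {
    recs$cohort_frequency <- vapply(seq_len(nrow(recs)), function(i) {
      cls <- if (identical(recs$hla_class[i], "II")) "II" else "I"
      cohort_frequency(recs$sequence[i], cohort, hla_class = cls)
    }, numeric(1))
  }
  recs$tumor_association <-
    as.numeric(dplyr::coalesce(recs$tumor_association, 0))
  rank_candidates(recs, cap = cap)
}

#' @export
print.patient_report <- function(x, ...) {
  cat(sprintf("<patient_report> %s\n", x$patient_id))
  for (cl in c("class1", "class2")) {
    if (!is.null(x[[cl]])) {
      cat(sprintf("  %s: %d -> %d peptides\n", cl,
                  x[[cl]]$trace$n_retained[1],
                  nrow(x[[cl]]$final_candidates)))
    }
  }
  if (!is.null(x$neoepitopes)) {
    cat(sprintf("  neoepitope 15-mers: %d\n", nrow(x$neoepitopes)))
  }
  if (!is.null(x$candidates)) {
    cat(sprintf("  curated candidates: %d\n", nrow(x$candidates)))
  }
  invisible(x)
}

#' Write a patient report bundle as tab-separated text
#'
#' Emits one file per populated stage (`class1_trace.tsv`,
#' `class1_candidates.tsv`, likewise for class II, `neoepitopes.tsv`,
#' `candidates.tsv`, `ics_calls.tsv`). Row order and number formatting
#' are fixed, so re-running an identical configuration yields
#' byte-identical files.
#'
#' @param report A `patient_report`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(dir, name)
    df <- dplyr::select(df, !dplyr::where(is.list))
    df <- dplyr::mutate(df, dplyr::across(
      dplyr::where(is.numeric), ~ formatC(.x, digits = 6, format = "g")))
    readr::write_tsv(df, path, progress = FALSE)
    written <<- c(written, path)
  }
  for (cl in c("class1", "class2")) {
    if (!is.null(report[[cl]])) {
      emit(report[[cl]]$trace, paste0(cl, "_trace.tsv"))
      emit(report[[cl]]$final_candidates, paste0(cl, "_candidates.tsv"))
    }
  }
  if (!is.null(report$neoepitopes)) {
    emit(report$neoepitopes, "neoepitopes.tsv")
  }
  if (!is.null(report$candidates)) emit(report$candidates, "candidates.tsv")
  if (!is.null(report$ics)) {
    emit(report$ics$timepoint_calls, "ics_timepoints.tsv")
    emit(report$ics$stimulus_calls, "ics_calls.tsv")
  }
  invisible(written)
}

#' Sample-level ligandomics summary
#'
#' Computes, per sample, the binder percentage (one decimal, round half
#' up) from peptide and binder counts -- the per-row summary of an HLA
#' ligandomics yield table.
#'
#' @param samples Tibble with columns `sample_id`, `tissue`,
#'   `n_peptides`, `n_binders`.
#' @return Input with an added `binder_pct` column.
#' @export
summarize_ligandomics <- function(samples) {
  req <- c("sample_id", "tissue", "n_peptides", "n_binders")
  missing <- setdiff(req, names(samples))
  if (length(missing) > 0) {
    stop("summary table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(
    samples,
    binder_pct = ifelse(.data$n_peptides > 0,
                        round_half_up(100 * .data$n_binders /
                                        .data$n_peptides, 1), NA_real_))
}

#' Binder percentage of a single sample
#'
#' @param n_binders,n_peptides Counts; `n_peptides` must be positive.
#' @param digits Decimal places (round half up, default 1).
#' @return Percentage of eluted peptides with confirmed binding.
#' @export
binder_percentage <- function(n_binders, n_peptides, digits = 1) {
  stopifnot(all(n_peptides > 0))
  round_half_up(100 * n_binders / n_peptides, digits)
}

#' Mean peptide yield per tissue
#'
#' @param samples Tibble with `tissue` and `n_peptides`.
#' @return Tibble of `tissue`, `mean_peptides` (nearest integer, round
#'   half up) and `n_samples`.
#' @export
mean_yield_by_tissue <- function(samples) {
  samples |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(mean_peptides = round_half_up(mean(.data$n_peptides)),
                     n_samples = dplyr::n(), .groups = "drop")
}
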