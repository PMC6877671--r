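# Tumor-exclusive ligand selection cascades. Class I: seven ordered
# filters from binder classification through benign-ligandome subtraction
# to a final stringency cut on the relative PSSM score. Class II: five
# subtraction filters ending with removal of candidates that embed a
# benign class I ligand. Every step logs its retained count, so a run
# reproduces the per-step trace of the published selection funnels.

new_cascade_result <- function(patient_id, hla_class, trace, final, meta) {
  structure(
    list(patient_id = patient_id, hla_class = hla_class, trace = trace,
         final_candidates = final, meta = meta),
    class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("<cascade_result> patient %s, HLA class %s\n",
              x$patient_id %||% "?", x$hla_class))
  print(x$trace)
  cat(sprintf("final candidates: %d\n", nrow(x$final_candidates)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cascade result into its step trace
#'
#' @param x A `cascade_result`.
#' @param ... Unused.
#' @return Tibble with columns `step`, `name`, `n_retained`.
#' @method tidy cascade_result
#' @export
tidy.cascade_result <- function(x, ...) x$trace

#' One-row summary of a cascade run
#'
#' @param x A `cascade_result`.
#' @param ... Unused.
#' @return Tibble with `patient_id`, `hla_class`, `n_input`, `n_final`,
#'   `reduction_pct` (percent of the initial pool removed, rounded half up
#'   to the nearest integer).
#' @method glance cascade_result
#' @export
glance.cascade_result <- function(x, ...) {
  n0 <- x$trace$n_retained[1]
  nf <- nrow(x$final_candidates)
  tibble::tibble(
    patient_id = x$patient_id %||% NA_character_,
    hla_class = x$hla_class,
    n_input = n0, n_final = nf,
    reduction_pct = pool_reduction_pct(n0, nf))
}

#' Percent reduction of a candidate pool
#'
#' @param n_initial,n_final Pool sizes before and after selection.
#' @param digits Decimal places (round half up); default whole percent.
#' @return `100 * (n_initial - n_final) / n_initial`, rounded.
#' @export
pool_reduction_pct <- function(n_initial, n_final, digits = 0) {
  stopifnot(n_initial > 0, n_final >= 0, n_final <= n_initial)
  round_half_up(100 * (n_initial - n_final) / n_initial, digits)
}

#' Step funnel plot for a cascade result
#'
#' @param object A `cascade_result`.
#' @param ... Unused.
#' @return A ggplot bar chart of retained counts per step.
#' @method autoplot cascade_result
#' @export
autoplot.cascade_result <- function(object, ...) {
  tr <- object$trace
  tr$name <- factor(tr$name, levels = tr$name)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$name, y = .data$n_retained)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_retained),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(
      x = NULL, y = "peptides retained",
      title = sprintf("HLA class %s selection cascade%s", object$hla_class,
                      if (is.null(object$patient_id)) "" else
                        paste0(" (", object$patient_id, ")"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

`%||%` <- function(a, b) if (is.null(a)) b else a

check_ref <- function(refs, name) {
  if (is.null(refs[[name]])) {
    stop(sprintf(
      "reference compendium is missing sub-set '%s' (disable the step or supply it)",
      name), call. = FALSE)
  }
  refs[[name]]
}

#' Run the HLA class I tumor-exclusive selection cascade
#'
#' Applies, in order (each step individually switchable via `steps`):
#' \enumerate{
#'   \item `binder` -- keep peptides called binders on >= 1 patient allele
#'     ([classify_binder()]; PSSM relative score > `syf_binder` OR
#'     predicted IC50 < `ic50_threshold` under the default union rule);
#'     peptides no allele can evaluate are dropped here.
#'   \item `motif` -- binding-motif confirmation: relative PSSM score
#'     > `syf_binder` on >= 1 patient allele specifically (the stricter
#'     matrix-only check).
#'   \item `autologous_nml` -- exact subtraction of the patient's own
#'     non-malignant liver ligandome.
#'   \item `cohort_nml` -- exact subtraction of all cohort NML ligandomes.
#'   \item `nmt_colon` -- exact subtraction of non-malignant colon tissue
#'     ligands.
#'   \item `benign_multi` -- exact subtraction of the multi-tissue benign
#'     class I compendium.
#'   \item `class2_nesting` -- remove peptides nested within any class II
#'     ligand of `refs$class2_for_nesting` (contiguous substring).
#'   \item `final_score` -- retain relative PSSM score > `syf_final` on
#'     >= 1 patient allele.
#' }
#'
#' @param tumor Class I ligand set tibble (tumor tissue).
#' @param alleles Character vector of the patient's class I alleles.
#' @param refs Named list of reference ligand sets (or character vectors):
#'   `autologous_nml`, `cohort_nml`, `nmt_colon`, `benign_multi`,
#'   `class2_for_nesting`. Only sub-sets used by enabled steps are
#'   required.
#' @param matrices List of [score_matrix()] objects.
#' @param predictor Optional IC50 predictor (see [lookup_predictor()]).
#' @param syf_binder,syf_final Relative-score thresholds, percent
#'   (defaults 50 and 60, strict `>`).
#' @param ic50_threshold IC50 cutoff in nM (default 500, strict `<`).
#' @param rule Binder combination rule, `"OR"` (default) or `"AND"`.
#' @param steps Character vector of enabled steps, in execution order.
#' @param patient_id Optional identifier carried into the result.
#' @return A `cascade_result`: `trace` (tibble of step, name, n_retained,
#'   beginning with the `input` row) and `final_candidates` (the retained
#'   ligand set with `best_relative` / `best_allele` columns, sorted by
#'   descending best relative score then sequence).
#' @export
run_class1_cascade <- function(tumor, alleles, refs = list(),
                               matrices, predictor = NULL,
                               syf_binder = 50, syf_final = 60,
                               ic50_threshold = 500, rule = "OR",
                               steps = c("binder", "motif",
                                         "autologous_nml", "cohort_nml",
                                         "nmt_colon", "benign_multi",
                                         "class2_nesting", "final_score"),
                               patient_id = NULL) {
  stopifnot(is.data.frame(tumor))
  cur <- tumor
  trace <- tibble::tibble(step = 0L, name = "input",
                          n_retained = nrow(cur))
  scores <- NULL
  get_scores <- function(seqs) {
    if (is.null(scores) || !all(seqs %in% scores$sequence)) {
      scores <<- best_relative_score(tumor$sequence, alleles, matrices)
    }
    scores[match(seqs, scores$sequence), ]
  }

  for (i in seq_along(steps)) {
    s <- steps[i]
    cur <- switch(s,
      binder = {
        if (nrow(cur) == 0) cur else {
          cls <- classify_binder(cur$sequence, alleles, matrices,
                                 predictor = predictor,
                                 syf_threshold = syf_binder,
                                 ic50_threshold = ic50_threshold,
                                 rule = rule)
          ov <- attr(cls, "overall")
          keep <- ov$sequence[!is.na(ov$binder) & ov$binder]
          cur[cur$sequence %in% keep, , drop = FALSE]
        }
      },
      motif = {
        if (nrow(cur) == 0) cur else {
          sc <- get_scores(cur$sequence)
          cur[!is.na(sc$best_relative) & sc$best_relative > syf_binder, ,
              drop = FALSE]
        }
      },
      autologous_nml = ligand_subtract(
        cur, check_ref(refs, "autologous_nml"), "exact"),
      cohort_nml = ligand_subtract(
        cur, check_ref(refs, "cohort_nml"), "exact"),
      nmt_colon = ligand_subtract(
        cur, check_ref(refs, "nmt_colon"), "exact"),
      benign_multi = ligand_subtract(
        cur, check_ref(refs, "benign_multi"), "exact"),
      class2_nesting = ligand_subtract(
        cur, check_ref(refs, "class2_for_nesting"),
        "query_within_reference"),
      final_score = {
        if (nrow(cur) == 0) cur else {
          sc <- get_scores(cur$sequence)
          cur[!is.na(sc$best_relative) & sc$best_relative > syf_final, ,
              drop = FALSE]
        }
      },
      stop("unknown cascade step: ", s, call. = FALSE))
    trace <- dplyr::bind_rows(
      trace, tibble::tibble(step = i, name = s, n_retained = nrow(cur)))
  }

  final <- cur
  if (nrow(final) > 0) {
    sc <- best_relative_score(final$sequence, alleles, matrices)
    final$best_relative <- sc$best_relative
    final$best_allele <- sc$best_allele
    final <- dplyr::arrange(final, dplyr::desc(.data$best_relative),
                            .data$sequence)
  } else {
    final$best_relative <- numeric(0)
    final$best_allele <- character(0)
  }
  new_cascade_result(patient_id, "I", trace, final,
                     meta = list(steps = steps, rule = rule,
                                 syf_binder = syf_binder,
                                 syf_final = syf_final,
                                 ic50_threshold = ic50_threshold))
}

#' Run the HLA class II tumor-exclusive selection cascade
#'
#' Applies, in order (switchable via `steps`):
#' \enumerate{
#'   \item `autologous_nml` -- subtract the patient's own NML class II
#'     ligandome (exact; when `nested_variants = TRUE`, peptides that are
#'     nested length variants of any autologous NML ligand are removed as
#'     well).
#'   \item `cohort_nml` -- exact subtraction of cohort NML class II.
#'   \item `nmt_colon` -- exact subtraction of non-malignant colon class II.
#'   \item `benign_multi` -- exact subtraction of the multi-tissue benign
#'     class II compendium.
#'   \item `class1_containment` -- remove candidates containing any benign
#'     class I ligand (`refs$benign_class1_containment`, typically the
#'     benign class I compendium plus cohort NML class I) as a contiguous
#'     substring.
#' }
#'
#' @param tumor Class II ligand set tibble.
#' @param refs Named list with `autologous_nml`, `cohort_nml`,
#'   `nmt_colon`, `benign_multi`, `benign_class1_containment`.
#' @param nested_variants Also remove nested length variants at the
#'   autologous NML step (default `TRUE`).
#' @param steps Enabled steps in execution order.
#' @param patient_id Optional identifier.
#' @return A `cascade_result` (final candidates sorted by sequence).
#' @export
run_class2_cascade <- function(tumor, refs = list(),
                               nested_variants = TRUE,
                               steps = c("autologous_nml", "cohort_nml",
                                         "nmt_colon", "benign_multi",
                                         "class1_containment"),
                               patient_id = NULL) {
  stopifnot(is.data.frame(tumor))
  cur <- tumor
  trace <- tibble::tibble(step = 0L, name = "input",
                          n_retained = nrow(cur))
  for (i in seq_along(steps)) {
    s <- steps[i]
    cur <- switch(s,
      autologous_nml = {
        ref <- check_ref(refs, "autologous_nml")
        out <- ligand_subtract(cur, ref, "exact")
        if (nested_variants && nrow(out) > 0) {
          refs_seq <- ligand_sequences(ref)
          if (length(refs_seq) > 0) {
            nested <- vapply(out$sequence, function(q)
              any(is_nested(q, refs_seq)), logical(1))
            out <- out[!nested, , drop = FALSE]
          }
        }
        out
      },
      cohort_nml = ligand_subtract(
        cur, check_ref(refs, "cohort_nml"), "exact"),
      nmt_colon = ligand_subtract(
        cur, check_ref(refs, "nmt_colon"), "exact"),
      benign_multi = ligand_subtract(
        cur, check_ref(refs, "benign_multi"), "exact"),
      class1_containment = ligand_subtract(
        cur, check_ref(refs, "benign_class1_containment"),
        "reference_within_query"),
      stop("unknown cascade step: ", s, call. = FALSE))
    trace <- dplyr::bind_rows(
      trace, tibble::tibble(step = i, name = s, n_retained = nrow(cur)))
  }
  final <- dplyr::arrange(cur, .data$sequence)
  new_cascade_result(patient_id, "II", trace, final,
                     meta = list(steps = steps,
                                 nested_variants = nested_variants))
}
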