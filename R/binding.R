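# Matrix-based HLA binding assessment. Scoring is the additive
# SYFPEITHI-style scheme: a per-allele, per-length position-specific
# scoring matrix (PSSM); a peptide's raw score is the sum of its
# position-residue weights and its relative score is the percentage of the
# maximal allelic score (the sum of per-position maxima). An external
# IC50 affinity predictor is abstracted behind a simple function contract.

#' Construct an allele score matrix
#'
#' @param allele Allele name, e.g. `"A*02"`. Two-digit group names are the
#'   expected convention; names are matched verbatim elsewhere.
#' @param weights Numeric matrix of scores with one row per peptide
#'   position and the 20 residues as column names (missing residues are
#'   treated as columns of zeros). Row count defines the peptide length
#'   the matrix scores.
#' @return An object of class `score_matrix`: list with `allele`,
#'   `length`, `weights` (full 20-column matrix) and `max_score` (sum over
#'   positions of the per-position maximum weight).
#' @export
score_matrix <- function(allele, weights) {
  stopifnot(is.matrix(weights), nrow(weights) >= 1)
  full <- matrix(0, nrow = nrow(weights), ncol = 20,
                 dimnames = list(NULL, aa_alphabet()))
  if (is.null(colnames(weights))) {
    stop("weights must have residue column names", call. = FALSE)
  }
  keep <- intersect(colnames(weights), aa_alphabet())
  full[, keep] <- weights[, keep, drop = FALSE]
  max_score <- sum(apply(full, 1, max))
  if (max_score <= 0) stop("max_score must be positive", call. = FALSE)
  structure(
    list(allele = allele, length = nrow(full), weights = full,
         max_score = max_score),
    class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> allele %s, length %d, max score %g\n",
              x$allele, x$length, x$max_score))
  invisible(x)
}

#' Read a delimited allele score matrix
#'
#' One file per allele/length: a header row of residue letters and one row
#' per peptide position of integer weights.
#'
#' @param path Delimited text file (tab or comma auto-detected).
#' @param allele Allele name to attach.
#' @return A [score_matrix()].
#' @export
read_score_matrix <- function(path, allele) {
  delim <- detect_delim(path)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  score_matrix(allele, m)
}

#' Raw PSSM score of peptides
#'
#' Sum over positions of the matrix weight of the residue observed at that
#' position; residues with no defined weight contribute 0.
#'
#' @param peptides Character vector; every peptide must have length equal
#'   to `matrix$length` (a scoring error otherwise).
#' @param matrix A [score_matrix()].
#' @return Numeric vector of raw scores.
#' @export
score_peptide <- function(peptides, matrix) {
  stopifnot(inherits(matrix, "score_matrix"))
  peptides <- toupper(peptides)
  if (length(peptides) == 0) return(numeric(0))
  if (any(nchar(peptides) != matrix$length)) {
    stop(sprintf("peptide length must equal matrix length (%d)",
                 matrix$length), call. = FALSE)
  }
  vapply(peptides, function(p) {
    res <- strsplit(p, "", fixed = TRUE)[[1]]
    sum(matrix$weights[cbind(seq_along(res), match(res, aa_alphabet()))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Relative PSSM score (percent of maximal allelic score)
#'
#' @inheritParams score_peptide
#' @param digits Decimal places for the reported value (round half up);
#'   use `digits = NULL` for the unrounded value. Threshold comparisons
#'   elsewhere always use unrounded values.
#' @return Numeric vector on a 0--100 scale.
#' @export
relative_score <- function(peptides, matrix, digits = 1) {
  rel <- 100 * score_peptide(peptides, matrix) / matrix$max_score
  if (is.null(digits)) rel else round_half_up(rel, digits)
}

#' Build an IC50 predictor from a lookup table
#'
#' The external affinity predictor is represented as a function contract
#' `(peptide, allele) -> IC50 in nM`, returning `NA` for unsupported
#' pairs. This constructor wraps a lookup table (the bundled test
#' implementation); any deterministic function with the same signature
#' can be supplied instead.
#'
#' @param table Data frame with columns `peptide`, `allele`, `ic50_nm`.
#' @return A vectorized predictor function.
#' @export
lookup_predictor <- function(table) {
  stopifnot(all(c("peptide", "allele", "ic50_nm") %in% names(table)))
  key <- paste(toupper(table$peptide), table$allele, sep = "|")
  vals <- table$ic50_nm
  function(peptide, allele) {
    vals[match(paste(toupper(peptide), allele, sep = "|"), key)]
  }
}

# Best matrix for an allele at a given peptide length, or NULL.
matrix_for <- function(matrices, allele, length) {
  for (m in matrices) {
    if (identical(m$allele, allele) && m$length == length) return(m)
  }
  NULL
}

#' Classify peptides as binders against a patient's allele set
#'
#' For every peptide x allele pair with a matching-length matrix, the
#' PSSM relative score is compared against `syf_threshold` (strict `>`);
#' where an IC50 predictor supports the pair, the predicted affinity is
#' compared against `ic50_threshold` (strict `<`). Within an allele the
#' two predictor verdicts are combined with `rule` (`"OR"`, the default
#' union rule, or `"AND"`); a peptide is an overall binder when at least
#' one allele calls it. Peptides no allele can evaluate are `NA`
#' ("unevaluable"), distinct from non-binders.
#'
#' @param peptides Character vector.
#' @param alleles Character vector of the patient's class I alleles.
#' @param matrices List of [score_matrix()] objects (any alleles/lengths).
#' @param predictor Optional IC50 predictor function (see
#'   [lookup_predictor()]); `NULL` disables the affinity route.
#' @param syf_threshold Relative-score cutoff, percent (default 50).
#' @param ic50_threshold Affinity cutoff in nM (default 500).
#' @param rule `"OR"` or `"AND"`.
#' @return Tibble with one row per evaluable peptide x allele pair
#'   (`sequence`, `allele`, `raw_score`, `relative_score`,
#'   `predicted_ic50`, `binder_matrix`, `binder_ic50`, `binder`) plus an
#'   `overall` attribute: a tibble of per-peptide `binder` (logical, `NA`
#'   if unevaluable) and `best_relative` / `best_allele`.
#' @export
classify_binder <- function(peptides, alleles, matrices, predictor = NULL,
                            syf_threshold = 50, ic50_threshold = 500,
                            rule = c("OR", "AND")) {
  rule <- match.arg(rule)
  peptides <- toupper(peptides)
  per <- purrr::map_dfr(alleles, function(al) {
    purrr::map_dfr(unique(nchar(peptides)), function(len) {
      m <- matrix_for(matrices, al, len)
      idx <- nchar(peptides) == len
      p <- peptides[idx]
      if (length(p) == 0) return(NULL)
      raw <- if (is.null(m)) rep(NA_real_, length(p)) else score_peptide(p, m)
      rel <- if (is.null(m)) rep(NA_real_, length(p)) else
        100 * raw / m$max_score
      ic50 <- if (is.null(predictor)) rep(NA_real_, length(p)) else
        as.numeric(predictor(p, al))
      tibble::tibble(sequence = p, allele = al, raw_score = raw,
                     relative_score = rel, predicted_ic50 = ic50)
    })
  })
  if (nrow(per) == 0) {
    per <- tibble::tibble(sequence = character(), allele = character(),
                          raw_score = numeric(), relative_score = numeric(),
                          predicted_ic50 = numeric())
  }
  per <- per |>
    dplyr::mutate(
      binder_matrix = .data$relative_score > syf_threshold,
      binder_ic50 = .data$predicted_ic50 < ic50_threshold,
      binder = if (rule == "OR") {
        dplyr::coalesce(.data$binder_matrix, FALSE) |
          dplyr::coalesce(.data$binder_ic50, FALSE)
      } else {
        # AND: a missing route cannot confirm; require both where defined,
        # a single defined route must still pass its own threshold.
        dplyr::case_when(
          is.na(.data$binder_matrix) & is.na(.data$binder_ic50) ~ NA,
          is.na(.data$binder_ic50) ~ .data$binder_matrix,
          is.na(.data$binder_matrix) ~ .data$binder_ic50,
          TRUE ~ .data$binder_matrix & .data$binder_ic50)
      }) |>
    dplyr::filter(!(is.na(.data$raw_score) & is.na(.data$predicted_ic50)))

  overall <- tibble::tibble(sequence = peptides) |>
    dplyr::distinct() |>
    dplyr::left_join(
      per |>
        dplyr::group_by(.data$sequence) |>
        dplyr::summarise(
          binder = any(.data$binder, na.rm = TRUE),
          best_relative = ifelse(
            all(is.na(.data$relative_score)), NA_real_,
            max(.data$relative_score, na.rm = TRUE)),
          best_allele = if (all(is.na(.data$relative_score)))
            NA_character_ else
              .data$allele[which.max(.data$relative_score)],
          .groups = "drop"),
      by = "sequence")
  attr(per, "overall") <- overall
  per
}

# Per-peptide best relative score across a patient's alleles; NA when no
# allele has a matching-length matrix.
best_relative_score <- function(peptides, alleles, matrices) {
  peptides <- toupper(peptides)
  best <- rep(NA_real_, length(peptides))
  best_allele <- rep(NA_character_, length(peptides))
  for (al in alleles) {
    for (len in unique(nchar(peptides))) {
      m <- matrix_for(matrices, al, len)
      if (is.null(m)) next
      idx <- which(nchar(peptides) == len)
      rel <- 100 * score_peptide(peptides[idx], m) / m$max_score
      upd <- is.na(best[idx]) | rel > best[idx]
      best[idx[upd]] <- rel[upd]
      best_allele[idx[upd]] <- al
    }
  }
  tibble::tibble(sequence = peptides, best_relative = best,
                 best_allele = best_allele)
}
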