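# Neoepitope prediction from somatic variant and fusion calls: depth and
# split-read filtering, protein-level application of the change, scanning
# of mutation-spanning windows against the patient's binding matrices, and
# extension of predicted binders to 15-mer long peptides with their
# wildtype counterparts.

#' Filter somatic variant calls for neoepitope prediction
#'
#' A variant is retained when it is non-synonymous, covered by more than
#' `min_depth` reads in the tumor (strict `>`), carries zero
#' alt-supporting reads in the matched normal, maps to a single genetic
#' locus, and (when a whitelist is supplied) affects a whitelisted gene.
#'
#' @param variants Tibble with columns `gene`, `consequence`
#'   (`"non_synonymous"` kept), `tumor_depth`, `normal_alt_reads`,
#'   `multi_locus` (logical).
#' @param min_depth Tumor read-depth cutoff (default 25, strict `>`).
#' @param gene_whitelist Optional character vector of genes with
#'   established relevance (driver curation); `NULL` keeps all genes.
#' @return The retained rows.
#' @export
filter_somatic_variants <- function(variants, min_depth = 25,
                                    gene_whitelist = NULL) {
  req <- c("gene", "consequence", "tumor_depth", "normal_alt_reads",
           "multi_locus")
  missing <- setdiff(req, names(variants))
  if (length(missing) > 0) {
    stop("variant table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::filter(
    variants,
    .data$consequence == "non_synonymous",
    .data$tumor_depth > min_depth,
    .data$normal_alt_reads == 0,
    !.data$multi_locus)
  if (!is.null(gene_whitelist) && length(gene_whitelist) > 0) {
    out <- dplyr::filter(out, .data$gene %in% gene_whitelist)
  }
  out
}

#' Filter gene-fusion calls
#'
#' A fusion is retained when more than `min_split` junction-spanning
#' split reads support it (strict `>`), its caller probability exceeds
#' `min_prob` (strict `>`, on a 0--1 scale), and (when a whitelist is
#' supplied) at least one partner gene is whitelisted.
#'
#' @param fusions Tibble with columns `gene_5p`, `gene_3p`,
#'   `split_reads`, `probability`.
#' @param min_split Split-read cutoff (default 10).
#' @param min_prob Probability cutoff on a 0--1 scale (default 0.8).
#' @param gene_whitelist Optional character vector; at least one partner
#'   must match.
#' @return The retained rows.
#' @export
filter_fusions <- function(fusions, min_split = 10, min_prob = 0.8,
                           gene_whitelist = NULL) {
  req <- c("gene_5p", "gene_3p", "split_reads", "probability")
  missing <- setdiff(req, names(fusions))
  if (length(missing) > 0) {
    stop("fusion table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(fusions$probability < 0 | fusions$probability > 1, na.rm = TRUE)) {
    stop("fusion probability must lie in [0, 1]", call. = FALSE)
  }
  out <- dplyr::filter(fusions,
                       .data$split_reads > min_split,
                       .data$probability > min_prob)
  if (!is.null(gene_whitelist) && length(gene_whitelist) > 0) {
    out <- dplyr::filter(out, .data$gene_5p %in% gene_whitelist |
                           .data$gene_3p %in% gene_whitelist)
  }
  out
}

#' Apply a protein-level change to a reference protein
#'
#' @param protein Reference protein sequence (single string).
#' @param position 1-based position of the first affected residue.
#' @param ref Reference residue(s) expected at `position` (consistency
#'   checked; a mismatch is an error).
#' @param alt Alternate residue(s). For `"substitution"` ref and alt have
#'   equal length; for `"inframe_ins"` alt is inserted in place of ref
#'   (ref may be a single anchor residue retained in alt); for
#'   `"inframe_del"` alt is the (possibly empty) replacement of ref; for
#'   `"frameshift"` alt is the full alternate C-terminal tail replacing
#'   everything from `position` onward.
#' @param kind One of `"substitution"`, `"inframe_ins"`, `"inframe_del"`,
#'   `"frameshift"`.
#' @return The mutated protein sequence. A substitution with `alt == ref`
#'   returns the input unchanged with a warning.
#' @examples
#' apply_protein_change("TLPLPNLRVVRGTQV", 9, "V", "L") # V9L
#' @export
apply_protein_change <- function(protein, position, ref, alt,
                                 kind = c("substitution", "inframe_ins",
                                          "inframe_del", "frameshift")) {
  kind <- match.arg(kind)
  protein <- toupper(protein); ref <- toupper(ref); alt <- toupper(alt)
  n <- nchar(protein)
  stopifnot(position >= 1, position <= n)
  observed <- substr(protein, position, position + nchar(ref) - 1L)
  if (!identical(observed, ref)) {
    stop(sprintf(
      "reference mismatch at position %d: protein has '%s', change expects '%s'",
      position, observed, ref), call. = FALSE)
  }
  if (kind == "substitution" && identical(alt, ref)) {
    warning("substitution with alt == ref: protein returned unchanged",
            call. = FALSE)
    return(protein)
  }
  head <- substr(protein, 1L, position - 1L)
  if (kind == "frameshift") {
    if (!nzchar(alt)) {
      stop("frameshift requires an explicit alternate C-terminal sequence",
           call. = FALSE)
    }
    return(paste0(head, alt))
  }
  tail <- substr(protein, position + nchar(ref), n)
  paste0(head, alt, tail)
}

#' Scan mutation-spanning windows for predicted binders
#'
#' Enumerates every contiguous window of the mutated protein, at every
#' peptide length for which the patient has a score matrix, that contains
#' at least one mutated position, and retains windows whose relative PSSM
#' score exceeds `rel_threshold` (strict `>`) on at least one allele.
#'
#' @param protein Mutated protein sequence.
#' @param mutated_positions Integer vector of 1-based mutated residue
#'   positions in the mutated protein.
#' @param alleles Patient's class I alleles.
#' @param matrices List of [score_matrix()] objects; the scanned window
#'   lengths are the matrix lengths available for the patient's alleles.
#' @param rel_threshold Relative-score cutoff, percent (default 60).
#' @return Tibble of retained windows: `sequence`, `start`, `end`,
#'   `length`, `best_relative`, `best_allele`, sorted by descending score
#'   then position.
#' @export
scan_mutated_windows <- function(protein, mutated_positions, alleles,
                                 matrices, rel_threshold = 60) {
  protein <- toupper(protein)
  n <- nchar(protein)
  stopifnot(length(mutated_positions) >= 1,
            all(mutated_positions >= 1), all(mutated_positions <= n))
  lengths <- sort(unique(unlist(lapply(matrices, function(m) {
    if (m$allele %in% alleles) m$length else NULL
  }))))
  out <- purrr::map_dfr(lengths, function(L) {
    if (L > n) return(NULL)
    starts <- seq_len(n - L + 1L)
    ends <- starts + L - 1L
    covers <- vapply(seq_along(starts), function(i)
      any(mutated_positions >= starts[i] & mutated_positions <= ends[i]),
      logical(1))
    starts <- starts[covers]; ends <- ends[covers]
    if (length(starts) == 0) return(NULL)
    seqs <- substring(protein, starts, ends)
    sc <- best_relative_score(seqs, alleles, matrices)
    tibble::tibble(sequence = seqs, start = starts, end = ends,
                   length = L, best_relative = sc$best_relative,
                   best_allele = sc$best_allele)
  })
  if (nrow(out) == 0) return(out)
  out |>
    dplyr::filter(!is.na(.data$best_relative),
                  .data$best_relative > rel_threshold) |>
    dplyr::arrange(dplyr::desc(.data$best_relative), .data$start)
}

#' Extend a predicted binder window to a 15-mer long peptide
#'
#' Flanking residues are distributed as evenly as possible around the
#' window; an odd remainder places the extra residue on the C-terminal
#' side. When the protein end clips one flank the deficit shifts to the
#' other side, so the output is always exactly 15 residues and always
#' contains the window.
#'
#' @param start,end 1-based window span in `protein`.
#' @param protein Mutated protein sequence (length >= 15, otherwise an
#'   error).
#' @param wildtype Optional wildtype protein of the same length
#'   (substitutions); when given, the wildtype counterpart 15-mer at the
#'   same coordinates is returned alongside.
#' @return Tibble row: `sequence` (the 15-mer), `start`, `end`,
#'   `window_start`, `window_end`, and `wildtype` (the counterpart
#'   sequence or `NA`).
#' @export
extend_to_15mer <- function(start, end, protein, wildtype = NULL) {
  protein <- toupper(protein)
  n <- nchar(protein)
  target <- 15L
  if (n < target) {
    stop("protein shorter than 15 residues: cannot extend", call. = FALSE)
  }
  stopifnot(start >= 1, end <= n, end >= start)
  wlen <- end - start + 1L
  if (wlen > target) {
    stop("window longer than 15 residues", call. = FALSE)
  }
  need <- target - wlen
  left <- need %/% 2L
  right <- need - left          # odd remainder goes C-terminal
  s <- start - left
  e <- end + right
  if (s < 1L) { e <- e + (1L - s); s <- 1L }
  if (e > n) { s <- s - (e - n); e <- n }
  out <- tibble::tibble(
    sequence = substr(protein, s, e), start = s, end = e,
    window_start = start, window_end = end,
    wildtype = NA_character_)
  if (!is.null(wildtype)) {
    wildtype <- toupper(wildtype)
    if (nchar(wildtype) == n) {
      out$wildtype <- substr(wildtype, s, e)
    }
  }
  out
}

#' Predict neoepitope long peptides from filtered variants
#'
#' End-to-end convenience wrapper: applies each retained substitution to
#' its reference protein, scans mutation-spanning windows
#' ([scan_mutated_windows()]), and extends every retained window to a
#' 15-mer with its wildtype counterpart ([extend_to_15mer()]). Fusion
#' events contribute their junction peptide context directly, with the
#' junction position treated as mutated.
#'
#' @param variants Filtered variant tibble (see
#'   [filter_somatic_variants()]) with additional columns `position`,
#'   `ref`, `alt`, `kind`.
#' @param proteins Named character vector of reference protein sequences,
#'   keyed by gene.
#' @param alleles,matrices,rel_threshold Passed to
#'   [scan_mutated_windows()].
#' @param fusions Optional filtered fusion tibble with
#'   `junction_context` (protein sequence spanning the junction) and
#'   `junction_position` (1-based first 3' residue).
#' @return Tibble of candidate long peptides: `gene`, `origin`
#'   (`"mutation"` or `"fusion"`), `sequence`, `wildtype`, `window`,
#'   `best_relative`, `best_allele`.
#' @export
predict_neoepitopes <- function(variants, proteins, alleles, matrices,
                                rel_threshold = 60, fusions = NULL) {
  rows <- list()
  if (!is.null(variants) && nrow(variants) > 0) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      wt <- proteins[[v$gene]]
      if (is.null(wt)) {
        stop("no reference protein for gene ", v$gene, call. = FALSE)
      }
      mut <- apply_protein_change(wt, v$position, v$ref, v$alt,
                                  kind = v$kind)
      mpos <- v$position + seq_len(max(nchar(v$alt), 1L)) - 1L
      mpos <- mpos[mpos <= nchar(mut)]
      wins <- scan_mutated_windows(mut, mpos, alleles, matrices,
                                   rel_threshold = rel_threshold)
      if (nrow(wins) == 0) next
      wt_aligned <- if (v$kind == "substitution") wt else NULL
      ext <- purrr::pmap_dfr(
        wins[, c("start", "end", "best_relative", "best_allele")],
        function(start, end, best_relative, best_allele) {
          e <- extend_to_15mer(start, end, mut, wildtype = wt_aligned)
          e$window <- substr(mut, start, end)
          e$best_relative <- best_relative
          e$best_allele <- best_allele
          e
        })
      ext$gene <- v$gene
      ext$origin <- "mutation"
      rows[[length(rows) + 1L]] <- ext
    }
  }
  if (!is.null(fusions) && nrow(fusions) > 0) {
    for (i in seq_len(nrow(fusions))) {
      f <- fusions[i, ]
      ctx <- toupper(f$junction_context)
      wins <- scan_mutated_windows(ctx, f$junction_position, alleles,
                                   matrices, rel_threshold = rel_threshold)
      if (nrow(wins) == 0) next
      ext <- purrr::pmap_dfr(
        wins[, c("start", "end", "best_relative", "best_allele")],
        function(start, end, best_relative, best_allele) {
          e <- extend_to_15mer(start, end, ctx)
          e$window <- substr(ctx, start, end)
          e$best_relative <- best_relative
          e$best_allele <- best_allele
          e
        })
      ext$gene <- paste(f$gene_5p, f$gene_3p, sep = "-")
      ext$origin <- "fusion"
      rows[[length(rows) + 1L]] <- ext
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      gene = character(), origin = character(), sequence = character(),
      wildtype = character(), window = character(),
      best_relative = numeric(), best_allele = character()))
  }
  dplyr::bind_rows(rows) |>
    dplyr::distinct(.data$gene, .data$sequence, .keep_all = TRUE) |>
    dplyr::select("gene", "origin", "sequence", "wildtype", "window",
                  "best_relative", "best_allele")
}
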