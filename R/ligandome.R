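# Ligand set ingest and set-algebra primitives. A "ligand set" is a plain
# tibble with one row per unique peptide sequence; every cascade step is a
# set operation on these tibbles.

#' Class-specific peptide length range
#'
#' Eluted HLA class I ligands are retained at 8--12 residues, class II
#' ligands at 9--25 residues; rows outside the range are dropped at ingest.
#'
#' @param hla_class `"I"` or `"II"`.
#' @return Integer vector `c(min, max)`.
#' @export
ligand_length_range <- function(hla_class) {
  hla_class <- match.arg(hla_class, c("I", "II"))
  if (hla_class == "I") c(8L, 12L) else c(9L, 25L)
}

#' Build a ligand set from a data frame
#'
#' Validates, uppercases and deduplicates peptide records. The identity key
#' of a ligand set is the peptide sequence: duplicated sequences keep the
#' first-seen row's metadata and a `multiplicity` column records how many
#' input rows collapsed into each record.
#'
#' @param x Data frame with at least a `sequence` column; `patient_id`,
#'   `tissue` and `source_proteins` are carried through when present.
#' @param hla_class `"I"` or `"II"`; determines the permitted length range.
#' @param enforce_length Drop rows whose length is outside the class range
#'   (default `TRUE`). Dropped and rejected rows are recorded in the
#'   `"drop_log"` attribute of the result.
#' @return A tibble with columns `sequence`, `patient_id`, `tissue`,
#'   `hla_class`, `multiplicity`, one row per unique sequence, and a
#'   `drop_log` attribute (tibble of `reason`, `n`).
#' @export
as_ligand_set <- function(x, hla_class = c("I", "II"), enforce_length = TRUE) {
  hla_class <- match.arg(hla_class)
  stopifnot(is.data.frame(x))
  if (!"sequence" %in% names(x)) {
    stop("ligand table lacks required column 'sequence'", call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (!"patient_id" %in% names(x)) x$patient_id <- NA_character_
  if (!"tissue" %in% names(x)) x$tissue <- NA_character_
  x$sequence <- toupper(as.character(x$sequence))

  bad_alpha <- !is_canonical_seq(x$sequence)
  drops <- tibble::tibble(reason = "non_canonical_residue",
                          n = sum(bad_alpha))
  x <- x[!bad_alpha, , drop = FALSE]

  if (enforce_length) {
    rng <- ligand_length_range(hla_class)
    len <- nchar(x$sequence)
    bad_len <- len < rng[1] | len > rng[2]
    drops <- dplyr::bind_rows(
      drops, tibble::tibble(reason = "length_out_of_range", n = sum(bad_len)))
    x <- x[!bad_len, , drop = FALSE]
  }

  x$hla_class <- hla_class
  out <- x |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(
      dplyr::across(dplyr::everything(), dplyr::first),
      multiplicity = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row")
  attr(out, "drop_log") <- drops
  out
}

#' Read a delimited ligand identification table
#'
#' Ingests a mass-spectrometry identification export (one row per peptide)
#' into a ligand set. Tab or comma separation is auto-detected from the
#' header line unless `delim` is given. Rows with non-canonical residues
#' or out-of-range lengths are dropped and counted in the `drop_log`
#' attribute.
#'
#' @param path Path to a delimited text file.
#' @param hla_class `"I"` or `"II"`.
#' @param col_map Named character vector mapping the canonical roles
#'   `sequence`, `patient`, `tissue` to the file's header names.
#' @param delim Field separator; `NULL` (default) auto-detects.
#' @return A ligand set tibble (see [as_ligand_set()]).
#' @export
read_ligand_table <- function(path, hla_class = c("I", "II"),
                              col_map = c(sequence = "sequence",
                                          patient = "patient",
                                          tissue = "tissue"),
                              delim = NULL) {
  hla_class <- match.arg(hla_class)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- detect_delim(path)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing <- setdiff(unname(col_map), names(raw))
  if (length(missing) > 0) {
    stop("ligand table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- tibble::tibble(
    sequence = raw[[col_map[["sequence"]]]],
    patient_id = as.character(raw[[col_map[["patient"]]]]),
    tissue = as.character(raw[[col_map[["tissue"]]]]))
  as_ligand_set(df, hla_class = hla_class)
}

#' Write a ligand set as tab-separated text
#'
#' @param x Ligand set tibble.
#' @param path Output path.
#' @param provenance Optional string recorded in a `provenance` column.
#' @return `x`, invisibly.
#' @export
write_ligand_table <- function(x, path, provenance = NA_character_) {
  out <- dplyr::mutate(x, provenance = provenance)
  out <- dplyr::select(out, !dplyr::where(is.list))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(x)
}

# Extract the sequence vector from a ligand set, character vector, or NULL.
ligand_sequences <- function(x) {
  if (is.null(x)) return(character(0))
  if (is.character(x)) return(unique(toupper(x)))
  if (is.data.frame(x)) return(unique(x$sequence))
  stop("expected a ligand set tibble or character vector", call. = FALSE)
}

#' Subtract reference peptides from a ligand set
#'
#' The core primitive of tumor-versus-benign ligandome comparison. Three
#' modes are supported:
#' \describe{
#'   \item{`exact`}{remove query records whose sequence equals any
#'     reference sequence (the usual benign-tissue subtraction);}
#'   \item{`query_within_reference`}{remove query records that are a
#'     contiguous substring of any reference sequence (e.g. discarding
#'     class I peptides that are shorter length variants of longer class II
#'     ligands);}
#'   \item{`reference_within_query`}{remove query records that contain any
#'     reference sequence as a contiguous substring (e.g. discarding class
#'     II candidates embedding a benign class I ligand).}
#' }
#'
#' @param query Ligand set tibble (or data frame with a `sequence` column).
#' @param reference Ligand set, character vector of sequences, or `NULL`
#'   (treated as empty; the query is returned unchanged).
#' @param mode One of `"exact"`, `"query_within_reference"`,
#'   `"reference_within_query"`.
#' @return The query tibble with matching records removed; always a subset
#'   of the input rows.
#' @export
ligand_subtract <- function(query,
                            reference,
                            mode = c("exact", "query_within_reference",
                                     "reference_within_query")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(query))
  refs <- ligand_sequences(reference)
  if (nrow(query) == 0 || length(refs) == 0) return(query)
  qs <- query$sequence
  drop <- switch(mode,
    exact = qs %in% refs,
    query_within_reference =
      vapply(qs, function(q) any(stringr::str_detect(
        refs, stringr::fixed(q))), logical(1)),
    reference_within_query =
      vapply(qs, function(q) any(stringr::str_detect(
        q, stringr::fixed(refs))), logical(1)))
  query[!drop, , drop = FALSE]
}

#' Are two peptides nested length variants?
#'
#' Two peptides are nested when one is a contiguous substring of the other
#' (equality counts). This is the length-variant relation used for class II
#' ligands, e.g. a 9-mer core detected alongside its embedding 15-mer.
#'
#' @param a,b Character vectors of peptide sequences (recycled pairwise).
#' @return Logical vector.
#' @examples
#' is_nested("NPPSM", "NPPSMVAAGSVVAAV") # TRUE
#' is_nested("ALK", "GAK")               # FALSE
#' @export
is_nested <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  stringr::str_detect(b, stringr::fixed(a)) |
    stringr::str_detect(a, stringr::fixed(b))
}
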