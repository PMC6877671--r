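# Shared helpers: residue alphabet, rounding convention, delimiter sniffing.

#' Canonical amino-acid alphabet
#'
#' The 20 proteinogenic residues in one-letter code. Isoleucine and leucine
#' are kept distinct: eluted-ligand tables are taken at face value even
#' though mass spectrometry cannot distinguish the two.
#'
#' @format Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Round half away from zero
#'
#' Percentages and means throughout the package are reported with
#' "round half up" semantics (0.5 rounds away from zero), not the IEEE
#' round-half-even used by [base::round()]. Comparisons are always made
#' on unrounded values; this helper only affects reported numbers.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.45, 1) # 0.5
#' round_half_up(84.47)   # 84
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Sniff tab vs comma from the header line; tab wins when both occur
# (gene/peptide tables exported from spreadsheets often carry commas in
# free-text columns).
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

# Is every character of `x` drawn from the canonical alphabet?
is_canonical_seq <- function(x) {
  !is.na(x) & nzchar(x) &
    vapply(strsplit(x, "", fixed = TRUE),
           function(ch) all(ch %in% aa_alphabet()), logical(1))
}
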