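# Independent brute-force oracles used by the property-style tests.
# These deliberately use naive quadratic loops and position-by-position
# summation, independent of the package's vectorized implementations.

oracle_random_peptides <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(aa_alphabet(), len, replace = TRUE), collapse = ""),
    character(1))
}

# Quadratic subtraction oracle over sequence vectors.
oracle_subtract <- function(query, refs, mode) {
  keep <- logical(length(query))
  for (i in seq_along(query)) {
    q <- query[i]
    hit <- FALSE
    for (r in refs) {
      hit <- switch(mode,
        exact = q == r,
        query_within_reference = grepl(q, r, fixed = TRUE),
        reference_within_query = grepl(r, q, fixed = TRUE))
      if (hit) break
    }
    keep[i] <- !hit
  }
  query[keep]
}

# Position-by-position summation oracle for PSSM scoring.
oracle_score <- function(peptide, mat) {
  res <- strsplit(peptide, "")[[1]]
  total <- 0
  for (p in seq_along(res)) {
    w <- mat$weights[p, res[p]]
    total <- total + w
  }
  total
}

# Exhaustive best size-k subset sum for hot-spot selection.
oracle_hotspot_sum <- function(counts, k) {
  max(vapply(utils::combn(seq_along(counts), k, simplify = FALSE),
             function(idx) sum(counts[idx]), numeric(1)))
}

# Hand-rolled 3x3 test matrix used across binding tests:
# p1 A=10 G=0; p2 L=8 A=2; p3 K=6 Y=6 (max score 24).
toy_matrix <- function() {
  w <- matrix(0, nrow = 3, ncol = 3,
              dimnames = list(NULL, c("A", "L", "K")))
  w[1, "A"] <- 10
  w[2, "L"] <- 8; w[2, "A"] <- 2
  w[3, "K"] <- 6
  w <- cbind(w, Y = c(0, 0, 6), G = c(0, 0, 0))
  score_matrix("A*02", w)
}
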