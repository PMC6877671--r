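test_that("somatic variant filtering applies the depth and locus rules", {
  v <- tibble::tibble(
    gene = c("G1", "G2", "G3", "G4", "G5"),
    consequence = c("non_synonymous", "non_synonymous", "non_synonymous",
                    "synonymous", "non_synonymous"),
    tumor_depth = c(30, 25, 80, 90, 40),
    normal_alt_reads = c(0, 0, 2, 0, 0),
    multi_locus = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  kept <- filter_somatic_variants(v)
  # depth 25 is rejected (strict >25); normal-detected, synonymous and
  # multi-locus variants are all discarded
  expect_equal(kept$gene, "G1")
  expect_equal(filter_somatic_variants(v, gene_whitelist = "G2")$gene,
               character(0))
  expect_error(filter_somatic_variants(v[, -3]), "tumor_depth")
})

test_that("fusion filtering applies strict split-read and probability rules", {
  f <- tibble::tibble(
    gene_5p = c("ME2", "AAA", "BBB", "CCC"),
    gene_3p = c("SMAD4", "DDD", "EEE", "FFF"),
    split_reads = c(12, 10, 50, 30),
    probability = c(0.9, 0.9, 0.5, 0.85))
  kept <- filter_fusions(f)
  expect_equal(kept$gene_5p, c("ME2", "CCC"))
  # whitelist needs only one involved partner
  expect_equal(filter_fusions(f, gene_whitelist = "SMAD4")$gene_5p, "ME2")
  f$probability[1] <- 1.2
  expect_error(filter_fusions(f), "probability")
})

test_that("protein changes apply at the stated position", {
  expect_equal(apply_protein_change("TLPLPNLRVVRGTQV", 9, "V", "L"),
               "TLPLPNLRLVRGTQV")
  expect_warning(
    out <- apply_protein_change("TLPLPNLRVVRGTQV", 9, "V", "V"),
    "unchanged")
  expect_equal(out, "TLPLPNLRVVRGTQV")
  expect_error(apply_protein_change("TLPLPNLRVVRGTQV", 9, "A", "L"),
               "mismatch")
  # in-frame insertion and deletion splice the sequence
  expect_equal(
    apply_protein_change("ACDEFG", 3, "D", "DKK", kind = "inframe_ins"),
    "ACDKKEFG")
  expect_equal(
    apply_protein_change("ACDEFG", 3, "DE", "", kind = "inframe_del"),
    "ACFG")
  expect_equal(
    apply_protein_change("ACDEFG", 4, "E", "WYW", kind = "frameshift"),
    "ACDWYW")
})

test_that("window scan finds exactly the hand-enumerated binder window", {
  m <- toy_matrix() # p1 A=10, p2 L=8/A=2, p3 K=6/Y=6; max 24
  # protein AAAALKAAA, mutation at position 5 (L). Length-3 windows that
  # contain position 5: AAL (3-5, score 12 -> 50%), ALK (4-6, 24 -> 100%),
  # LKA (5-7, 0+0+0 -> 0%)
  wins <- scan_mutated_windows("AAAALKAAA", 5, "A*02", list(m),
                               rel_threshold = 60)
  expect_equal(nrow(wins), 1)
  expect_equal(wins$sequence, "ALK")
  expect_equal(wins$start, 4)
  expect_equal(wins$best_relative, 100)
  # threshold 100 excludes even the optimal window
  expect_equal(
    nrow(scan_mutated_windows("AAAALKAAA", 5, "A*02", list(m), 100)), 0)
  # terminal mutation: only windows fitting inside the protein
  wins_t <- scan_mutated_windows("ALK", 3, "A*02", list(m),
                                 rel_threshold = -1)
  expect_equal(wins_t$sequence, "ALK")
})

test_that("window scan agrees with a brute-force enumerator", {
  set.seed(71)
  for (rep in 1:50) {
    n <- sample(15:60, 1)
    prot <- oracle_random_peptides(1, n)
    mpos <- sort(sample(seq_len(n), sample(1:2, 1)))
    L <- sample(8:10, 1)
    w <- matrix(sample(0:9, 20 * L, replace = TRUE), nrow = L,
                dimnames = list(NULL, aa_alphabet()))
    m <- score_matrix("A*02", w)
    thr <- sample(c(40, 60, 80), 1)
    got <- scan_mutated_windows(prot, mpos, "A*02", list(m), thr)
    # oracle: enumerate all windows of length L, keep covering + passing
    exp_rows <- list()
    if (L <= n) {
      for (s in seq_len(n - L + 1)) {
        e <- s + L - 1
        if (!any(mpos >= s & mpos <= e)) next
        seqw <- substr(prot, s, e)
        rel <- 100 * oracle_score(seqw, m) / m$max_score
        if (rel > thr) exp_rows[[length(exp_rows) + 1]] <-
            tibble::tibble(sequence = seqw, start = s)
      }
    }
    if (length(exp_rows) == 0) {
      expect_equal(nrow(got), 0)
    } else {
      exp_df <- dplyr::bind_rows(exp_rows)
      expect_equal(got[order(got$start), c("sequence", "start")],
                   exp_df[order(exp_df$start), ],
                   ignore_attr = TRUE)
      # every retained window occurs at its recorded span
      expect_equal(substring(prot, got$start, got$end), got$sequence)
    }
  }
})

test_that("15-mer extension is symmetric, C-biased on odd remainder, and clips", {
  prot <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 2), collapse = "")
  # 9-mer centered: 3 flank residues each side
  e1 <- extend_to_15mer(16, 24, prot)
  expect_equal(nchar(e1$sequence), 15)
  expect_equal(c(e1$start, e1$end), c(13, 27))
  # even window (8-mer): need 7, left 3, right 4 (extra residue C-terminal)
  e2 <- extend_to_15mer(16, 23, prot)
  expect_equal(c(e2$start, e2$end), c(13, 27))
  # window at the N-terminus of the protein: deficit shifts C-terminal
  e3 <- extend_to_15mer(1, 9, prot)
  expect_equal(c(e3$start, e3$end), c(1, 15))
  # window at the C-terminus: deficit shifts N-terminal
  e4 <- extend_to_15mer(nchar(prot) - 8, nchar(prot), prot)
  expect_equal(c(e4$start, e4$end), c(nchar(prot) - 14, nchar(prot)))
  expect_error(extend_to_15mer(1, 8, "ACDEFGHIKLMNPQ"), "shorter")
})

test_that("neoepitope pipeline reproduces a mutated/wildtype 15-mer pair", {
  # reference protein embedding the wildtype context; V->L substitution
  wt_prot <- paste0("MKKAAGG", "TLPLPNLRVVRGTQV", "GGAAKKM")
  pos <- 7 + 9 # the V at position 9 of the embedded context
  # matrix that scores the mutated 9-mer LPNLRLVRG maximally; that window
  # is centered in the 15-mer context, so symmetric extension recovers it
  target <- "LPNLRLVRG"
  w <- matrix(0, nrow = 9, ncol = 20, dimnames = list(NULL, aa_alphabet()))
  for (p in 1:9) w[p, substr(target, p, p)] <- 10
  m <- score_matrix("A*02", w)
  variants <- tibble::tibble(
    gene = "ERBB3", position = pos, ref = "V", alt = "L",
    kind = "substitution", consequence = "non_synonymous",
    tumor_depth = 60, normal_alt_reads = 0, multi_locus = FALSE)
  neo <- predict_neoepitopes(
    filter_somatic_variants(variants),
    proteins = c(ERBB3 = wt_prot), alleles = "A*02", matrices = list(m))
  expect_equal(nrow(neo), 1)
  expect_equal(neo$sequence, "TLPLPNLRLVRGTQV")
  expect_equal(neo$wildtype, "TLPLPNLRVVRGTQV")
  expect_equal(neo$window, "LPNLRLVRG")
  # the pair differs at exactly the mutated position
  d <- which(strsplit(neo$sequence, "")[[1]] !=
               strsplit(neo$wildtype, "")[[1]])
  expect_equal(length(d), 1)
})

test_that("15-mer outputs always contain window and mutation (property)", {
  set.seed(91)
  for (rep in 1:25) {
    n <- sample(15:50, 1)
    prot <- oracle_random_peptides(1, n)
    L <- sample(8:12, 1)
    s <- sample(seq_len(n - L + 1), 1)
    e <- s + L - 1
    mpos <- sample(s:e, 1)
    ext <- extend_to_15mer(s, e, prot)
    expect_equal(nchar(ext$sequence), 15)
    expect_true(ext$start <= s && ext$end >= e)
    expect_true(ext$start <= mpos && ext$end >= mpos)
    expect_equal(substr(prot, ext$start, ext$end), ext$sequence)
  }
})

test_that("synthetic variant tables separate passing from failing calls", {
  vt <- gen_variant_table(7)
  kept <- filter_somatic_variants(vt$variants)
  expect_equal(sort(kept$gene), sort(vt$truth))
  vt2 <- gen_variant_table(7)
  expect_identical(vt$variants, vt2$variants)
})
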