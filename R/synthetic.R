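# Seeded synthetic-data generators with planted ground truth. These
# emulate the *structure* of the study inputs -- tumor ligandomes with a
# tumor-exclusive high-binding subset, benign reference compendia, nested
# class I/class II length variants, somatic variant tables, ICS event
# counts with planted response classes, and IHC counts with a group
# effect -- so every pipeline stage can be exercised against a known
# answer. Each generator draws from its own stream (stable sub-seeding
# from the scenario seed), so adding one generator never perturbs
# another.

sub_seed <- function(seed, k) {
  (as.integer(seed) + k * 10007L) %% .Machine$integer.max
}

# n unique random peptides of the given length, avoiding `exclude`.
rand_peptides <- function(n, length, exclude = character()) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 200L) {
      stop("alphabet too small to generate enough unique peptides",
           call. = FALSE)
    }
    batch <- vapply(seq_len(max(n, 32L)), function(i)
      paste(sample(aa_alphabet(), length, replace = TRUE), collapse = ""),
      character(1))
    out <- unique(c(out, setdiff(batch, exclude)))
  }
  out[seq_len(n)]
}

#' Generate a synthetic allele score matrix
#'
#' Builds a PSSM with pronounced anchor columns: each anchor position has
#' one dominant residue (weight 10, all others 0), non-anchor positions
#' carry small random weights (0--4). With no anchors the matrix is
#' near-uniform (weights 4--5), so every peptide scores at least 80% of
#' the maximum. Deterministic per seed.
#'
#' @param seed Integer seed for this matrix's stream.
#' @param length Peptide length scored (default 9).
#' @param anchor_positions Integer positions of anchor columns (default
#'   position 2 and the C-terminus, the classic class I anchors).
#' @param allele Allele name to attach (default `"A*02"`).
#' @return A [score_matrix()].
#' @export
gen_score_matrix <- function(seed, length = 9,
                             anchor_positions = c(2, length),
                             allele = "A*02") {
  stopifnot(length >= 8)
  set.seed(sub_seed(seed, 1L))
  w <- matrix(0, nrow = length, ncol = 20,
              dimnames = list(NULL, aa_alphabet()))
  for (p in seq_len(length)) {
    if (p %in% anchor_positions) {
      dom <- sample(aa_alphabet(), 1)
      w[p, dom] <- 10
    } else if (length(anchor_positions) == 0) {
      w[p, ] <- sample(4:5, 20, replace = TRUE)
    } else {
      w[p, ] <- sample(0:4, 20, replace = TRUE)
    }
  }
  score_matrix(allele, w)
}

# Construct a peptide scoring above `rel_min` on `matrix` by sampling
# residues from the top of each position's weight column.
strong_binder <- function(matrix, rel_min = 70, exclude = character()) {
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 500L) {
      stop("failed to construct a strong binder above the requested band",
           call. = FALSE)
    }
    res <- vapply(seq_len(matrix$length), function(p) {
      col <- matrix$weights[p, ]
      if (stats::runif(1) < 0.85) {
        names(which.max(col))
      } else {
        sample(aa_alphabet(), 1)
      }
    }, character(1))
    pep <- paste(res, collapse = "")
    rel <- 100 * score_peptide(pep, matrix) / matrix$max_score
    if (rel > rel_min && !(pep %in% exclude)) return(pep)
  }
}

# Random peptide whose best relative score across `matrices` does not
# exceed `rel_max` (a guaranteed non-binder under strict thresholds).
weak_binder <- function(matrices, length, rel_max = 50,
                        exclude = character()) {
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 1000L) {
      stop("failed to generate a weak binder", call. = FALSE)
    }
    pep <- rand_peptides(1, length, exclude = exclude)
    rels <- vapply(matrices, function(m) {
      if (m$length != length) return(0)
      100 * score_peptide(pep, m) / m$max_score
    }, numeric(1))
    if (max(rels) <= rel_max) return(pep)
  }
}

#' Generate a ligandome scenario with planted tumor-exclusive binders
#'
#' Builds a tumor class I ligandome composed of (a) peptides shared with
#' the benign reference compendia, (b) tumor-exclusive weak binders
#' (relative score at most 50 on every patient allele), (c)
#' `n_planted` tumor-exclusive strong binders (relative score above
#' `planted_rel_min`), and (d) `n_nested` strong binders that are
#' embedded in class II ligands of the nesting reference (removed at the
#' class II nesting step). A class II tumor set with
#' `n_planted_class2` exclusives is built analogously. The planted
#' truth never collides with any reference set -- checked at generation.
#'
#' @param seed Scenario seed.
#' @param alleles Patient class I alleles; one anchor matrix is generated
#'   per allele.
#' @param n_shared,n_weak,n_planted,n_nested Class I tumor composition.
#' @param n_autologous,n_cohort,n_nmt,n_benign1 Class I reference sizes.
#' @param n_class2_nesting Size of the class II set used for the nesting
#'   filter.
#' @param n_shared_class2,n_planted_class2,n_benign2 Class II scenario
#'   sizes.
#' @param planted_rel_min Lower edge of the planted binder score band,
#'   percent (default 70, comfortably above the final-step threshold of
#'   60).
#' @return List with `tumor_class1`, `tumor_class2` (ligand set
#'   tibbles), `refs_class1`, `refs_class2` (reference lists in the form
#'   [run_class1_cascade()] / [run_class2_cascade()] expect), `matrices`,
#'   `alleles`, and the planted truth (`planted_class1`,
#'   `planted_class2`, `nested_class1`).
#' @export
gen_ligandome_scenario <- function(seed,
                                   alleles = c("A*02", "B*07"),
                                   n_shared = 300, n_weak = 180,
                                   n_planted = 20, n_nested = 5,
                                   n_autologous = 350, n_cohort = 350,
                                   n_nmt = 250, n_benign1 = 500,
                                   n_class2_nesting = 150,
                                   n_shared_class2 = 150,
                                   n_planted_class2 = 20,
                                   n_benign2 = 250,
                                   planted_rel_min = 70) {
  set.seed(sub_seed(seed, 2L))
  matrices <- lapply(seq_along(alleles), function(i)
    gen_score_matrix(sub_seed(seed, 100L + i), length = 9,
                     allele = alleles[i]))

  set.seed(sub_seed(seed, 3L))
  # Benign class I universe; reference sub-sets are overlapping samples.
  universe <- rand_peptides(n_benign1 + 200L, 9)
  benign_multi <- sample(universe, n_benign1)
  autologous <- sample(universe, n_autologous)
  cohort <- sample(universe, n_cohort)
  nmt <- sample(universe, n_nmt)
  any_ref <- unique(c(benign_multi, autologous, cohort, nmt))

  shared <- sample(any_ref, n_shared)
  weak <- character(n_weak)
  taken <- c(universe, shared)
  for (i in seq_len(n_weak)) {
    weak[i] <- weak_binder(matrices, 9, rel_max = 50, exclude = taken)
    taken <- c(taken, weak[i])
  }

  # Class II nesting reference: random 15-mers plus the embedders of the
  # nested class I peptides; none may contain a planted exclusive.
  nesting_base <- rand_peptides(n_class2_nesting, 15, exclude = taken)

  planted <- character(n_planted)
  for (i in seq_len(n_planted)) {
    m <- matrices[[((i - 1L) %% length(matrices)) + 1L]]
    repeat {
      pep <- strong_binder(m, rel_min = planted_rel_min, exclude = taken)
      inside_ref <- any(stringr::str_detect(nesting_base,
                                            stringr::fixed(pep)))
      if (!inside_ref && !(pep %in% any_ref)) break
    }
    planted[i] <- pep
    taken <- c(taken, pep)
  }

  nested <- character(n_nested)
  embedders <- character(n_nested)
  for (i in seq_len(n_nested)) {
    m <- matrices[[((i - 1L) %% length(matrices)) + 1L]]
    repeat {
      pep <- strong_binder(m, rel_min = planted_rel_min, exclude = taken)
      if (!(pep %in% any_ref)) break
    }
    nested[i] <- pep
    taken <- c(taken, pep)
    flank_n <- paste(sample(aa_alphabet(), 3, replace = TRUE),
                     collapse = "")
    flank_c <- paste(sample(aa_alphabet(), 3, replace = TRUE),
                     collapse = "")
    embedders[i] <- paste0(flank_n, pep, flank_c)
  }
  class2_nesting <- unique(c(nesting_base, embedders))

  tumor1 <- as_ligand_set(
    tibble::tibble(sequence = c(shared, weak, planted, nested),
                   patient_id = "SYN01", tissue = "tumor"),
    hla_class = "I")

  # ---- class II scenario ----
  set.seed(sub_seed(seed, 4L))
  universe2 <- rand_peptides(n_benign2 + 150L, 15, exclude = class2_nesting)
  benign_multi2 <- sample(universe2, n_benign2)
  autologous2 <- sample(universe2, round(n_benign2 * 0.7))
  cohort2 <- sample(universe2, round(n_benign2 * 0.7))
  nmt2 <- sample(universe2, round(n_benign2 * 0.5))
  any_ref2 <- unique(c(benign_multi2, autologous2, cohort2, nmt2))
  containment_ref <- unique(c(benign_multi, cohort))

  shared2 <- sample(any_ref2, n_shared_class2)
  planted2 <- character(n_planted_class2)
  taken2 <- c(universe2, shared2)
  for (i in seq_len(n_planted_class2)) {
    repeat {
      pep <- rand_peptides(1, 15, exclude = taken2)
      contains_ref1 <- any(stringr::str_detect(pep,
                                               stringr::fixed(containment_ref)))
      nested_in_ref2 <- any(is_nested(pep, any_ref2))
      if (!contains_ref1 && !nested_in_ref2) break
    }
    planted2[i] <- pep
    taken2 <- c(taken2, pep)
  }
  tumor2 <- as_ligand_set(
    tibble::tibble(sequence = c(shared2, planted2),
                   patient_id = "SYN01", tissue = "tumor"),
    hla_class = "II")

  stopifnot(!any(planted %in% any_ref),
            !any(planted2 %in% any_ref2))

  list(
    tumor_class1 = tumor1,
    tumor_class2 = tumor2,
    refs_class1 = list(
      autologous_nml = autologous, cohort_nml = cohort,
      nmt_colon = nmt, benign_multi = benign_multi,
      class2_for_nesting = class2_nesting),
    refs_class2 = list(
      autologous_nml = autologous2, cohort_nml = cohort2,
      nmt_colon = nmt2, benign_multi = benign_multi2,
      benign_class1_containment = containment_ref),
    matrices = matrices,
    alleles = alleles,
    planted_class1 = sort(planted),
    planted_class2 = sort(planted2),
    nested_class1 = sort(nested))
}

#' Generate an ICS panel with planted response classes
#'
#' Produces a long-format event-count table (one row per stimulus,
#' timepoint, marker, plus matched DMSO control rows) in which each
#' stimulus carries a planted longitudinal truth: `"absent"` stimuli stay
#' at background; `"induced"` stimuli exceed both positivity criteria on
#' three markers at post-treatment timepoints only; `"enhanced"` stimuli
#' are positive before treatment and triple their background-subtracted
#' magnitude afterwards; `"pre_existing_not_enhanced"` stimuli repeat
#' their pre-treatment signal unchanged.
#'
#' @param seed Integer seed.
#' @param classes Character vector of planted truth classes, one per
#'   stimulus (values from the set above).
#' @param timepoints Timepoint labels; the first is the pre-treatment
#'   baseline.
#' @param subset `"CD4"` or `"CD8"`.
#' @param total_events Subset total event count per observation.
#' @param background_band Control positive fraction band, in percent
#'   (default 0.05--0.15).
#' @param effect_fold Planted fold over background for positive markers
#'   (default 3; must be at least the positivity fold threshold of 2).
#' @param excess_margin Planted background-subtracted cell excess
#'   (default 60; must be at least the 20-cell criterion).
#' @return List with `data` (the event-count tibble for [call_ics()])
#'   and `truth` (tibble of `stimulus`, `class`).
#' @export
gen_ics_panel <- function(seed,
                          classes = c("induced", "enhanced",
                                      "pre_existing_not_enhanced",
                                      "absent"),
                          timepoints = c("pre", "1M", "4M"),
                          subset = "CD4",
                          total_events = 15000,
                          background_band = c(0.05, 0.15),
                          effect_fold = 3, excess_margin = 60) {
  if (effect_fold < 2 || excess_margin < 20) {
    stop("planted effect sizes must meet the positivity criteria ",
         "(fold >= 2, excess >= 20)", call. = FALSE)
  }
  set.seed(sub_seed(seed, 5L))
  stimuli <- sprintf("PEP%02d", seq_along(classes))

  # One DMSO control per (timepoint, marker), shared by all stimuli.
  controls <- tidyr::expand_grid(timepoint = timepoints,
                                 marker = ICS_MARKERS) |>
    dplyr::mutate(
      is_pre = .data$timepoint == timepoints[1],
      ctrl_pos = round(stats::runif(dplyr::n(), background_band[1],
                                    background_band[2]) / 100 *
                         total_events))

  rows <- list()
  for (si in seq_along(stimuli)) {
    cls <- classes[si]
    pos_markers <- sample(ICS_MARKERS, 3)
    stim_rows <- controls |>
      dplyr::mutate(
        active = .data$marker %in% pos_markers & switch(cls,
          absent = FALSE,
          induced = !.data$is_pre,
          enhanced = TRUE,
          pre_existing_not_enhanced = TRUE,
          stop("unknown planted class: ", cls, call. = FALSE)),
        base = (effect_fold - 1) * .data$ctrl_pos + excess_margin,
        boost = dplyr::case_when(
          !.data$active ~ 0,
          cls == "enhanced" & !.data$is_pre ~ 3 * .data$base,
          TRUE ~ .data$base),
        patient_id = "SYN01", stimulus = stimuli[si], subset = subset,
        pos_events = .data$ctrl_pos + .data$boost,
        total_events = total_events) |>
      dplyr::select("patient_id", "timepoint", "is_pre", "stimulus",
                    "subset", "marker", "pos_events", "total_events")
    rows[[length(rows) + 1L]] <- stim_rows
  }
  ctrl_rows <- controls |>
    dplyr::mutate(patient_id = "SYN01", stimulus = "DMSO",
                  subset = subset, pos_events = .data$ctrl_pos,
                  total_events = total_events) |>
    dplyr::select("patient_id", "timepoint", "is_pre", "stimulus",
                  "subset", "marker", "pos_events", "total_events")
  data <- dplyr::bind_rows(c(rows, list(ctrl_rows)))
  list(data = data,
       truth = tibble::tibble(stimulus = stimuli, class = classes))
}

#' Generate an IHC count table with a planted group effect
#'
#' Per-patient, per-HPF positive-cell counts drawn from a negative
#' binomial distribution, with a configurable mean shift between the two
#' treatment groups. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param n_a,n_b Patients per group (defaults 9 and 7).
#' @param mean_a,mean_b Group mean counts per HPF.
#' @param dispersion Negative binomial size parameter (smaller = more
#'   overdispersed; default 8).
#' @param n_hpf Fields counted per patient (default 5).
#' @return List with `data` (tibble: `patient_id`, `group`, `hpf`,
#'   `count`), `per_patient` (mean count per patient via
#'   [mean_per_hpf()]), and `truth` (the generating means).
#' @export
gen_ihc_table <- function(seed, n_a = 9, n_b = 7, mean_a = 60,
                          mean_b = 30, dispersion = 8, n_hpf = 5) {
  set.seed(sub_seed(seed, 6L))
  gen_group <- function(n, mu, group, prefix) {
    purrr::map_dfr(seq_len(n), function(i)
      tibble::tibble(
        patient_id = sprintf("%s%02d", prefix, i), group = group,
        hpf = seq_len(n_hpf),
        count = stats::rnbinom(n_hpf, size = dispersion, mu = mu)))
  }
  data <- dplyr::bind_rows(
    gen_group(n_a, mean_a, "RFA_plus_surgery", "RFA"),
    gen_group(n_b, mean_b, "surgery_only", "SRG"))
  per_patient <- data |>
    dplyr::group_by(.data$patient_id, .data$group) |>
    dplyr::summarise(value = mean_per_hpf(.data$count, n_expected = n_hpf),
                     .groups = "drop")
  list(data = data, per_patient = per_patient,
       truth = tibble::tibble(group = c("RFA_plus_surgery", "surgery_only"),
                              mean = c(mean_a, mean_b)))
}

#' Generate a somatic variant table with depth structure
#'
#' Emulates a filtered variant-caller export at the protein level:
#' substitutions in synthetic reference proteins with tumor depths drawn
#' around a configurable mean, a fraction of rows planted to fail each
#' filter (shallow depth, normal-detected, multi-locus, synonymous).
#'
#' @param seed Integer seed.
#' @param n_pass Variants constructed to pass every filter.
#' @param n_fail Variants constructed to fail at least one filter.
#' @param protein_length Length of each synthetic reference protein.
#' @return List with `variants` (tibble ready for
#'   [filter_somatic_variants()], including `position`, `ref`, `alt`,
#'   `kind`), `proteins` (named character vector), and `truth` (genes of
#'   the passing variants).
#' @export
gen_variant_table <- function(seed, n_pass = 4, n_fail = 6,
                              protein_length = 60) {
  set.seed(sub_seed(seed, 7L))
  n <- n_pass + n_fail
  genes <- sprintf("GENE%02d", seq_len(n))
  proteins <- vapply(genes, function(g)
    rand_peptides(1, protein_length), character(1))
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    pos <- sample(seq(10, protein_length - 10), 1)
    ref <- substr(proteins[[i]], pos, pos)
    alt <- sample(setdiff(aa_alphabet(), ref), 1)
    passing <- i <= n_pass
    fail_mode <- if (passing) "none" else
      sample(c("depth", "normal", "multi_locus", "synonymous"), 1)
    tibble::tibble(
      gene = genes[i], position = pos, ref = ref, alt = alt,
      kind = "substitution",
      consequence = if (fail_mode == "synonymous") "synonymous" else
        "non_synonymous",
      tumor_depth = if (fail_mode == "depth") sample(5:25, 1) else
        sample(30:120, 1),
      normal_alt_reads = if (fail_mode == "normal") sample(1:5, 1) else 0L,
      multi_locus = fail_mode == "multi_locus")
  })
  list(variants = rows, proteins = proteins,
       truth = genes[seq_len(n_pass)])
}
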