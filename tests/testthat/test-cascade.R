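test_that("class I cascade recovers exactly the planted exclusives", {
  sc <- gen_ligandome_scenario(101)
  res <- run_class1_cascade(sc$tumor_class1, sc$alleles, sc$refs_class1,
                            sc$matrices, patient_id = "SYN01")
  expect_s3_class(res, "cascade_result")
  expect_equal(sort(res$final_candidates$sequence), sc$planted_class1)
  # counts are non-increasing along the trace
  expect_true(all(diff(res$trace$n_retained) <= 0))
  # the nesting step removes exactly the planted nested peptides
  tr <- res$trace
  n_before <- tr$n_retained[tr$name == "benign_multi"]
  n_after <- tr$n_retained[tr$name == "class2_nesting"]
  expect_equal(n_before - n_after, length(sc$nested_class1))
})

test_that("class II cascade recovers planted exclusives and handles overlap", {
  sc <- gen_ligandome_scenario(102)
  res <- run_class2_cascade(sc$tumor_class2, sc$refs_class2,
                            patient_id = "SYN01")
  expect_equal(sort(res$final_candidates$sequence), sc$planted_class2)

  # tumor identical to autologous NML -> empty final set
  tum <- as_ligand_set(
    tibble::tibble(sequence = sc$refs_class2$autologous_nml[1:30]), "II")
  res2 <- run_class2_cascade(
    tum, list(autologous_nml = sc$refs_class2$autologous_nml,
              cohort_nml = character(0), nmt_colon = character(0),
              benign_multi = character(0),
              benign_class1_containment = character(0)))
  expect_equal(nrow(res2$final_candidates), 0)
})

test_that("class II candidates embedding a benign class I ligand are removed", {
  tum <- as_ligand_set(
    tibble::tibble(sequence = c("NPPSMVAAGSVVAAV", "WIVDHEYRNAQKMPF")), "II")
  refs <- list(autologous_nml = character(0), cohort_nml = character(0),
               nmt_colon = character(0), benign_multi = character(0),
               benign_class1_containment = "SMVAAGSVV")
  res <- run_class2_cascade(tum, refs)
  expect_equal(res$final_candidates$sequence, "WIVDHEYRNAQKMPF")
  tr <- res$trace
  expect_equal(tr$n_retained[tr$name == "class1_containment"], 1)
})

test_that("empty tumor input yields an all-zero trace", {
  sc <- gen_ligandome_scenario(103, n_shared = 5, n_weak = 5,
                               n_planted = 2, n_nested = 1,
                               n_benign1 = 60, n_autologous = 40,
                               n_cohort = 40, n_nmt = 30,
                               n_class2_nesting = 20,
                               n_shared_class2 = 5, n_planted_class2 = 2,
                               n_benign2 = 40)
  empty <- sc$tumor_class1[0, ]
  res <- run_class1_cascade(empty, sc$alleles, sc$refs_class1, sc$matrices)
  expect_true(all(res$trace$n_retained == 0))
  expect_equal(nrow(res$final_candidates), 0)
})

test_that("a missing reference sub-set is a configuration error, and steps can be disabled", {
  sc <- gen_ligandome_scenario(104, n_shared = 20, n_weak = 20,
                               n_planted = 3, n_nested = 1,
                               n_benign1 = 80, n_autologous = 50,
                               n_cohort = 50, n_nmt = 40,
                               n_class2_nesting = 30,
                               n_shared_class2 = 10, n_planted_class2 = 3,
                               n_benign2 = 50)
  refs_no_auto <- sc$refs_class1
  refs_no_auto$autologous_nml <- NULL
  expect_error(
    run_class1_cascade(sc$tumor_class1, sc$alleles, refs_no_auto,
                       sc$matrices),
    "autologous_nml")
  # the same run with the step disabled (the no-autologous-tissue case)
  res <- run_class1_cascade(
    sc$tumor_class1, sc$alleles, refs_no_auto, sc$matrices,
    steps = c("binder", "motif", "cohort_nml", "nmt_colon",
              "benign_multi", "class2_nesting", "final_score"))
  expect_s3_class(res, "cascade_result")
  # disabling a subtraction step never shrinks the final set
  full <- run_class1_cascade(sc$tumor_class1, sc$alleles, sc$refs_class1,
                             sc$matrices)
  expect_true(all(full$final_candidates$sequence %in%
                    res$final_candidates$sequence))
})

test_that("exact-subtraction steps commute: membership is order-invariant", {
  sc <- gen_ligandome_scenario(105, n_shared = 120, n_weak = 60,
                               n_planted = 8, n_nested = 2)
  subtr <- c("autologous_nml", "cohort_nml", "nmt_colon", "benign_multi")
  base <- run_class1_cascade(sc$tumor_class1, sc$alleles, sc$refs_class1,
                             sc$matrices)
  set.seed(9)
  for (rep in 1:4) {
    perm <- sample(subtr)
    res <- run_class1_cascade(
      sc$tumor_class1, sc$alleles, sc$refs_class1, sc$matrices,
      steps = c("binder", "motif", perm, "class2_nesting", "final_score"))
    expect_equal(sort(res$final_candidates$sequence),
                 sort(base$final_candidates$sequence))
  }
})

test_that("with empty references the cascade is a one-pass binder filter", {
  set.seed(55)
  m <- gen_score_matrix(77, length = 9, allele = "A*02")
  peps <- unique(oracle_random_peptides(500, 9))
  tum <- as_ligand_set(tibble::tibble(sequence = peps), "I")
  refs <- list(autologous_nml = character(0), cohort_nml = character(0),
               nmt_colon = character(0), benign_multi = character(0),
               class2_for_nesting = character(0))
  res <- run_class1_cascade(tum, "A*02", refs, list(m))
  # brute-force one-pass filter at the final threshold
  rel <- vapply(peps, function(p)
    100 * oracle_score(p, m) / m$max_score, numeric(1))
  expect_equal(sort(res$final_candidates$sequence),
               sort(unname(peps[rel > 60])))
})

test_that("cascade accessors tidy/glance/autoplot expose the trace", {
  sc <- gen_ligandome_scenario(106, n_shared = 30, n_weak = 20,
                               n_planted = 4, n_nested = 1)
  res <- run_class1_cascade(sc$tumor_class1, sc$alleles, sc$refs_class1,
                            sc$matrices, patient_id = "SYN01")
  td <- generics::tidy(res)
  expect_named(td, c("step", "name", "n_retained"))
  gl <- generics::glance(res)
  expect_equal(gl$n_final, nrow(res$final_candidates))
  expect_equal(gl$reduction_pct,
               round_half_up(100 * (gl$n_input - gl$n_final) / gl$n_input))
  expect_s3_class(autoplot(res), "ggplot")
})
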