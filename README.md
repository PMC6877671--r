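# hlacascade

Patient-individualized tumor-antigen target selection from eluted HLA
ligandomes, and assessment of the immune responses those targets
elicit.

## What it does, and for whom

Immunopeptidomics labs that profile naturally presented HLA ligands on
tumor and benign tissue face the same per-patient question: which of
the thousands of eluted peptides are worth synthesizing and testing as
T cell targets? `hlacascade` implements the selection arithmetic as
tested, composable R functions:

- **Ligand set algebra** — ingest of delimited peptide identification
  tables with class-specific length ranges (8–12 for class I, 9–25 for
  class II), and exact / substring subtraction primitives.
- **Binding assessment** — additive position-specific scoring matrices
  (SYFPEITHI style). A peptide of length *L* scores
  *S* = Σᵢ *w*(i, aᵢ); its **relative score** is 100·*S*/*S*ₘₐₓ, where
  *S*ₘₐₓ is the sum of the per-position maxima (the maximal allelic
  score). A binder satisfies relative score > 50 **or** predicted
  IC50 < 500 nM (pluggable predictor contract).
- **Selection cascades** — class I: binder classification, motif
  confirmation, exact subtraction of autologous/cohort benign liver,
  benign colon, and a multi-tissue benign compendium, removal of
  class II-nested peptides, final stringency cut at relative score
  > 60. Class II: four subtractions (with nested length variants) plus
  removal of candidates containing a benign class I ligand. Every step
  logs its retained count.
- **Neoepitope prediction** — depth/split-read filtering of somatic
  variant and fusion calls (>25 tumor reads, zero normal alt reads,
  single locus; >10 split reads, probability > 0.8), protein-level
  mutation application, scanning of all mutation-spanning windows
  against the patient's matrices, and extension of predicted binders
  to 15-mers with wildtype counterparts.
- **Curation** — CPM normalization, log2 fold change
  (log₂((t+1)/(n+1))), cohort identification frequency (length variants
  for class II), and deterministic ranking/capping (mutated candidates
  first, 6–9 peptides per patient).
- **ICS response calling** — a marker is positive when its stimulated
  percentage is ≥2× the DMSO control *and* the background-subtracted
  count is ≥20 cells; a response needs ≥2 of 5 markers (IFNG, TNF,
  IL2, CD107a, CD154); longitudinal classes absent / induced /
  pre-existing / enhanced.
- **IHC scoring** — immunoreactive score (positivity bin 0–4 ×
  intensity 0–3, range 0–12), per-HPF means, hot-spot selection,
  Mann–Whitney group comparison (exact for small samples).
- **Synthetic scenarios** — seeded generators with planted ground truth
  for every stage, so the whole pipeline is testable offline.

## Worked example

```r
library(hlacascade)

sc  <- gen_ligandome_scenario(1)   # 505-peptide tumor ligandome, 20 planted
res <- run_class1_cascade(sc$tumor_class1, sc$alleles,
                          sc$refs_class1, sc$matrices,
                          patient_id = "SYN01")
tidy(res)
#>    step name           n_retained
#>   <int> <chr>               <int>
#> 1     0 input                 505
#> 2     1 binder                 52
#> 3     2 motif                  52
#> 4     3 autologous_nml         35
#> 5     4 cohort_nml             29
#> 6     5 nmt_colon              26
#> 7     6 benign_multi           25
#> 8     7 class2_nesting         20
#> 9     8 final_score            20
glance(res)
#>   patient_id hla_class n_input n_final reduction_pct
#> 1 SYN01      I             505      20            96
identical(sort(res$final_candidates$sequence), sc$planted_class1)
#> [1] TRUE
```

The trace reads as a funnel: 505 eluted peptides, 52 confirmed binders,
35 left after removing the patient's own benign-liver ligands, and so
on down to the 20 final candidates — exactly the 20 tumor-exclusive
strong binders the generator planted, a 96% reduction of the initial
pool. The same grammar covers the other stages:

```r
binder_percentage(1508, 1785)      # sample-level binder yield
#> [1] 84.5
irs(85, 3)                         # maximal immunoreactive score
#> [1] 12
compare_groups(c(1, 2, 3), c(4, 5, 6))
#>   u_statistic p_value method significant
#> 1           0     0.1 exact  FALSE
```

`autoplot(res)` draws the funnel; `plot_ics_timecourse()` and
`plot_ihc_groups()` cover the response readouts. See the methods
vignette (`vignettes/target-selection-methods.Rmd`) for the model,
parameter and design-decision details.

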