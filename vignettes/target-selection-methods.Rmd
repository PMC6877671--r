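---
title: "Methods: individualized HLA ligandome target selection and immune response assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individualized HLA ligandome target selection and immune response assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlacascade)
library(dplyr)
```

## The problem

Thermal ablation of a liver metastasis releases tumor cell content in
situ and may prime or boost T cell responses against the patient's own
tumor antigens. Monitoring such responses requires choosing, per
patient, a small set of peptides worth testing: HLA-presented ligands
found on the tumor but on no benign tissue, plus predicted neoepitopes
from somatic mutations and gene fusions. This package implements that
selection arithmetic — the subtraction cascades over eluted ligandomes,
PSSM-based binding assessment, neoepitope window scanning with 15-mer
design, expression-based curation, and the downstream readouts
(intracellular cytokine staining positivity calling,
immunohistochemistry scoring) — as tested, seedable functions.

## Binding model

Binding is scored with additive position-specific scoring matrices
(SYFPEITHI style): one matrix per allele and peptide length, integer
weights per (position, residue), and a *maximal allelic score* equal to
the sum of the per-position maxima. A peptide's **relative score** is
its raw score as a percentage of that maximum, so scores are comparable
across alleles and invariant under rescaling the matrix. External IC50
affinity predictors are abstracted as a function contract
`(peptide, allele) -> nM`; a lookup-table implementation is bundled.
Thresholds follow the printed conventions and are strict: a binder
needs relative score `> 50` *or* IC50 `< 500` nM (the union rule is the
default because either predictor sufficed in the source workflow; an
intersection rule is a switch), and the final cascade stringency cut is
relative score `> 60`. Reported percentages round half up to one
decimal; comparisons always use unrounded values.

```{r}
m <- gen_score_matrix(1, length = 9, allele = "A*02")
peps <- c("ALKDYTREW", "GAKLMNPQR")
relative_score(peps, m)
```

## The selection cascades

The class I cascade applies, in order: binder classification; motif
confirmation (matrix route alone, `> 50%` on a patient allele); exact
subtraction of the autologous non-malignant liver (NML) ligandome, the
cohort NML ligandomes, non-malignant colon tissue (NMT), and a
multi-tissue benign class I compendium; removal of peptides nested
inside any class II ligand (contiguous substring — no core-epitope
alignment); and the `> 60%` stringency cut. The class II cascade
subtracts autologous NML (optionally including nested length variants),
cohort NML, NMT and the benign class II compendium, then removes
candidates that *contain* a benign class I ligand.

Two published descriptions of the class I step order disagree; the
cascade here is a configurable ordered list of named filters, and the
default order follows the version with a printed per-step count trace.
Steps can be disabled individually (patients without autologous benign
tissue skip that subtraction), and the exact-subtraction block is
order-invariant in membership — only the intermediate counts change,
which is property-tested. Final candidates are sorted by best relative
score, then sequence, so reports are deterministic.

Each run returns a `cascade_result` carrying the step trace
(`tidy()`), a one-row summary with the pool reduction percentage
(`glance()`), and a funnel plot (`autoplot()`).

```{r}
sc <- gen_ligandome_scenario(1)
res <- run_class1_cascade(sc$tumor_class1, sc$alleles, sc$refs_class1,
                          sc$matrices, patient_id = "SYN01")
tidy(res)
glance(res)
all(sort(res$final_candidates$sequence) == sc$planted_class1)
```

## Neoepitope prediction

Somatic variants are retained when non-synonymous, covered by more than
25 tumor reads, absent from the matched normal (zero alt reads), and
unambiguous (single-locus transcripts); fusions need more than 10 split
reads and caller probability above 0.8 (the probability is read on a
0–1 scale; the threshold is configurable). Driver/relevance curation is
a user-supplied gene whitelist — the package hard-codes no cancer-gene
list. Depth is interpreted as total tumor coverage at the locus and
"undetectable in normal" as zero alt-supporting reads; both are
parameters.

Retained changes are applied at the protein level (substitution,
in-frame insertion/deletion, or frameshift with an explicit alternate
tail). Every window containing a mutated position, at every
matrix-supported length, is scored; windows above 60% relative score
are extended to exactly 15 residues, distributing flanks evenly with
the odd residue toward the C-terminus and shifting the deficit inward
at protein ends. Scanning *all* mutation-spanning windows is a superset
of any fixed flanking convention, so no predicted binder is missed. For
substitutions the wildtype counterpart 15-mer at the same coordinates
is reported alongside.

## Curation and ranking

Expression support uses counts-per-million normalization and
`log2((tumor + c) / (normal + c))` with pseudocount `c = 1` (the
pseudocount is not printed anywhere authoritative; 1 is the
conventional choice and is configurable). Cohort identification
frequency counts exact matches for class I and nested length variants
for class II. Ranking places mutation/fusion-derived candidates first,
then sorts by an equal-weight score of fold change, cohort frequency
and the user-supplied tumor-association flag (the equal weights are the
package's explicit record of an undocumented manual judgment), breaks
ties lexicographically, and truncates at the testing budget (6–9
peptides per patient in the source workflow; `cap = 9` default).

## ICS response calling

A marker is positive when its stimulated percentage is at least 2-fold
the matched DMSO control percentage *and* the background-subtracted
event count is at least 20 cells; a stimulus responds when at least two
of the five markers (IFNG, TNF, IL2, CD107a, CD154) are positive.
"2-fold above" is implemented inclusively (`>=`), the reading adopted
here because the subtraction criterion already enforces a margin; it is
a parameter. Criterion II subtracts raw gated counts, not percentages.
Longitudinal classes: *absent*, *induced* (negative before treatment,
positive after), *pre-existing not enhanced*, and *enhanced*. No
quantitative definition of enhancement is printed anywhere; the package
defines it as a ≥2-fold increase of the summed background-subtracted
positive-marker percentages over the pre-treatment magnitude, exposes
the fold as a parameter, and records it in every report. Peptide pools
are treated as single stimuli (deconvolution is a wet-lab matter).

## IHC scoring

The immunoreactive score multiplies a binned percent-positive score
(0 = 0%, 1 = 1–10%, 2 = 11–50%, 3 = 51–80%, 4 = >80%; fractional
values in (0, 10] fall in bin 1) by staining intensity 0–3, giving
0–12. Per-case summaries are means over five high-power fields;
hot-spot selection takes the top-k regions by count with ties broken in
input order. Group comparisons use the two-sided Mann–Whitney U test:
exact distribution when both groups have at most 8 untied observations,
normal approximation with continuity correction otherwise; a fully tied
comparison (zero rank variance) reports p = 1. Marker-specific
evaluation modes (automated vs manual counting) collapse to one
arithmetic path — counts are counts, their origin is metadata.

## What the synthetic data does and does not show

The generators plant ground truth by construction: tumor ligandomes
with 20 tumor-exclusive strong binders (relative score >70%) among
~500 peptides that are otherwise shared with the references or weak
binders (≤50%), nested class I/class II pairs, variant tables with one
planted failure mode per rejected row, ICS panels whose planted effects
(3-fold over a 0.05–0.15% background, 60-cell excess) sit safely beyond
the positivity thresholds, and negative-binomial IHC counts (size 8,
group means 60 vs 30 per HPF) matching the 9-vs-7 group design. Each
generator draws from its own sub-seeded stream, so scenarios are
bit-reproducible and adding a generator never perturbs another.

Passing on these scenarios demonstrates that the filters implement
their definitions exactly — zero false positives or negatives when the
planted classes are separated from the thresholds. It does not
demonstrate robustness to what real immunopeptidomics data adds:
identification noise near the score thresholds, shared peptides missing
from incomplete benign compendia, isobaric I/L ambiguity (sequences are
taken at face value), or acquisition-size differences between ICS
wells. Problem sizes (≈500-peptide ligandomes, 10-seed recovery suites,
100-replicate power checks at n = 9 vs 7) were chosen as the smallest
scales at which the planted structure is non-trivial.

## Numerical conventions and edge cases

Half-up rounding for all reported percentages (one decimal) and means
(nearest integer); unrounded values in all comparisons. Empty inputs
propagate as valid empty results (an empty tumor set yields an all-zero
trace); a missing reference sub-set for an enabled step is a
configuration error naming the sub-set, distinguishing "absent tissue"
(disable the step) from "forgot the file". Peptides no allele can
evaluate are *unevaluable*, not non-binders, and leave the cascade at
the binder step. A substitution whose alternate equals the reference
warns and returns the protein unchanged; a reference mismatch between
variant and protein is an error, as the two inputs are out of sync.

## Known limitations

Reproducing a real patient's per-step funnel counts requires the
original raw identification data and the in-house multi-tissue benign
compendia, neither of which is redistributable; such runs are an
integration exercise for labs holding those inputs, not something the
test suite asserts. The binding model is the additive matrix itself —
no trained affinity predictor is included, only the contract for one.
Survival analysis, FDR estimation, alignment and flow-cytometry gating
are upstream/downstream of this package's scope.
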