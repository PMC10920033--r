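---
title: "Methods: conservation and acceleration scanning in conaccr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation and acceleration scanning in conaccr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`conaccr` detects two kinds of evolutionary signal in a reference-anchored
multiple genome alignment of eight *Anolis* lizards: **all-branch conserved
elements (CEs)**, windows evolving slower than neutral on every branch, and
**lineage-specific accelerated regions (ARs)**, windows evolving faster than
neutral on one chosen branch while the rest of the tree stays neutral. This
vignette documents the statistical model, the deterministic data-handling
rules, and the design decisions behind both, in the order the pipeline applies
them.

```{r setup}
library(conaccr)
```

## 1. Alignment curation

Input is a set of pairwise, reference-anchored alignments (MAF), one per
non-reference species, plus the reference-species annotation (GFF3). Four
deterministic rules turn these into clean multi-species blocks:

1. **Edge trimming.** Leading and trailing `N` runs are removed from each
   pairwise block; coordinates advance by the number of reference (non-gap)
   bases trimmed.
2. **Internal N splitting.** An internal run of `N`s longer than a
   configurable fraction (default 0.5) of *that row's own ungapped length* is
   deleted and the block split around it. Shorter runs are retained as
   missing data — the likelihood treats `N` and `-` as fully ambiguous, so
   retention is unbiased.
3. **Overlap resolution.** When two blocks of the same species pair claim
   overlapping reference intervals, the block covering more alignment columns
   wins the contested region; ties go to the block with the smaller reference
   start. The losing block is truncated, and insertion columns (reference
   gaps) always travel with the preceding reference base so no column is
   orphaned.
4. **Reference-anchored merge and species filter.** Pairwise rows with
   identical reference coordinates and compatible reference sequence are
   stacked into multi-species blocks, grouped by the exact species set and by
   contiguity; conflicting reference bases across sources are a data error,
   not silently resolved. Blocks with fewer than 7 of the 8 species are
   dropped: with fewer taxa the per-branch test loses essentially all power,
   and keeping a uniform species floor makes window p-values comparable.

## 2. Neutral model from fourfold-degenerate sites

The neutral substitution model is a GTR (optionally +Γ) fitted to
fourfold-degenerate (4D) third codon positions — sites where any base encodes
the same amino acid, the standard choice of putatively neutral proxy.

4D sites are only neutral *markers* if codon usage itself is unbiased, so the
package first computes **relative synonymous codon usage** (RSCU = k·n_c/Σn,
for a family of k synonyms) per species and flags codons with RSCU strictly
below 0.6 or strictly above 1.6 (boundary values are unflagged; the rule is
strict inequality). Only 4D families in which *no* codon is flagged in *any*
species contribute sites. A family is identified by its first two codon
bases; a column is used only when all species share that same prefix, so the
site is 4D in every genome simultaneously.

The codon-usage input (coding sequences) and the 4D alignment columns are
deliberately decoupled inputs: codon bias is a property of the annotated
transcriptome, while the 4D columns come from the genome alignment. The
synthetic generator mirrors this by emitting per-species CDS FASTAs with a
controllable codon bias alongside the alignment.

**Fitting.** `fit_neutral_model()` maximises the likelihood by coordinate
sweeps: branch lengths one at a time (Brent), then the five free
exchangeabilities (G↔T fixed at 1 for identifiability), then the base
frequencies (softmax parameterisation), repeating until the log-likelihood
improves by less than `tol`. The rate matrix is renormalised to one expected
substitution per site after every parameter move, so branch lengths stay in
substitution units.

## 3. Likelihood machinery

Likelihoods use Felsenstein's pruning algorithm with three numerical
choices worth recording:

- **Symmetrised eigendecomposition.** The GTR generator `Q` is similar to the
  symmetric matrix `diag(√π) Q diag(1/√π)`, so `P(t) = exp(Qt)` is computed
  from a real symmetric eigendecomposition — stable and reusable across the
  thousands of branch lengths visited during optimisation.
- **Per-node rescaling.** Partial likelihood vectors are renormalised at each
  internal node with the log of the scale accumulated separately, so windows
  of any length avoid underflow.
- **Site-pattern compression.** Identical alignment columns are collapsed to
  unique patterns with counts before any optimisation; a per-window scan
  re-optimises the same patterns dozens of times, so this dominates the
  constant factor.

Ambiguity (`N`, `-`, IUPAC codes mapped to `N` on read) enters as a tip
partial vector of ones, the exact marginalisation. Rate variation uses the
discrete-gamma approximation with category means computed by the
incomplete-gamma (mean-of-bin) formula.

The root sits at the ape-numbered node `ntip+1` and the model is reversible,
so the likelihood is independent of root placement (verified against a
brute-force enumeration oracle in the tests); no separate root-edge
parameter exists — any rate change on the two root-adjacent edges is
absorbed into their shared path, which is why the internal test branch
`TC_open` is defined as the stem of the Cuban trunk-crown clade rather than
a root edge.

## 4. Window construction and annotation

Curated blocks are cut at annotation boundaries into segments with a single
category, using the priority **CDS > 5′UTR > 3′UTR > intron > intergenic**
when transcripts overlap; a base inside a gene span but in no exon-level
feature is intron, and exons of non-coding RNAs rank as intron. A base in
the CDS of two genes keeps both gene IDs.

Segments become test windows by exact rules: segments shorter than 10
reference bases are dropped; 10–99 bases are one window; segments of ≥100
bases are split into 60-base windows from the left, with a final remainder
of fewer than 20 bases merged into the previous window (130 → 60 + 70;
139 → 60 + 79; 140 → 60 + 60 + 20; 315 → 60 × 4 + 75). A window is testable
only if at least two species have a non-ambiguous base in some column.

## 5. The conservation/acceleration test

For each window the scan fits, by bounded one-dimensional likelihood
maximisation on [10⁻⁶, 100]:

- a **global scale** ρ multiplying every branch (conservation test), and
- a **branch scale** λ multiplying one target branch with the rest of the
  tree fixed at neutral (acceleration test), for each of the eight target
  branches (the seven ingroup tips and the internal branch `TC_open`).

Each fit yields `T = 2(lnL₁ − lnL₀)` against the neutral model. Because the
null value (scale = 1) is interior but the alternative is one-dimensional,
the two-sided null distribution of T is χ²₁; the package wants *directional*
p-values, so it sets `p_dir = ½·P(χ²₁ ≥ T)` and assigns

- `p_cons = p_dir` if the fitted scale < 1, else `1 − p_dir`, and
  symmetrically
- `p_acc = p_dir` if the fitted scale > 1, else `1 − p_dir`.

This construction makes `p_cons + p_acc = 1` within a test, both equal to
0.5 at T = 0, and each marginally uniform under the null (the ½χ²₀ + ½χ²₁
boundary mixture folded into a direction), which the calibration tests
verify empirically. The **CONACC score** is the signed transform
`−log10(p_cons)` when conservation is favoured and `+log10(p_acc)`-signed
negative when acceleration is favoured, so positive scores mean
conservation.

**Multiple testing.** Benjamini–Hochberg correction is applied within
families: one family for all-window conservation p-values, and one family
per target branch for acceleration p-values. Elements are called at
`q < 0.05` (strict inequality). The worked BH example
`c(0.01, 0.02, 0.04) → c(0.03, 0.03, 0.04)` is pinned in the tests.

## 6. Downstream genomics

- **Gene association.** An AR in CDS/UTR is assigned to its host gene
  directly. An AR in an intron or intergenic window must overlap an
  all-branch CE by at least one base (half-open intervals — touching
  endpoints do not count) before association, since acceleration is only
  interpretable against prior constraint there. Intergenic ARs associate
  with genes whose strand-aware 5-kb flanks they overlap.
- **ncRNA filter.** A window counts as ncRNA-overlapping only if strictly
  more than 80% of its bases fall inside the union of ncRNA exons (49 of 60
  passes, 48 of 60 does not).
- **Enrichment.** One-sided Fisher tests (hypergeometric tail, odds ratio
  ad/bc) ask whether AR base content is ncRNA-enriched relative to the
  aligned background. Two backgrounds are supported: **exclusive** (the
  2×2 table contrasts the set against the background *minus* the set — the
  default, since the set is part of the genome-wide totals) and
  **inclusive** (set vs the full background as given). Habitat-matched
  lineage pairs (`hot_open` = `TC_open` + *A. sagrei*; `cool_shaded` =
  *A. isolepis* + *A. allogus*) are intersected for commonly accelerated
  genes, flagging whether the two lineages hit the same window.

## 7. Synthetic data generator

`region_plan()` + `generate_dataset()` produce an eight-taxon dataset with
known truth: neutral, conserved (default scale 0.1) and accelerated (default
scale 10, one target branch) regions placed without overlap on a reference
chromosome, written as MAF + GFF3 + truth BED. Sequences are simulated
column-by-column from the same GTR machinery used for inference (sampling a
root state from π and evolving along the tree), so generator and fitter
share no code path with the test statistics themselves — the brute-force
oracle in the test suite is the independent check on the likelihood.

`inject_artefacts()` adds the pathologies the curation stage must fix (N
runs, duplicated overlapping blocks, dropped species), and
`generate_biased_codon_data()` emits CDS sets whose RSCU hits requested
per-codon targets, for exercising the 4D-family selection.

**Realism limits.** Columns are i.i.d. given the region class: no indel
process (gaps only arise from injected artefacts), no CpG or context
effects, no rate autocorrelation along the sequence, and conserved regions
are uniformly scaled rather than profile-constrained. These are adequate for
calibration (the null is exactly the fitted model class) and for sensitivity
benchmarks, but synthetic power estimates will be optimistic relative to
real genomes.

## 8. Problem sizes and costs

A single window fit is a bounded 1-D optimisation, each evaluation costing
O(patterns × branches × 16) after compression; on one CPU the scan runs on
the order of 100 global fits per second at 60-base windows. The per-branch
scan multiplies this by the number of target branches (8). Neutral-model
fitting on 20,000 4D sites (the default in the analysis workflow) takes a
few minutes because each sweep re-optimises 14 branch lengths, 5
exchangeabilities and 3 free frequencies. The brute-force test oracle
enumerates 4^(internal nodes) state assignments and is only feasible for the
3–5-taxon trees used in tests.

## 9. Running the full pipeline

`run_pipeline(pipeline_config(...))` chains every stage (optionally from
simulated data) and writes windows, scan results, calls (TSV + BED), gene
associations, and a JSON report; `read_pipeline_config()` loads the same
configuration from YAML. The numbered scripts under `analysis/` run the
identical stages as separate reproducible steps writing into `results/`.
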