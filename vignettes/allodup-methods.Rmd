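---
title: "Methods: duplicate-gene fates, cis/trans divergence and methylation in allopolyploids"
author: "allodup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplicate-gene fates, cis/trans divergence and methylation in allopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allodup)
```

This vignette documents the models behind each stage of the package, the
tunable parameters and their defaults, what the synthetic-data
generators do and do not emulate, and the numerical and design choices
that were genuinely open.

## Expression preprocessing

Expression matrices (genes by the four tissues stem, leaf, flower,
silique) enter on a raw FPKM/TPM scale and carry an explicit scale flag;
`log_transform()` maps every value to `log2(v + 1)` and refuses to run
twice. Two filters precede any classification:

* genes with `log2(FPKM + 1) < 1` in **all** tissues are removed, as
  expression at that level is indistinguishable from transcriptional
  noise. The comparison is strict, so a gene with one value exactly 1
  survives;
* duplicate triples whose synonymous divergence satisfies `Ks >= 3` are
  removed (substitution saturation), again with a strict boundary;
  triples with no Ks entry are removed too and counted separately —
  a saturation criterion cannot be evaluated on a missing value.

The low-expression filter runs before triples are paired; any triple or
ortholog pair with a filtered member is dropped with a logged count,
since a distance against a missing profile is undefined.

## Duplicate-fate classification

The classifier works entirely in expression space. For a single-copy
ortholog pair the Euclidean distance between the two species'
log-profiles measures the expression divergence expected from speciation
alone; `E_div` is the empirical `q`-quantile of those distances
(`stats::quantile` type 7, i.e. linear interpolation). The default
`q = 0.90` operationalizes "expected interspecies divergence"
generously: only the top decile of single-copy divergence counts as
evidence of functional change. `q` is configurable, a user-supplied
`E_div` overrides selection entirely, and the chosen value is recorded
in every result object and run manifest. At least 30 single-copy
distances are required (configurable floor); below that the empirical
quantile is too unstable and the caller must supply the cutoff.

Each triple then contributes three distances to the ancestral profile:
parent `E_P,A`, child `E_C,A`, and combined `E_P+C,A`, where the
combined profile sums the two copies on the **raw** scale and re-logs
(`log2(2^p + 2^c - 1)`): transcript abundance of a merged P+C unit is
additive in molecules, not in log space. The four rules (conserved /
neofunctionalized with the diverged copy named / subfunctionalized /
specialized) are exhaustive and mutually exclusive by construction;
ties at the cutoff count as "within E_div", i.e. toward conservation.

Numerical choice: distances are compared to `E_div` with an absolute
tolerance of 1e-9. In the degenerate noiseless limit all single-copy
distances are 0, hence `E_div = 0`, and the re-logged combined profile
reconstructs the ancestral values only to float precision (~1e-16);
without the tolerance such round-off would flip subfunctionalized calls
to specialized at the boundary.

## Tissue specificity and divergence correlations

`tau(x) = sum(1 - x_i/x_max) / (n - 1)` is the standard
tissue-specificity index: 0 for uniform expression, 1 for single-tissue
expression, invariant under positive rescaling, undefined (an error) on
all-zero profiles. It is computed on the same log2(x+1) profiles the
distances use; this is configurable by simply passing raw rows instead.

Correlations of expression divergence with Ka, Ks, Ka/Ks and tau are
Pearson product-moment coefficients with two-sided t-distribution
p-values (n − 2 df). Records missing a covariate are dropped from that
covariate's row only (pairwise-complete, mirroring per-panel sample
sizes), never listwise; covariates left with fewer than 3 complete
records, or with zero variance, are reported as NA with the reason.

## Cis/trans regulatory divergence

For each homoeolog pair, `A = log2(A/C)` from the progenitor-mix counts
confounds cis and trans divergence; `B = log2(An/Cn)` inside the
allopolyploid isolates cis effects because both homoeologs share one
trans environment; `A - B` is the trans component. Ratios are computed
on replicate-summed counts with a pseudocount (default 0.5 per side) so
zero counts cannot produce infinities; per-replicate log ratios are
retained for the trans test. A library-size toggle (default on) rescales
every compartment x replicate library to the mean depth before ratio
computation, mirroring the depth-matching of an in-silico progenitor mix
to the allopolyploid libraries.

Three hypotheses are tested per pair and BH-adjusted across pairs at
FDR < 0.05 (configurable):

* `A != 0` and `B != 0`: a two-sided exact binomial test of the pooled
  counts against 0.5, with both sides deflated by the common factor
  `1 + phi * h` (`h` = harmonic mean of the two replicate-mean counts,
  `phi` = common negative-binomial dispersion estimated across all pairs
  by a method-of-moments average). The deflation preserves the observed
  proportion while shrinking the total to the information biological
  replicates actually carry: the deflated totals reproduce the NB
  log-ratio variance `(1/R)(1/m_x + 1/m_y + 2 phi)`. With `phi = 0` the
  plain exact binomial test is recovered; externally computed p-values
  (e.g. from a dedicated differential-expression tool) can be
  substituted by bypassing `call_cis_trans()` and feeding
  `assign_category()` directly.
* `A != B`: Student's two-sample t-test (pooled variance) on the
  per-replicate log ratios. Pooled rather than Welch because the two
  ratio variances are equal by construction under the count model and,
  at the usual 3-vs-3 replication, Welch's random degrees of freedom
  (as low as ~2.2) cost substantial power. Zero-variance degenerate
  inputs are resolved deterministically: identical constant ratios give
  p = 1, different constants p = 0.

The seven categories are a pure function of the three significance flags
plus the signs of B and trans. The scheme (I cis-only, II trans-only,
III enhancing, IV opposing, V compensatory, VI conserved, VII ambiguous,
with VII also absorbing untestable pairs) is the classical
allele-specific-expression classification; the package fixes it
explicitly because category labels I–VII alone do not determine it.

## Methylation profiling

Expression classes use FPKM cutpoints `non < 0.001`,
`0.001 <= low <= 5`, `5 < medium <= 50`, `high > 50` — "between x and y"
read as closed intervals, "above" as strict; the boundary rule lives in
one function (`classify_expression`) so it can be audited or changed in
one place.

Region levels are coverage-weighted pools `sum(m)/sum(t)` over the
cytosines of the requested context inside the region — weighting by
reads rather than averaging per-site fractions makes the estimate robust
to coverage variation. Promoters are the 2 kb upstream of the TSS and
downstream regions the 2 kb past the TES, both strand-aware; regions
running past the chromosome start are truncated at position 1 with a
logged count. A level is reported only when at least `min_sites`
(default 3) covered cytosines support it.

Meta-gene profiles use 20 fixed 100-bp bins per 2-kb flank and 40
proportional gene-body bins (all configurable); genes shorter than one
bp per body bin are excluded and counted. Bins are indexed along the
transcription direction, which makes profiles invariant under
mirror-imaging the genome — a property the test suite checks directly.
Contexts (CG/CHG/CHH) can be profiled separately or combined.

## Generational transmission

A homoeolog pair's bias state in one generation is `A_eq_C` when its
divergence test is non-significant (`q >= alpha`, default 0.05), else
`A_gt_C`/`A_lt_C` by sign. The 3x3 parental-by-progeny grid is
enumerated as patterns I–IX with group A (I–III) the three diagonal
"parental legacy" cells, group B (IV–V) the two cells where a parental
bias relaxes to balance, and group C (VI–IX) the four cells where the
progeny shows a bias the parents did not (gained or reversed). The
numbering is fixed by the group structure and emitted with every output
so results are self-describing. The same machinery runs on expression
and on region-methylation divergence q-values; the package does not
prescribe which upstream test produced them.

## What the generators emulate — and what they do not

Each `simulate_*` function draws everything from one mandatory seed and
returns a truth table aligned by id; fixed seed means byte-identical
output.

`simulate_fate_dataset` models log2 expression as per-gene, per-tissue
baselines (uniform 2–8) plus Gaussian lineage drift (`noise_sd = 0.25`
per branch). Single-copy orthologs drift independently along both
lineages, so their interspecies distances — the E_div calibration set —
have per-tissue SD `noise_sd * sqrt(2)`. Duplicate copies whose
ancestral expression role is retained (conserved copies, the
non-diverged neofunctionalization copy, subfunctionalized split halves)
drift at `noise_sd * conserved_noise_factor` (default 0.5): functional
conservation of expression is not a neutral outcome but the signature of
stabilizing selection, so retained-function copies track the ancestral
profile more tightly than neutrally drifting single-copy genes.
Diverged copies carry full drift plus a `divergence_offset` (default
1.5, i.e. ~3x the conserved-copy noise) in a random 1–3 tissue subset.
Subfunctionalization splits the ancestral raw profile over complementary
tissue subsets so the raw parent+child sum equals the ancestor exactly
at zero noise. A separate `null_mode` makes all duplicates behave
exactly like single-copy genes (two-branch drift, no offsets, no
stabilizing selection); under it the fraction of copies within E_div
approximates `q` by construction, which is the calibration property the
tests check.

`simulate_count_dataset` draws negative-binomial replicate counts
(dispersion 0.05, 3 replicates, ~1e6 reads per library) around per-pair
cis/trans log2 effects whose magnitudes are uniform on 1.5–3 — strong
but variable effects, rather than a degenerate all-at-the-boundary
design. `noiseless = TRUE` emits rounded expected counts for
deterministic-limit checks.

`simulate_methylome` plants a flank/body methylation landscape
(binomial calls at fixed coverage over evenly spaced cytosines) with
per-expression-class body levels; the default genome is 4 Mb because
500 non-overlapping loci of 2 kb + body + 2 kb plus spacing need about
3 Mb, and the generator refuses genomes that cannot hold the requested
loci rather than silently overlapping flanks into neighbouring bodies.
`simulate_gbm_dataset` instead plants a continuous joint distribution of
body methylation and log-expression with an exact population Pearson
correlation (affine construction on a bivariate-normal driver).

None of the generators emulate: read-level data or mapping artefacts,
chromosomal structure (linkage, centromeres, real gene density),
context-specific methylation differences, expression correlation between
neighbouring genes, or dosage responses after polyploidy. Passing the
planted-recovery tests therefore demonstrates that the inference
machinery is correct and calibrated under its stated model — not that
the model captures every property of real allopolyploid data.

## Problem sizes and runtime

The shipped checks run the fate classifier on 2000 single-copy pairs +
400 triples (and 5000 triples for null calibration), the cis/trans
caller on 1000 pairs x 3 replicates, the meta-gene profiler on 500 loci
(~125k cytosine calls), the methylation–expression association on 1000
genes, and the transmission classifier on 10000 pairs; the full
pipeline plus all checks completes in about a minute on one CPU. These
sizes were chosen so each recovery estimate has sampling error well
below its acceptance margin.

## Known limitations

* Which copy of a WGD pair is "parent" and which "child" is taken from
  the input triple table as-is; the classifier itself is symmetric up to
  relabelling of the two neofunctionalized calls.
* Ka/Ks values are consumed, never computed; the table is keyed by the
  child (duplicate) gene id.
* The binomial divergence test assumes a single common dispersion across
  pairs; strongly gene-specific dispersions would need an external
  count-model test, which can be plugged in via `assign_category()`.
* Meta-gene profiles weight every covered cytosine by its reads;
  unweighted per-site averaging is not currently exposed.
* DEG discovery, differentially-methylated-region calling, GO
  enrichment and alternative-splicing quantification are out of scope.
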