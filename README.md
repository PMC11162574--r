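# allodup

Analysis of duplicated-gene evolution in an allopolyploid and its two
diploid progenitors, from multi-tissue expression, homoeolog read counts
and whole-genome bisulfite methylation calls. The package implements, as
tested reusable functions, the full chain an allopolyploid
duplicate-gene study needs:

1. **Duplicate-fate classification.** For each duplicate triple
   (ancestral gene *A* in the reference genome; parent *P* and child *C*
   copies in the duplicate-bearing genome) the Euclidean distances
   between log2(FPKM+1) expression profiles over four tissues (stem,
   leaf, flower, silique) are compared against a cutoff *E_div*, the
   empirical *q*-quantile (default 0.90, linear interpolation) of the
   distances between single-copy ortholog pairs:

   - conserved: `E_P,A <= E_div` and `E_C,A <= E_div`
   - neofunctionalized: exactly one copy exceeds `E_div`
     (the diverged copy is named in the call)
   - subfunctionalized: both exceed `E_div`, but the combined P+C
     profile (raw-scale sum, re-logged) does not: `E_P+C,A <= E_div`
   - specialized: all three distances exceed `E_div`

   Calls are cross-tabulated against the five duplication types
   (WGD, TD, PD, DSD, TRD).

2. **Divergence statistics.** The tissue-specificity index
   `tau = sum(1 - x_i/x_max) / (n - 1)` (0 = uniform, 1 = single-tissue),
   and Pearson correlations of expression divergence with Ka, Ks, Ka/Ks
   (consumed as a precomputed table) and tau, with pairwise-complete
   handling of missing covariates.

3. **Cis/trans regulatory divergence.** From replicate homoeolog read
   counts in an in-silico progenitor mix and in the allopolyploid:
   `A = log2(A/C)` (cis + trans), `B = log2(An/Cn)` (cis, shared trans
   environment), trans `= A - B`. Three FDR-controlled tests (A != 0,
   B != 0 via an overdispersion-corrected exact binomial test; A != B
   via Student's t-test on replicate log ratios; Benjamini-Hochberg,
   FDR < 0.05) route each pair into one of seven categories:
   I cis-only, II trans-only, III enhancing, IV opposing,
   V compensatory, VI conserved, VII ambiguous.

4. **Methylation profiling.** Genes are classed non/low/medium/high by
   FPKM (cutpoints 0.001, 5, 50); coverage-weighted methylation levels
   are computed per region (2 kb promoter, gene body, 2 kb downstream,
   strand-aware) and as class-stratified meta-gene profiles in aligned
   bins around TSS and TES; gene-body methylation is tested for its
   negative correlation with expression.

5. **Generational transmission.** Homoeolog bias states
   (A>C / A=C / A<C, from an FDR-adjusted divergence test) in the
   progenitor generation versus the allopolyploid define nine patterns
   in three groups: A = parental legacy (state inherited),
   B = parental bias lost, C = novel bias.

Every input the pipeline consumes can be simulated with planted ground
truth (`simulate_*` functions), so the whole chain is testable without
any external data.

## Worked example

```r
library(allodup)

sim <- simulate_fate_dataset(20, n_single = 2000, n_per_fate = 100)
res <- fate_analysis(log_transform(sim$expr_ref),
                     log_transform(sim$expr_dup), sim$pairs)
res
#> fate_result: 400 triples, E_div = 0.9852 (q = 0.9)
#>                 conserved neofunctionalized(parent)  neofunctionalized(child)
#>                       101                        49                        51
#>         subfunctionalized               specialized
#>                       100                        99
```

`E_div = 0.985` is the 90th percentile of the 2000 single-copy ortholog
distances; with the generator's default noise (per-tissue log2 SD 0.25)
and divergence offset (1.5), 99.5% of the 400 planted fates are
recovered. The same objects feed the duplication-type cross-table
(`fate_by_dup_type(res)`).

```r
sc <- simulate_count_dataset(20, n_pairs = 1000)
cc <- call_cis_trans(sc$counts)
category_summary(cc)
#>   category   n proportion
#> 1        I 175      0.175
#> 2       II 143      0.143
#> 3      III 162      0.162
#> 4       IV 179      0.179
#> 5        V 151      0.151
#> 6       VI 155      0.155
#> 7      VII  35      0.035
attr(cc, "dispersion")
#> [1] 0.049
```

The six planted categories (~167 pairs each) are recalled almost
one-for-one; the estimated common negative-binomial dispersion (0.049)
matches the generator's 0.05. `run_all(list(outdir = "out", seed = 1))`
executes all five stages end to end and writes each stage's TSV tables
plus a JSON manifest; reruns with the same seed are byte-identical.

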