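# threedfunc

Tools for relating genetic variants to three-dimensional genome
organization. The package is aimed at regulatory-genomics analysts who
have Hi-C contact matrices, variant calls (interchromosomal
translocations, structural variants, SNPs) and matched expression data,
and who want to (a) quantify the 3D contact between two loci robustly
across matrix resolutions, (b) annotate which layer of 3D organization a
variant disrupts, and (c) rank variant–gene pairs by how anomalous their
expression change is given their change in 3D contact.

## The statistics at the core

**Flexible interaction frequency.** For candidate regions
`C_a = [S_a, E_a)` and `C_b = [S_b, E_b)`, each region is matched to the
stored resolution nearest its length (`R_a`, `R_b`), contacts are
queried at the window `W_ab = min(R_a, R_b)`, and the statistic is the
containment ratio

    FlexibleIF = IF(S_a:E_a, S_b:E_b, W_ab) / IF(S'_a:E'_a, S'_b:E'_b, W_ab)

where the background regions extend each side by its resolution times
the extension coefficient `alpha = max(R_a,R_b)/min(R_a,R_b)`
(`S'_a = S_a − R_a·alpha`, `E'_a = E_a + R_a·alpha`, analogously for
`b`), clamped to the chromosome. The value lies in `[0, 1]`.

**Expression change (EC).** The lower-tail Welch *t* CDF comparing a
gene between cancer and normal samples:
`EC = P(T < (Ē_C − Ē_N) / sqrt(S_C²/n_c + S_N²/n_n))`, with
Welch–Satterthwaite degrees of freedom. EC ≈ 1 means up-regulated in
cancer.

**3DFunc score.** With `IC = |C_i − N_i|` (cancer vs normal flexible
IF), pairs are fitted per cell line to the exponential decay
`EC = A·exp(−IC/τ)` by bounded nonlinear least squares; each pair's
score is `|expected EC − observed EC|`, its significance a 1-df
chi-square on the variance-standardized residual, and pairs are ranked
by descending score.

Rule-based classifiers cover the other layers: SV filtering
(10 kb–10 Mb, frequency > 1%), compartment disruption (`A-A`, `A-B`,
`B-A`, `B-B` from the breakpoint labels), TAD disruption (`intra-TAD`,
`inter-TAD1/2/3`, with a 50%-of-local-TAD-size exclusion), fusion-pair
merging (unordered, deduplicated, `high_frequency` at count > 10),
SNP-to-gene loop mapping (±1 kb extension), loop classes (`CSL`/`OL`/`NSL`
by cancer-SNP content across tissues; `EP` > `CTCF` > `other` with E–P
priority) and coding/noncoding SNP annotation (CDS or within 10 bp of a
splice site).

## Worked example

Everything below runs on simulated data generated by the package itself
(a distance-decay contact matrix with planted compartments, TADs, loops
and fusion hotspots, plus variant–gene pairs drawn on a known decay
curve with 5% planted outliers):

```r
library(threedfunc)
library(dplyr)

cfg <- sim_config(seed = 1, chrom_sizes = c(chrS1 = 1.2e6, chrS2 = 1e6),
                  resolutions = c(10000, 50000), n_genes = 60)
store <- gen_hic(cfg)
truth <- gen_variant_truth(cfg)

# flexible IF between a planted loop's anchors
lp <- truth$loops[1, ]
flexible_if(store, region(lp$chromA, lp$startA, lp$endA),
            region(lp$chromB, lp$startB, lp$endB))[
  , c("Ra", "Rb", "Wab", "alpha", "core_if", "extended_if", "flexible_if")]
#>      Ra    Rb   Wab alpha core_if extended_if flexible_if
#> 1 10000 10000 10000     1    20.4        23.5       0.870

# fit the EC ~ IC decay and score the pairs
fit <- fit_ec_ic(truth$score_pairs)
glance(fit)
#>       A   tau   rss residual_sd n_points converged
#> 1 0.869 0.563  1.60      0.0899      200 TRUE

scored <- score_pairs(fit, truth$score_pairs, force = TRUE) |>
  score_significance(fit)
evaluate_ranking(scored, truth$score_pairs$causal)
#>       n n_causal top_decile_causal_fraction auroc auprc
#> 1   200       10                        0.5     1     1
```

Reading the numbers: both loop anchors are 10 kb, so both match the
10 kb resolution (`alpha = 1`) and the planted loop concentrates 87% of
the background window's contact in the core rectangle. The decay fit
recovers parameters close to the generating curve (A = 0.9, τ = 0.5),
and every one of the 10 planted outlier pairs ranks above every
unperturbed pair (AUROC = 1); the top decile holds 20 pairs, so the
10 planted outliers fill half of it.

A full pipeline run (`run_pipeline()`, or the CLI in
`inst/cli/threedfunc.R`: `simulate`, `flexif`, `v4c`, `run`) writes one
TSV plus a JSON run log per stage and is byte-identical when repeated
with the same configuration.

## Native contact-store format

One JSON manifest (`chrom_sizes`, `resolutions`, `files`) plus one
whitespace-delimited COO file per resolution with columns

    chromA  binA  chromB  binB  value

— bin indices are 0-based at that resolution, values are normalized
non-negative contacts, and each unordered bin pair appears once
(symmetry is implied). Matrices are assumed balanced upstream. FPKM-UQ
normalization divides by the per-sample 75th percentile of nonzero gene
counts instead of the library total, so its values sit on a much larger
scale than FPKM; only within-normalization comparisons are meaningful.

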