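# satseq

**Sequencing-depth saturation analysis for 3′ mRNA-Seq molecular
phenotyping.**

Population-scale genetics programs need phenotypes that are cheap to
measure at scale. Gene expression from 3′ mRNA-Seq of easy-to-collect
tissue (e.g. whole blood) is a promising proxy phenotype: each
transcript contributes a single poly-A-proximal read, so counts need no
gene-length normalization and useful expression profiles can be
obtained at a fraction of whole-transcriptome depth. The practical
question is *how deep to sequence*: every extra million reads per
sample multiplies across thousands of animals, while too few reads miss
genes, differential-expression signal and the intragenic variants that
enable genotype imputation.

`satseq` answers the question for a given dataset by serial
downsampling. Full-depth gene-by-sample counts are thinned without
replacement (the count-level equivalent of read subsampling — exactly
multivariate hypergeometric) to a ladder of depths with replicate
seeds; at each depth the package recomputes

- **expressed genes** (count ≥ 1),
- **informative genes** (count ≥ 10 in ≥ 50% of samples),
- **DEGs** (two-group negative-binomial Wald test, BH-adjusted p < 0.05),
- optionally **variant survivors** of depth-based hard filters from a
  called VCF,

benchmarks each set against the full-depth truth set with

```
Precision = TP / (TP + FP),  Recall = TP / (TP + FN),
F = TP / (TP + (FP + FN) / 2),
```

and fits the asymptotic regression model

```
y = ymax + (y0 − ymax) · exp(−exp(lrc) · x)
```

to the set sizes, where `ymax` is the asymptote, `y0` the response at
zero depth and `lrc` the log rate constant. The **saturation depth** is
the closed-form point where the fitted slope drops to a marginal-gain
threshold (default 1e-4: one more gene per 10,000 extra reads):

```
x_plateau = −( ln(−t / (y0 − ymax)) − lrc ) / exp(lrc)
```

The package also ships the post-calling variant stages used alongside
the expression metrics: GATK-style site hard filters (QD/FS/MQRankSum/
ReadPosRankSum/SOR), the lenient (`DP_total ≥ 10` with alt support) and
stringent (per-allele `AD ≥ 2` or `AR ≥ 0.1 & DP > 10`, recalculated
depth ≥ 5) criteria, intragenic classification against a GFF3/GTF
annotation, strand-aware 5′→3′ gene-body position histograms, and
known-site overlap. Synthetic-data generators for counts, saturation
observations, gene models and variant records make the whole pipeline
testable without external data.

## Worked example

```r
library(satseq)

# a study-scale synthetic dataset: 4,000 genes, 27 samples in two
# conditions, 2M reads/sample, 400 true DE genes
sim <- simulate_counts(n_genes = 4000, n_samples_per_condition = c(14, 13),
                       depth_per_sample = 2e6, n_de_genes = 400, seed = 1)

nb_de(sim$counts, sim$condition)
#> <nb_de> 3953 tested genes: 235 DE at FDR 0.05 (117 up, 118 down); 47 untested

report <- run_saturation(sim$counts, condition = sim$condition,
                         depths = c(0.1, 0.2, 0.4, 0.7, 1, 1.4, 1.8) * 1e6,
                         master_seed = 1)
report
#> <saturation_report> 3 metrics x 7 depths x 10 seeds
#> # A tibble: 3 × 9
#>   metric         y0  ymax   lrc residual_sse saturating x_plateau y_at_plateau
#>   <chr>       <dbl> <dbl> <dbl>        <dbl> <lgl>          <dbl>        <dbl>
#> 1 degs         109.  237. -13.3        1868. TRUE         445818.         174.
#> 2 expressed   3023. 3930. -12.7       20951. TRUE        1120397.        3896.
#> 3 informative 1038. 2120. -13.3       40075. TRUE        1744364.        2060.
```

Reading the `expressed` row: detection rises from ~3,000 genes toward
an asymptote of ~3,930 and flattens to the one-gene-per-10k-reads rate
at **1.12M reads/sample**, where ~3,896 genes (99% of the asymptote)
are already captured. Sequencing to the full 1.8M reads would add only

```r
fit <- report$fits[report$fits$metric == "expressed", ]
marginal_gain(list(y0 = fit$y0, ymax = fit$ymax, lrc = fit$lrc),
              fit$x_plateau, 1.8e6)
#> [1] 29.3
```

about 29 more genes. `tidy(report)` returns the per-(metric, depth,
seed) precision/recall/F table, `autoplot(report)` draws the replicate
points, fitted curves and plateau dots, and
`write_saturation_report(report, dir)` emits diff-able TSV/JSON.

The informative-gene curve plateaus later than the expressed-gene curve
(1.74M vs 1.12M here): stabilizing a 10-read threshold in half the
samples needs more depth than touching a gene once — the same ordering
the method reports on real whole-blood data.

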