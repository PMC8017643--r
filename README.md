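# txenrich

Bulk RNA-seq studies of disease models often ask one question in several
tissues at once: which transcriptional programs are disrupted, and which of
those disruptions are *shared* across brain regions and ages? `txenrich`
implements that transcriptome-to-enrichment workflow as a tested, reusable R
package — from raw gene counts to disease-set enrichment and qPCR
validation — for analysts who want every stage scriptable, seeded and
checkable against ground truth.

## What the pipeline computes

Given an integer count matrix (genes × samples) with genotype/age/region
annotations, for each region × age stratum:

1. **Low-count filtering** — a gene is excluded when it has fewer than
   `min_count` (10) reads in at least `min_samples` (10) samples, applied
   once across the full sample set.
2. **TMM normalization** — per-sample scaling factors from the trimmed mean
   of M-values: against a reference sample, `M_g = log2((y_gj/N_j)/(y_gr/N_r))`
   over genes expressed in both, doubly trimmed (30% on M, 5% on A), averaged
   with inverse delta-method-variance weights, rescaled to geometric mean 1.
   Expression is then `logCPM = log2((y + 0.5)/(N·f + 1)·10⁶)`.
3. **Precision-weighted DE** — per-gene linear models on logCPM with
   voom-style observation weights (a lowess trend of √(residual SD) against
   average log-expression, predicted at each fitted value and raised to the
   −4th power), empirical-Bayes variance moderation
   `s̃²_g = (d₀s₀² + d_g σ̂²_g)/(d₀ + d_g)`, moderated t on `d₀ + d_g` df,
   Benjamini–Hochberg adjustment, and DE calls at `|log2FC| > 0.585` and
   adjusted `p < 0.05`.
4. **Ranking** — genes ordered by `−log₁₀(p) · sign(log2FC)` (RNK export).
5. **Gene-set hygiene** — GMT collections deduplicated by pairwise Jaccard
   coefficient: exact duplicates collapse, and of any pair with `J > 0.8` the
   larger set survives; optional mouse→human ortholog mapping of the
   collection.
6. **Pre-ranked GSEA** — from-scratch weighted running-sum enrichment score,
   a gene-permutation null (antithetic rank-mirrored pairs), sign-preserving
   NES, and a sign-stratified permutation FDR; sets are selected at
   `FDR q < 0.05` and `|NES| > 1.4`.
7. **Shared signatures** — Venn-region tables of up/down DE genes across all
   stratum combinations.
8. **qPCR validation** — endogenous-control selection by raw-Ct stability,
   geometric-mean reference Ct, ΔCt, and equal-variance t-tests with BH
   correction (ΔΔCt = −1 ≈ a 2-fold increase).

A negative-binomial simulator (`sim_spec()`, `simulate_counts()`,
`simulate_enrichment_study()`, `simulate_ct_table()`,
`simulate_ortholog_map()`, `simulate_study()`) generates all of these inputs
with known ground truth, so every stage has a parameter-recovery test
surface.

## Worked example

```r
library(txenrich)

spec <- sim_spec(n_genes = 2000, de_fraction = 0.06, de_log2fc = 1, seed = 42)
sim  <- simulate_counts(spec)          # 120 genes planted at |log2FC| = 1
cm   <- filter_low_counts(sim$cm)
cm
#> count_matrix: 1948 genes x 12 samples
#> annotations: genotype

fit <- de_fit(cm)                      # TMM -> logCPM -> voom -> eBayes -> BH
fit
#> de_fit: 1948 genes; transgenic vs control -> 33 up, 32 down
summary(fit, n = 5)
#> Top 5 genes by p-value:
#>   gene    logFC    t_mod            p        adj_p is_de
#>  g0184 1.691347 7.213802 2.884503e-07 0.0005619012  TRUE
#>  g1071 1.484737 6.788054 7.455233e-07 0.0007261397  TRUE
#>  g0736 1.509522 6.463206 1.562754e-06 0.0010147480  TRUE
#>  g0599 2.138487 6.253020 2.540176e-06 0.0012370657  TRUE
#>  g1243 1.431257 6.145650 3.262203e-06 0.0012709544  TRUE
```

The 65 called genes are almost all planted ones: the thresholds trade
sensitivity (~0.6 at n = 6 per group) for a low false-discovery proportion
(~0.03). Enrichment on a collection with 10 planted and 90 null sets:

```r
st  <- simulate_enrichment_study(sim_spec(n_genes = 2000, seed = 42))
f2  <- de_fit(filter_low_counts(st$cm))
res <- run_gsea(f2$ranked, st$collection, gsea_config(n_perm = 1000, seed = 42))
res
#> gsea_result: 100 sets tested, 10 selected (q < 0.05 , |NES| > 1.4 )
#>   set_name size_used    ES   NES p_nominal fdr_q selected
#>  planted09        38 0.899 2.448   0.00194 0.000     TRUE
#>  planted05        38 0.883 2.403   0.00194 0.000     TRUE
#>  ...
```

All ten planted sets are selected at `q < 0.05`, `|NES| > 1.4`; no null set
is. The full multi-stratum pipeline (counts → DE per region × age → GSEA →
shared-gene report → qPCR) runs from one YAML config:

```sh
exec/txenrich pipeline --config config.yaml
```

and writes per-stratum `genestats_*.tsv`, `ranked_*.rnk`, `gsea_*.tsv`,
`shared_up.tsv`/`shared_down.tsv` and a deterministic `manifest.yaml`;
re-running the same config reproduces the outputs byte for byte.

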