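---
title: "Methods: from counts to shared enrichment signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from counts to shared enrichment signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txenrich)
```

`txenrich` implements a complete transcriptome-to-enrichment analysis for
two-genotype designs measured across several tissues and ages: count
filtering, TMM normalization, precision-weighted moderated differential
expression, signed −log(p) ranking, gene-set redundancy filtering,
pre-ranked GSEA with a permutation FDR, cross-stratum shared-gene
reporting, and qPCR ΔCt validation. This vignette explains each model, the
parameters that matter, the numerical choices, and what the synthetic-data
tests do and do not establish.

## The count model and normalization

Counts are treated as negative binomial: `Var(y) = μ + φμ²`, with gene-wise
dispersion `φ`. Sequencing depth and RNA composition differ between
libraries, so expression comparisons use TMM-scaled effective library
sizes.

**Low-count filter.** A gene is excluded iff its count is below
`min_count` (default 10) in at least `min_samples` (default 10) samples.
The rule is deliberately literal and per-sample; both knobs are exposed
because the sentence "fewer than 10 counts in at least 10 samples" also
admits a per-total reading, and the literal reading is the one adopted.
The filter is applied once to the full sample set before stratification,
so all per-stratum comparisons share a single tested gene universe — this
is what makes the downstream shared-gene intersections well defined.
`filter_low_counts()` refuses `min_samples` larger than the number of
samples (the rule could never trigger), so callers opting into small
designs must lower it explicitly.

**TMM.** The reference sample is the one whose 75th-percentile CPM is
closest to the mean of those percentiles. For each sample, M-values (log2
ratios of library-normalized counts) and A-values (average log2 abundance)
are computed over genes positive in both sample and reference; the most
extreme 30% of M and 5% of A are trimmed from each tail (rank-based, as in
the published definition), and the factor is the mean of the surviving
M-values weighted by inverse delta-method (binomial) variances. Factors
are rescaled to geometric mean 1, so they are composition corrections, not
depth corrections. Degenerate cases are exact: identical columns and pure
depth scalings give factors of exactly 1 (the weighted mean is snapped to
zero when all |M| < 1e-6, matching the behaviour of the reference
implementation in common use).

**logCPM.** `log2((y + prior)/(N·f + 2·prior) · 1e6)` with `prior = 0.5`.
The prior keeps zeros finite; the `2·prior` library adjustment keeps the
transform monotone and ratio-invariant.

## Differential expression

Within one stratum (one region × age), the model is a two-group weighted
linear model per gene on logCPM. Observation weights follow the voom
recipe: fit unweighted per-gene models, smooth `sqrt(residual SD)` (a
quarter-root variance, approximately symmetric) against average
log-expression with `lowess` (span 0.5), predict the trend at each
observation's fitted value, and use `predicted^-4` as the weight. The
trend prediction is linearly interpolated and held constant beyond the
observed range, and predictions are floored at 1e-4 so weights stay
finite. Counting noise shrinks with abundance, so weights increase with
expression on NB data; on homoscedastic data they are flat — both
properties are asserted in the tests.

Variance moderation matches the first two moments of `log(σ̂²)` to a
scaled-F model. The prior df `d₀` solves a trigamma equation by Newton
iteration (tolerance 1e-8, with asymptotic branches for very large/small
arguments); the prior variance follows from the digamma identity. When the
observed spread of log-variances does not exceed what sampling alone
implies, `d₀ = ∞` and every posterior variance equals the common variance
(the plain mean of the `σ̂²`). The moderated t uses `d₀ + d_g` degrees of
freedom. The whole procedure reproduces the published empirical-Bayes
reference implementation to 1e-8 on random instances (a cross-check kept
in the test suite, not a dependency).

DE calls use strict inequalities: `|log2FC| > 0.585` (≈1.5-fold) and
BH-adjusted `p < 0.05`. A gene at exactly 0.585, or exactly 0.05, is not
called.

**Ranking for GSEA.** `score = −log₁₀(max(p, 1e-300)) · sign(log2FC)`.
Choices made here, all configurable: log base 10 (the base does not change
the ordering; 10 is the common pre-ranked convention); the *raw* p rather
than the BH-adjusted one (BH is rank-monotone so the ordering is
identical, but magnitudes differ); a 1e-300 underflow floor; ties broken
lexicographically by gene identifier so the ranking is identical across
platforms; `sign(0) = 0`.

## Gene-set redundancy filtering and ortholog mapping

Public mouse gene-set collections contain many near-copies. The filter
computes pairwise Jaccard coefficients `|A∩B|/|A∪B|` and keeps a set iff
its Jaccard with every previously kept set is ≤ 0.8, in a greedy pass
sorted by descending size with names as tie-break. Consequences, all
tested: exact duplicates (J = 1) collapse to one representative; in a
near-duplicate pair (J > 0.8) the larger set survives; a pair at exactly
J = 0.8 is untouched (strict inequality); survivors are pairwise ≤ 0.8 and
the filter is idempotent. The greedy order is a design choice — the
two stated rules (duplicates, J > 0.8 pairs) do not by themselves resolve
ties of equal size or chains A~B~C, and the sorted greedy pass makes the
result deterministic while containing both rules as special cases.
Filtering compares sets across all sources globally rather than within
source, the more aggressive reading of an ambiguous instruction.

Ortholog mapping replaces each member by all of its targets (one-to-many
expands then dedupes, exact case-sensitive matching), reports unmapped
genes, and drops emptied sets by default. It never increases the number of
sets.

## Pre-ranked GSEA

The enrichment score walks the ranked list; hits add
`|score|^w / NR`, misses subtract `1/(N − N_h)`, and ES is the running-sum
value of maximal absolute deviation. `weight_exponent` defaults to 1
(classic weighted GSEA; 0 gives the unweighted Kolmogorov–Smirnov
statistic — the test suite verifies `|ES|` equals the two-sample KS
statistic exactly in that case). The implementation walks only the hit
positions (the sum is linear between hits), and is verified against a full
running-sum enumeration to 1e-12. Two numerical conventions: an exact tie
between the positive and negative extrema resolves to the positive side,
compared with a 1e-9 tolerance because exact ties are common at weight 0;
a set whose in-universe scores are all zero falls back to equal increments
(the KS limit).

**Null and FDR.** The null for a set of size k is the ES of sets of size k
sampled uniformly without replacement, with `n_perm = 1000` by default and
one cached distribution per distinct size. Draws come in antithetic pairs
(each sampled position set is scored together with its rank-mirrored
counterpart), which makes the null exactly equivariant under negation of
the ranking — so negating all scores flips every ES, NES, and nominal p
exactly, a property the tests assert — and reduces null variance at no
cost. NES divides ES by the mean magnitude of same-sign null values,
preserving the sign; nominal p uses the `(r+1)/(n+1)` continuity floor.
If no same-sign null values exist the NES is undefined and the set is
flagged, never selected. FDR q is sign-stratified: the fraction of
same-sign null NES at least as extreme over the fraction of same-sign
observed NES at least as extreme, clipped to [0, 1] and made monotone
(BH-style suffix minimum within each sign). Selection applies
`q < 0.05` and `|NES| > 1.4`, both strict. Sets with fewer than 10 or more
than 500 members inside the ranked universe are skipped and reported;
members absent from the universe are dropped with the used size recorded.

## qPCR validation

Candidate endogenous controls are ranked by the standard deviation of
their raw Ct across all samples (mean reported alongside; a CV option
exists). SD of raw Ct is the minimal literal reading of "stability in
terms of mean and standard deviations"; note that a shared per-sample
shift cancels in ΔCt but *not* in raw-Ct SD — the tests pin this
behaviour down. The top-k (default 2) controls are combined by the
geometric mean of their Ct values (of the Ct values themselves, not of
linearized quantities — the alternative convention exists and the choice
is deliberate). `ΔCt = Ct(gene) − Ct(reference)` per sample;
`ΔΔCt = mean ΔCt(condition B) − mean ΔCt(condition A)`, so a planted
2-fold increase gives −1. Group comparison is a two-sided equal-variance
Student's t (Welch available) with BH adjustment reusing the same routine
as the DE stage. Undetermined reactions must be encoded `NA` (never 0);
candidates with >50% missing are excluded with a warning; a gene equal to
the single control has ΔCt identically 0 and p = 1 by the degenerate-data
guard. An overall-expression check gene can be passed through `exclude`
so it is reported but never tested.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions every recovery test runs under: 2,000 genes, n = 6 per group,
two genotypes, optionally crossed with 4 brain regions × 2 ages;
log-normal baseline means (meanlog 5, sdlog 1.5 — a realistic bulk
RNA-seq abundance spread after filtering); log-normal NB dispersion
centred on 0.1 (sdlog 0.4) as typical for bulk tissue; log-normal library
factors (sdlog 0.2); 6% of genes planted at |log2FC| = 1 with random
signs. Counts are drawn as
`y ~ NB(mean = s_j · m_g · 2^(x_j β_g), dispersion φ_g)`, with a Poisson
branch below φ = 1e-8 so the dispersion→0 limit is exact. Identical seeds
give bit-identical output, and simulated moments match `μ + φμ²` within
Monte-Carlo error — both tested.

For enrichment recovery, `simulate_enrichment_study()` plants 10 disjoint
sets of 40 genes in which 80% of members carry the effect (signs
alternating across sets) among 90 null sets of the same size. Null sets
are drawn from the unaffected portion of the universe: they are meant to
measure the method's false-selection rate, and drawing them from the full
universe would let them legitimately catch planted genes, conflating
overlap with error. The multi-stratum generator shares a configurable
fraction (default 50%) of each stratum's planted genes across all strata,
which is what the shared-gene report should recover.

What the generator does **not** emulate: batch effects, sex, outlier
samples, gene–gene correlation beyond set co-membership, length biases,
or library-preparation artefacts. Passing recovery tests therefore shows
the machinery is correct and well calibrated under an idealized NB world,
not that any particular biological dataset will yield 60% sensitivity.

## Orchestration, seeds and determinism

`run_pipeline()` is a pure composition of the exported stages: its outputs
equal the stages invoked individually with the same inputs and seeds
(tested). All randomness flows from one top-level seed expanded
deterministically per stage (small affine offsets, kept below 2³¹), so two
runs of one configuration are byte-identical; the run manifest records
seeds, parameters and counts but no timestamps, precisely so that it too
is reproducible. Any stage failure aborts with the stage name and leaves a
failure marker next to the partial outputs.

## Problem sizes used by the checks

The test suite verifies the enrichment score against full enumeration on
1,000 random instances (N = 50, set sizes 1–25, weights 0 and 1, max
deviation < 1e-12), the KS reduction on 100 instances, TMM against a
quadratic-time naive implementation on 100 random 200 × 6 NB matrices
(1e-10), BH against a quadratic step-up reference on 1,000 random
vectors, DE recovery over 20 seeds (empirical FDR ≤ 0.10, sensitivity
≥ 0.6 at the default conditions), GSEA recovery over 20 replicates at
1,000 permutations (all planted sets selected in ≥ 18, ≤ 5% null
selection), ΔΔCt recovery over 50 simulations (within 0.15 cycles of −1
at σ_Ct = 0.1), and byte-identical double runs of the full pipeline.
These sizes were chosen as the smallest at which the Monte-Carlo bounds
are stable.

## Known limitations

- One contrast per stratum; no joint model across regions/ages, no
  surrogate-variable or batch correction (out of scope by design).
- Gene-permutation is the only GSEA null (the appropriate one for
  pre-ranked input); phenotype permutation is not implemented.
- The redundancy filter is set-algebraic, not ontology-aware.
- qPCR quantification assumes 100% amplification efficiency (no Pfaffl
  correction) and equal-variance groups by default.
- The original study's own collections, accessions and per-region DE
  tables are not redistributed; the pipeline consumes any GMT/TSV inputs
  of the documented shapes.
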