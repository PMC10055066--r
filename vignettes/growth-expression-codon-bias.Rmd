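---
title: "Growth-coupled expression variation and codon usage bias: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-coupled expression variation and codon usage bias: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcicub)
```

## The scientific question

Highly expressed microbial genes preferentially use a restricted set of
synonymous codons. The usual way to quantify this is to correlate a per-gene
codon usage bias (CUB) score against expression measured in one condition.
But expression is condition-dependent: a gene that is abundant during rapid
growth may be scarce during starvation, and vice versa. This package
implements an analysis that makes the condition axis explicit:

1. score CUB per gene (codon adaptation index, CAI, or tRNA adaptation
   index, tAI) from coding sequences;
2. process a genes × conditions expression compendium with per-condition
   growth rates;
3. ask, per condition, how well expression predicts CUB, and how that
   predictivity relates to growth rate;
4. summarize each gene's growth coupling as the **Growth Correlation Index
   (GCI)** — the Pearson correlation `r` between the gene's log expression
   and the growth rate across conditions — with a permutation null;
5. predict CUB from mean expression and GCI with four nested linear models;
6. compare GCI between labeled gene groups (essential/non-essential,
   core/accessory) and run over-representation analysis on the positive-
   and negative-GCI gene sets.

## Codon usage bias scores

Both CAI and tAI are geometric means of per-codon weights,
`exp(mean(log w))`, with the weight table supplied as input (a two-column
TSV). Tables are max-normalized on load because both metrics are defined
relative to the optimal codon. Numerical and policy choices:

* **Stop codons** are never scored.
* **Single-codon families** (ATG, TGG) carry no synonymous choice; `cai()`
  excludes them by default, following the original CAI convention, with a
  switch (`exclude_single_codon_families = FALSE`) because usage differs
  between published implementations. Whether the initiator ATG should be
  scored is genuinely underdetermined; the default is documented rather
  than silently assumed.
* **Zero weights** occur in published tAI tables for codons with no
  decoding tRNA; `tai()` substitutes the geometric mean of the non-zero
  weights by default (the convention of the original tAI software), or can
  refuse to score (`zero_policy = "error"`).
* **Ambiguous bases** (N etc.) are skipped with a warning, not an error:
  real genome records contain them and dropping a codon is preferable to
  dropping the gene.

Coding sequences come from GenBank flat files via `read_genbank()` and
`extract_cds()`: minus-strand features are reverse-complemented, joined
locations spliced in annotation order, coordinates kept 1-based inclusive.
`filter_cds()` applies three quality rules — length divisible by 3, length
equal to the annotated interval span (catching malformed joins), and length
at most five times the median of the full input set, with the median always
computed before any removal.

## Expression processing

The compendium is a log-scale genes × conditions matrix (log-TPM or
equivalent) with per-condition growth rate (1/hr) and metadata. Processing
steps, in pipeline order:

* conditions with unknown or zero growth, or alignment score below 80
  (boundary retained), are dropped;
* biological replicates are averaged arithmetically **on the stored log
  scale** (matching how the source compendia report averaged, normalized
  profiles), along with their growth rates;
* condition pairs with all-by-all Spearman correlation exactly 1 (within
  1e-12) are treated as duplicated measurements. The default policy drops
  *both* members: when two identical expression columns carry different
  growth rates, neither pairing can be trusted. `drop_one` is available;
* genes with missing values in any condition are removed, and identical
  gene profiles deduplicated (first kept).

Absolute abundances (protein copies per cell, fmol/mgDW) are mapped to a
log-TPM-like scale by `x = 6 + log10(a / sum(a))` per condition, after
replacing zeros with the smallest non-zero value of the whole table (not
per column). Base 10 is the default because it makes the transform exactly
`log10(TPM)`; the base is configurable (`log_base = exp(1)` gives a
natural-log variant) since both conventions appear in the proteomics
literature. The transform is invariant to rescaling a column by a positive
constant, which the tests verify.

## Condition-level structure and pruning

`condition_correlation_matrix()` reports pairwise Pearson r and r² between
conditions over genes; `per_condition_cub_r2()` reports, per condition, the
squared correlation between expression and the CUB score;
`growth_predictivity_trend()` is the Spearman rank correlation (average
ranks, asymptotic two-sided p) between growth rate and that predictivity.
Spearman is used for the trend because predictivity is bounded in [0, 1]
and the claim of interest is monotone, not linear.

`prune_redundant_conditions()` builds a maximally distinct condition subset:
iteratively recompute the all-by-all Spearman matrix, find the highest
off-diagonal pair, and remove one member uniformly at random (seeded) until
the target count remains. Ties between equally correlated pairs resolve to
the lowest-index pair so that runs are reproducible; the removal order is
logged. The maximum off-diagonal correlation is non-increasing across
iterations (every surviving entry existed in the previous matrix), which
the tests assert as a property.

## GCI and its permutation null

`compute_gci()` is a per-gene Pearson correlation with the growth vector,
pairwise-complete over missing values; genes with zero expression variance
or fewer than three complete pairs are flagged `defined = FALSE` and
excluded from downstream statistics rather than silently imputed.

The null (`permuted_gci()`) shuffles the growth vector independently per
gene and records **one** permuted correlation per gene, giving a null
sample the same size as the observed set. Only one side of the pair is
shuffled: permuting both with independent permutations is equivalent in
distribution, while permuting both with the *same* permutation would
reproduce the observed value — a failure mode the one-sided design rules
out. A `n_replicates` argument provides a per-gene null spread when needed.

The mode of the observed GCI distribution is estimated by a histogram with
Freedman–Diaconis bins — robust at the few-thousand-gene scale and free of
a bandwidth choice. Skewness is the moment estimator `m3 / m2^1.5`.

## The four nested models

`fit_models()` fits, by ordinary least squares on a common listwise-complete
gene set:

| model | predictors |
|---|---|
| `expr_only` | mean log expression |
| `gci_only` | GCI |
| `additive` | both |
| `interaction` | both + product term |

Adjusted R² follows `1 - (1 - R²)(n - 1)/(n - p - 1)` with the interaction
counting as one predictor. Because the models nest, R² is non-decreasing
along the chain — asserted as an invariant on arbitrary data. Predictors
are left unstandardized by default so coefficients keep their natural units
(CUB per log-expression unit, CUB per unit correlation); `standardize =
TRUE` is available. The p-value reported per model is the overall F-test;
per-coefficient tests are emitted alongside, since published summaries do
not always say which is meant. Collinearity of the additive design is
quantified by `vif()`, computed from its definition `1/(1 - R_j²)` by
regressing each predictor on the other, and cross-checked in the tests
against an independent reference implementation.

Whether the CUB–GCI relationship needs curvature is checked by
`compare_gci_linearity()`, an AIC comparison of a linear against a
quadratic fit — a deliberately simple reinterpretation of a model-form
check for which no standard method exists.

## Gene-set statistics

`compare_groups()` is a pooled-variance two-sided Student's t-test on GCI
between two label groups (Welch behind a flag — pooled is the stated
convention of the analyses this package reproduces, Welch the safer modern
default). `enrich()` runs a one-sided hypergeometric over-representation
test per term, adjusts with Benjamini–Hochberg over all tested terms, and
applies the dual threshold `p <= 0.04` and `q <= 0.05` verbatim — the
unusual pairing is kept deliberately rather than normalized to a single
cutoff. Odds ratios use the cross-product with a flagged Haldane 0.5
correction when a cell is empty; `top_by_odds_ratio()` ranks descending
with ties broken by ascending p then term id. The universe is the set of
defined-GCI genes present in the term mapping; the mapping is taken as
given (no ontology-ancestor propagation).

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with recorded ground truth:

* growth rates uniform on 0.1–1.5 /hr (matching the broad observed spread
  of compendium growth rates, which cluster nowhere in particular);
* per-gene slopes from a sign-constrained two-component mixture: a
  fraction `slope_mix = 0.25` positive, magnitudes `|N(0.8, 0.4)|`. These
  defaults place the mode of the theoretical GCI near −0.3 at unit noise —
  a negatively skewed distribution with a positive minority, the shape
  reported for real compendia. The published analyses give only the mode
  and range of the GCI distribution, so these parameters are illustrative,
  not calibrated;
* expression `x = baseline + slope × growth + N(0, noise_sd²)`, baseline
  lognormal on the natural scale (stored on the log scale, mean 5, SD 1.5
  in log-TPM-like units), noise SD 1;
* optional replicate columns share a condition's growth rate but draw
  independent noise;
* ALE and mutant/knock-out flags drawn with probabilities mirroring the
  cohort proportions of the motivating compendium (about 53% ALE; about
  42% of non-ALE conditions mutant/KO), so the neutral-subset filters have
  realistic effect sizes.

The recorded truth includes the theoretical GCI,
`b·sd(μ) / sqrt(b²·var(μ) + noise_sd²)` computed from the realized growth
draws, against which recovery is tested. A per-gene latent score
(standardized baseline plus standardized theoretical GCI) sets the
codon-sampling exponent `beta = exp(coupling × score)` used by
`generate_sequences()`: each internal codon position draws an amino acid
uniformly and then a synonymous codon with probability `∝ w^beta`. `beta =
0` gives uniform within-family usage with a closed-form expected CAI;
large `beta` concentrates on optimal codons. Sequences start ATG and end
TAA (any stop satisfies the contract; fixing one keeps output minimal and
reproducible).

**What the generator does not emulate:** mechanistic transcription or
translation, tRNA-pool dynamics, condition-specific regulation structure,
heteroskedastic measurement noise, or compositional constraints of real
genomes. Passing recovery tests therefore demonstrates correctness of the
estimators under the stated statistical model, not biological fidelity.

## Problem sizes and determinism

The test suite exercises every stage at small scale (tens to a few
thousand genes, tens of conditions); the acceptance script runs the full
pipeline at 2,000 genes × 103 conditions × 2 replicates, comfortably at
desk scale. All randomness flows through explicit integer seeds
(`withr::with_seed`), and a pipeline rerun with the same configuration is
byte-identical, which the tests check via file checksums.

## Known limitations

* The GenBank reader is deliberately minimal: single-record flat files,
  `join`/`complement` locations on one strand. Mixed-strand joins and
  remote references are skipped with a warning.
* GCI is a correlation between two noisy quantities; with few conditions
  it is itself noisy, and nothing here separates measurement error from
  biological variation.
* The headline statistics of the motivating analyses depend on external
  compendia (hundreds of RNA-seq experiments, reference genomes); this
  package reproduces the *method* and validates it on synthetic data with
  known truth. An optional script (`inst/scripts/integration-genomes.R`)
  checks the CDS-filter counts against the full reference genomes when
  they are available locally.
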