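# gcicub

Growth-coupled expression variation and codon usage bias.

## The problem

Microbial genes that are highly expressed tend to use a restricted,
"preferred" subset of synonymous codons — a pattern usually attributed to
selection on translation speed and accuracy. But expression is
condition-dependent: the same gene can be abundant during rapid growth and
scarce during starvation. A CUB–expression correlation measured in one
condition therefore tells only part of the story.

`gcicub` makes the condition axis explicit. Its central statistic is the
**Growth Correlation Index (GCI)** of a gene:

```
GCI_g = cor( x_g. , mu )        (Pearson r)
```

where `x_gc` is the gene's log-scale expression in condition `c` and
`mu_c` the condition's growth rate (1/hr). Genes with `GCI > 0` are
relatively upregulated during rapid growth; genes with `GCI < 0` during
slow growth. Around this the package provides:

* **Codon bias scoring** — CAI and tAI as geometric means of pluggable
  codon-weight tables, `exp(mean(log w))`, with CDS extraction and quality
  filtering from GenBank flat files.
* **Expression processing** — condition filters (growth, alignment score),
  replicate averaging, rank-identical duplicate detection, the
  `6 + log10(a/Σa)` transform for absolute abundances, neutral
  (non-ALE/non-mutant) subsets.
* **Condition-level analysis** — all-by-all condition correlations,
  per-condition expression→CUB predictivity (r²), its Spearman trend with
  growth rate, and iterative pruning to a maximally distinct condition
  subset.
* **GCI inference** — per-gene GCI, a per-gene permutation null, summary
  statistics (range, histogram mode, skewness, fraction beyond twice the
  null SD).
* **Nested linear models** — CUB predicted from mean expression, GCI,
  both, or both with interaction; adjusted R², overall F-tests, variance
  inflation factors, prediction surfaces.
* **Gene-set statistics** — pooled t-tests of GCI between labeled groups
  (essential/non-essential, core/accessory) and hypergeometric
  over-representation analysis with Benjamini–Hochberg correction and
  odds-ratio ranking.
* **A synthetic-data generator** with recorded ground truth (true slopes,
  theoretical GCI, planted codon-bias coupling, planted enriched terms) so
  every stage is testable at desk scale.

## Worked example

```r
library(gcicub)

# a synthetic compendium with known ground truth
spec <- synthetic_spec(n_genes = 500, n_conditions = 60, seed = 7)
sim <- generate_dataset(spec)
sim$dataset
#> expression_dataset: 500 genes x 60 conditions
#>   scale: logTPM
#>   growth rate: 0.112-1.5 /hr (60 known)

# codon-bias scores from sequences whose bias is coupled to the truth
tab <- read_weight_table(system.file("extdata", "synthetic_cai_weights.tsv",
                                     package = "gcicub"))
cds <- generate_sequences(sim$truth, tab, n_codons = 200, seed = 8)
scores <- score_genes(filter_cds(cds)$kept, tab, metric = "cai")
head(scores, 3)
#>      id metric     score n_codons
#> 1 g0001    CAI 0.5960406      180
#> 2 g0002    CAI 0.5447362      180
#> 3 g0003    CAI 0.5403528      179

# GCI and its permutation null
gci <- compute_gci(sim$dataset)
null <- permuted_gci(sim$dataset, seed = 9)
s <- gci_summary(gci, null)
#> GCI range -0.76 to 0.65, mode -0.35; null sd 0.126; 66% beyond 2 null SD

# four nested models predicting CUB
fits <- fit_models(scores, rowMeans(sim$dataset$X), gci)
fits
#> Nested codon-bias models (n = 500 genes)
#>        model   n        r2    adj_r2     p_overall
#>    expr_only 500 0.7175669 0.7169998 7.994948e-139
#>     gci_only 500 0.4483193 0.4472115  2.549788e-66
#>     additive 500 0.8316119 0.8309343 5.474671e-193
#>  interaction 500 0.8335529 0.8325462 1.223090e-192
vif(rowMeans(sim$dataset$X), gci)
#>   predictor      vif
#> 1      expr 1.227648
#> 2       gci 1.227648
```

Reading the output: most genes are *down*-regulated under rapid growth
(negative GCI mode) while a minority with positive GCI carry the strongest
codon bias; mean expression alone explains some CUB variance, adding GCI
raises the adjusted R² substantially, and the near-1 VIF shows the two
predictors are not collinear — GCI carries information about codon bias
that mean expression does not.

`run_pipeline(pipeline_config(...))` chains all stages (simulate/load →
score → process → condition analysis → GCI → models → gene sets) with one
seed, writing per-stage TSVs, a checksummed manifest and a plain-text
report. A thin command-line wrapper is in
`inst/scripts/gcicub-run.R`.

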