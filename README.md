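# stemomics

Integrated metabolome–transcriptome analysis of parental versus stem-like
(stress-selected) cancer cells, as a tested, reusable R pipeline.

Stem-like cancer cells selected by chronic metabolic stress reprogram both
their metabolome and their transcriptome. Detecting that reprogramming from
paired targeted-metabolite and expression data takes a specific chain of
statistics, each of which this package implements and validates:

* **Targeted metabolomics** — protein-mass normalization (pmol/10⁶ cells/mg),
  per-metabolite Student/Welch t-tests with S/P fold changes and
  0.05/0.01/0.001 significance tiers, derived ratios such as NAAD⁺/NAADP⁺,
  and Z-score profiles against the parental reference.
* **PLS-DA chemometrics** — unit-variance scaling, NIPALS fitting, R²X/R²Y,
  cross-validated Q² = 1 − PRESS/TSS, VIP scores
  (VIPⱼ = √(p·Σₐ SSYₐ wⱼₐ²/Σₐ SSYₐ), so Σⱼ VIPⱼ² = p), Hotelling's T²
  95 % ellipse, and a repeated permutation test with empirical
  p = (1 + #{Q²perm ≥ Q²obs})/(nperm + 1).
* **Transcriptomics** — quantile normalization, log2 gene-centering,
  ordinary and random-variance (moderated) t-tests
  (s̃² = ((n−2)s² + 2ab)/((n−2)+2a), inverse-gamma prior fitted by ML), and
  classic Kolmogorov–Smirnov gene-set enrichment with a membership
  permutation null.
* **Differential co-expression networks** — per-condition Pearson edges over
  a pathway gene set, negative-edge removal, selection of pairs with
  r_S > 0 and r_S − r_P > τ (default τ = 0.6), and hub ranking by degree.
* **Gene–metabolite integration** — per-condition correlation matrices,
  average-linkage clustering of gene profiles (distance 1 − r) into k = 10
  sub-clusters, ±0.7 display capping, and a per-cluster differential
  association report with sign-flip flags.
* **Synthetic data with ground truth** — a generator that plants fold
  changes (a 2-fold NAAD⁺ elevation by default) and a condition-specific
  co-expression module with exact pairwise correlation ρ, so every estimator
  above can be scored against what was planted.

## Worked example

```r
library(stemomics)
report <- run_pipeline(list(seed = 17L))
print(report)
#> stemomics pipeline report
#>   NAAD+ fold change (S/P): 2.099 (p = 5.09e-07, p<0.001)
#>   NAAD+/NAADP+ ratio fold: 1.970 (p = 1.00e-04)
#>   PLS-DA: R2X = 0.333, R2Y = 0.984, Q2 = 0.326; permutation p = 0.0495
#>   VIP>1 & p<0.05 metabolites: 4 (NAAD, ADP, glutamate, proline)
#>   diffnet: 1915 selected edges; precision 0.02, recall 0.78; top hub GENE0029 (deg 30)
#>   integration: k = 10 clusters, 20 sign-flip cells
```

Reading the output: the generator planted a 2-fold NAAD⁺ elevation at
n = 5/group; the t-test recovers a 2.10-fold estimate at the strongest
significance tier, and exactly the four planted metabolites (NAAD⁺ up, ADP
up, glutamate and proline down) pass the VIP > 1 and p < 0.05 selection
rule. The PLS-DA model fits the classes almost perfectly (R²Y = 0.98) but
cross-validates modestly (Q² = 0.33) — an honest reflection of ten samples
and four informative features among 38; the permutation test is just
significant at 0.05. The network stage illustrates the opposite caveat: at 10
samples per condition a correlation-difference threshold of 0.6 admits many
noise edges (precision 0.02), which is why the calibrated recovery results
below use n = 30/condition, where precision and recall both reach ~0.9.

Individual stages are plain functions on matrices and sample sheets:

```r
truth <- synthetic_truth(seed = 1L, n_per_group = 15L)
tx    <- simulate_transcriptome(truth, n_genes = 30L)
net   <- build_diff_network(tx$matrix, tx$sheet, rownames(tx$matrix), tau = 0.6)
hub_ranking(net, 5)
score_network(net, truth)   # precision/recall against the planted module
```

A thin command-line wrapper with `simulate`, `metab`, `plsda`, `de`,
`enrich`, `diffnet`, `integrate` and `run` subcommands is installed at
`inst/scripts/stemomics`.

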