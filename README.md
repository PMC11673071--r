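# npvuln

Neuropeptide co-expression vulnerability analysis for brain transcriptomics.

Neuropeptides (NPs) are metabolically expensive to produce, and neurons that
co-express many of them at once — high-NP ("HNP") neurons, and in particular
those producing Alzheimer's-disease-associated neuropeptides (ADNPs) — are
candidates for selective vulnerability in AD. `npvuln` implements the full
analysis chain used to interrogate that hypothesis across three axes, for
anyone working with single-cell/nucleus count matrices, bulk brain RNA-seq,
or atlas cluster annotations:

* **Function** — per-cell NP co-expression scoring (`np_count` = number of
  distinct NP genes with nonzero counts), LNP/MNP/HNP stratification
  (0–1 / 2–5 / 6+), Spearman correlation of the count with summed NP
  abundance, Wilcoxon rank-sum differential expression with BH-FDR,
  per-gene OLS regression on the NP count, and a log-space hypergeometric
  test of gene-set overlap:
  `P(X ≥ x)` for `x` overlapping genes among `k` drawn from `m` successes
  and `n` failures.
* **Time** — donor-level stratum-proportion comparisons between diagnostic
  groups (exact tie-aware rank-sum enumeration at small donor counts), and
  a per-region pseudo-aging scan: cumulative ADNP expression
  `Σ_g log2(TPM_g + 1)` associated with age by covariate-adjusted partial
  Spearman correlation (rank residualization on RIN and Hardy score), after
  the standard exclusion filters (complete metadata, Hardy < 3, RIN > 6,
  ages 30+).
* **Space** — classification of annotated neuronal clusters as AHNP
  (≥ 6 ADNP tags, < 3 non-ADNP NP tags), percentage-based attribution of
  cluster cells to dissections and regions, top-k region ranking, and
  attribute breakdowns of a chosen dissection.

Seeded synthetic-data generators (`generate_sc_dataset()`,
`generate_aging_cohort()`, `generate_cluster_annotation()`) produce inputs
with the statistical structure these analyses assume — long-tailed zero-
inflated NP counts coupled to NP abundance, planted HNP depletion, planted
age-related ADNP decline with confounded covariates, planted AHNP cluster
totals — together with truth records, so every stage is testable end to end
without any external download.

## Worked example

```r
library(npvuln)

sc <- generate_sc_dataset(sc_params(seed = 42))            # 6,400 neurons, CT vs AD
prof <- stratify(count_np_coexpression(sc$matrix, default_np_panel()))
table(prof$stratum)
#>  low  mid high
#> 5190 1035  175

np_count_abundance_correlation(prof)
#>   statistic_name  estimate p_value    n alternative
#> 1   spearman_rho 0.9967867       0 6400   two_sided

props <- stratum_proportions(prof, sc$meta)
compare_stratum_proportions(props, "CT", "AD", "high", alternative = "greater")
#>   statistic_name estimate     p_value  n alternative
#> 1     wilcoxon_W     92.5 0.003807304 16     greater

hypergeom_overlap_test(overlap_input(x = 25, m = 91, n = 19430, k = 307))
#> <overlap_result> x=25 m=91 n=19430 k=307  P(X >= x) = 1.946e-24  (expected 1.43, fold 17.5)
```

Reading the output: the Spearman rho of 0.997 confirms that the number of
co-expressed NPs tracks total NP transcript load, so the count is a valid
proxy for HNP status. The one-tailed donor-level rank-sum p of 0.0038 says
control donors carry significantly larger high-stratum proportions than the
affected donors — the planted HNP depletion is detected. The overlap test
says an overlap of 25 genes, where 1.43 were expected by chance
(17.5-fold enrichment), has an upper-tail probability around 2e-24.

The three orchestrators run whole analyses from one config and write
deterministic result tables plus a JSON run report:

```r
run_function_analysis(list(matrix = sc$matrix, meta = sc$meta,
                           np_list = default_np_panel(), out_dir = "out/fn"))
```

See the methods vignette (`vignettes/np-vulnerability-methods.Rmd`) for the
models, parameter defaults and their rationale, and known limitations.

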