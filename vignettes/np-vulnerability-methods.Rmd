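---
title: "Neuropeptide co-expression vulnerability analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuropeptide co-expression vulnerability analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npvuln)
```

## The scientific problem

Neuropeptides (NPs) are small secreted signalling molecules whose synthesis,
processing and vesicular transport impose a substantial metabolic load on the
neurons that produce them. Neurons co-expressing many distinct NPs ("HNP
neurons") are hypothesized to be selectively vulnerable in Alzheimer's
disease (AD): their loss would explain both the depletion of high-NP neuronal
subpopulations observed in single-cell surveys of the entorhinal cortex and
the decline of AD-associated neuropeptide (ADNP) expression in aging bulk
brain RNA-seq. `npvuln` packages the complete analysis chain behind this
hypothesis so each step is reusable and testable:

1. **Function** — score each neuron by its NP co-expression count, stratify
   into LNP/MNP/HNP groups, test differential expression between strata and
   conditions, and test whether genes elevated in HNP neurons are
   over-represented among genes decreased in AD.
2. **Time** — compare donor-level stratum proportions across diagnostic
   groups, and associate cumulative ADNP expression with age per brain
   region, adjusting for RNA quality (RIN) and death circumstance (Hardy
   score).
3. **Space** — estimate where high-ADNP (AHNP) neuronal clusters live, from
   an atlas cluster-annotation table with per-dissection cell percentages.

## Core quantities and their definitions

**NP co-expression count.** For a cell with raw count vector $x$ over an NP
panel $P$, the count is $c = \#\{g \in P : x_g > 0\}$. Presence/absence is
deliberate: the zero pattern of a gene is more conserved across platforms and
studies than its exact magnitude, and the count is therefore invariant under
any positive rescaling of the data (a tested property). The companion
quantity is the NP transcript sum $s = \sum_{g \in P} x_g$, computed on the
declared layer (raw counts by default; the correlation between $c$ and $s$ is
rank-based, so the layer choice only matters through ties).

**Strata.** Cells are assigned low (0–1 NPs), mid (2–5), high (6+) by
`stratum_scheme()`. The cut points are the field's convention for this
analysis; both are configurable.

**QC.** Cells are retained with 200–2500 expressed genes and a mitochondrial
fraction strictly below 5% (`qc_thresholds()`); the fraction comes from
per-cell metadata when present, otherwise from `MT-` prefixed genes.
Normalization is counts-per-million per cell followed by `log2(x + 1)`.

**Stratum-proportion comparison.** The observational unit is the donor: for
each donor we compute the proportion of its neurons in each stratum, and
compare conditions with a Wilcoxon rank-sum test on those proportions. Donor
level was chosen over pooled cells to avoid pseudoreplication — cells within
a donor are not independent. With at most 10 donors per group the null is
enumerated exactly over all $\binom{n_a+n_b}{n_a}$ rank splits (mid-ranks,
so ties — e.g. several donors with proportion 0 — are handled exactly);
larger groups use the normal approximation with tie and continuity
corrections. A tie-free exact path via the Wilcoxon distribution covers
groups up to 50. The two-sided exact p doubles the smaller tail, capped
at 1.

**Differential expression.** Two-sided Wilcoxon rank-sum per gene on the
log-CPM layer, after two pre-test filters mirroring the standard single-cell
defaults: a gene must be expressed in ≥ 10% of cells in at least one group
and show ≥ 0.25 absolute natural-log fold change, computed as
$\ln\!\big(\frac{\overline{\mathrm{delog}(A)} + 1}{\overline{\mathrm{delog}(B)} + 1}\big)$
where delog inverts $\log_2(x+1)$. Benjamini–Hochberg FDR is computed over
the genes that survive the filters within one contrast (filter-then-test,
matching the convention the defaults come from). Both constants are
configurable; `dge_filter(0, 0)` tests everything.

**Per-gene regression.** For genes of interest, ordinary least squares of
log expression on the NP co-expression count, reporting slope, $R^2$ and the
two-sided slope t-test, with BH adjustment across the gene set; genes are
then ranked by slope and by $R^2$ (alphabetical tie-break) to surface the
genes that scale most strongly with NP load.

**Gene-set overlap.** The hypergeometric upper tail
$P(X \ge x)$ for drawing $k$ genes from a universe of $m$ successes and $n$
failures, summed in log space via `lchoose` so genome-scale universes
(~20,000 genes) cannot overflow. The inclusive tail ("as extreme or more
extreme") is the default; the exclusive convention $P(X > x)$ is exposed
because upper-tail CDF calls in common toolkits exclude the quantile, and
the two differ by one point mass. For any overlap worth reporting both are
far below any reasonable cut-off.

**Aging association.** Bulk samples are excluded when metadata (age, sex,
death classification) is incomplete, when the Hardy score is 3 or 4
(intermediate/slow death), when RIN is not strictly greater than 6, or when
the donor is 20–29 years old (brain maturation continues through the
twenties). The boundary at exactly RIN 6 is excluded — "larger than 6" is
enforced strictly. Cumulative ADNP expression is
$\sum_{g \in \mathrm{ADNP}} \log_2(\mathrm{TPM}_g + 1)$ (sum of logs; the
log-of-sum alternative is a flag — the two weigh genes differently, and the
sum of logs dampens domination by a single highly expressed gene).
Association with age is a **partial Spearman correlation**: mid-rank
transform $y$, age, and each covariate; residualize the ranks of $y$ and of
age on the covariate ranks by least squares; report the Pearson correlation
of the residuals, with a t approximation on $n - 2 - c$ degrees of freedom
or an optional free-permutation p-value. This rank-residualization estimator
targets the same estimand as probability-scale-residual estimators of
partial rank correlation but is closed-form and exactly testable: with
constant or absent covariates it reduces to plain Spearman (an equality we
test to 1e-12), and a strictly monotone $y$–age relationship with
independent covariates yields exactly ±1. Ages reported as GTEx-style
decade brackets enter by their midpoints — rank methods need only the order.

**Regional abundance.** A cluster tagged with $a$ ADNPs and $b$ non-ADNP
NPs is AHNP when $a \ge 6$ and $b < 3$ (both bounds configurable; tags
outside the NP universe are logged and ignored). A qualifying cluster's
cells are attributed to dissections as
$\mathrm{total\_cells} \times \mathrm{pct}/100$ and summed per dissection or
per region under the dissection→region map. Percentage shortfalls below
100% are **not** renormalized — the residual plausibly lies in unlisted
dissections, and renormalizing would inflate the listed ones. Estimates stay
real-valued internally and are rounded only at report time, so summation
precedes rounding. For the attribute breakdown of one dissection we keep
AHNP clusters whose percentage rank for that dissection is within the top
three, and sum the cells attributed *to that dissection* (not the clusters'
totals) per attribute group — the cells a cluster keeps elsewhere should not
count toward the dissection being described.

## The synthetic-data generators

The generators produce data with the statistical structure the analyses
assume, plus truth records, so parameter recovery — not reproduction of any
external dataset — is the test surface.

**Single cell** (`generate_sc_dataset()`): 2 conditions × 8 donors × 400
neurons (6,400 cells, mirroring an 8-donors-per-arm design). Per cell the NP
count is zero with probability 0.70 (the high-zero regime reported for
snRNA-seq of this region) and otherwise $1 + \mathrm{Geom}(0.35)$ truncated
at the panel size, giving a long tail with roughly 3–4% of cells at 6+.
Expressed NP identities are sampled ADNP-weighted (weight 5) for high
counts; each expressed NP's value is $1 + \mathrm{NB}(\mu, \theta)$ with
$\mu = 2(1 + 1.5c)$ — the `coupling = 1.5` default makes the summed NP
abundance grow steeply with the count, reproducing the very strong positive
rank correlation (≥ 0.9, typically ≈ 0.97) reported across real datasets.
Depletion multiplies the probability of remaining high by
$1 - \mathrm{hnp\_depletion}$ (default 0.5) in the affected condition via
resampling of high counts into the low/mid range, keeping per-donor totals
fixed so only the proportion signal moves. 500 background genes (plus 10
mitochondrial genes) carry twenty planted 2-fold differentially expressed
genes. What it does **not** model: doublets, ambient RNA, batch effects,
donor-level expression heterogeneity beyond sampling noise — so passing
tests demonstrate correctness of the statistical machinery under the
declared model, not robustness to those artefacts.

**Aging cohort** (`generate_aging_cohort()`): 11 brain regions, four with a
planted age-related decline of cumulative ADNP expression and seven null,
103 clean samples each (the scale of the smaller real region panels),
decade age brackets 30–79. The decline slope default is −0.045 log2 units
per year of cumulative ADNP expression: after attenuation by decade
binning, covariate adjustment and per-gene noise this realizes a partial
Spearman of roughly −0.4, i.e. the same order as the moderate negative
correlations such analyses report, and comfortably detectable at n = 103.
RIN is mildly confounded with age (r ≈ 0.3) and has a real effect on
expression, so covariate adjustment is doing genuine work; Hardy scores and
sex are drawn per sample. A configurable fraction of planted violators of
each exclusion rule (missing sex, Hardy 3–4, RIN ≤ 6, age 20–29) exercises
the filters, and the truth record lists them.

**Cluster annotation** (`generate_cluster_annotation()`): planted AHNP cell
totals at one tenth the scale of a whole-brain atlas (cerebral cortex
21,810; amygdala 7,230; basal forebrain 4,560; hippocampus 4,090;
hypothalamus 2,320; cerebellum 40), split into clusters with
multiple-of-10 cell counts and multiple-of-10 percentages summing to 100,
so attribution is exact in integer arithmetic and per-region recovery can be
asserted with equality. The cortical percentage splits are weighted toward
the MEC. Boundary decoys violate exactly one AHNP criterion each (5 ADNPs/0
non; 6/3; 5/3); noise tags outside the NP universe probe the
unknown-tag rule.

## Numerical and design choices

* **Gene symbols** are matched case-insensitively after trimming; curated NP
  lists merged across publications come with inconsistent casing. Duplicate
  features are a hard error by default (summing duplicates would silently
  change NP counts); an explicit keep-first policy is available.
* **Missing metadata** is represented as `NA`, never as sentinel values;
  exclusion rules act on missingness directly.
* **Exact-test switches**: tie-aware enumeration up to 10 per group
  (every donor-level comparison in practice), tie-free exact up to 50,
  normal approximation with tie and continuity corrections beyond. The
  Spearman p-value uses exact permutation up to n = 9 and the t
  approximation beyond.
* **Determinism**: every generator is a pure function of its parameter
  object, seed included, and restores the caller's RNG state; the pipeline
  orchestrators write byte-identical result files for identical configs.
  Result tables have documented sort keys and 6-significant-digit float
  rendering; dense matrices are written with 17 significant digits so a
  write/read round-trip reproduces doubles exactly.
* **Degenerate inputs**: all-zero cells stay all-zero under CPM and are
  flagged; constant genes get slope 0, $R^2$ 0, p 1 in the regression;
  empty DGE groups skip that contrast with a logged reason rather than
  aborting the pipeline run.
* **Problem sizes** used by the test-suite simulations (200 replicates for
  power and size checks, 500 for null-centering, 10,000 cells for marginal
  checks) were chosen so the whole suite runs in a couple of minutes while
  keeping binomial uncertainty on the estimated rates within about one
  percentage point.

## Interfaces

All analysis stages are plain R functions over in-memory domain objects; the
readers/writers in the IO layer connect them to Matrix Market triplets,
delimited expression tables, plain-text gene lists, metadata TSVs, and the
cluster-annotation CSV + dissection map. The three orchestrators
(`run_function_analysis()`, `run_time_analysis()`, `run_space_analysis()`)
take a single declarative config (in-memory objects or file paths), write
deterministic result tables plus a JSON run report with per-stage tallies
and timings, and are the package's batch interface;
`scripts/acceptance.R` is a worked example of driving them from a shell.

## Known limitations

* Cell-type identification, clustering and embedding are out of scope: the
  profiling operates on pre-annotated neurons.
* The partial Spearman estimator differs in mechanism (though not in target)
  from probability-scale-residual estimators; for heavily tied ordinal
  responses the permutation p-value is the safer path.
* The AHNP classification is cluster-level: all cells of a qualifying
  cluster count as AHNP. Per-cell classification from raw counts is the
  profiling module's job, not the regional module's.
* Synthetic data cannot validate robustness to the technical artefacts it
  does not model (see above); conclusions about real datasets require the
  real inputs, for which the IO layer and the documented schemas are the
  entry point.
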