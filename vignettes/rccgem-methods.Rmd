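---
title: "Methods: cross-species RCC genomics with rccgem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species RCC genomics with rccgem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rccgem)
```

`rccgem` connects engineered mouse kidney tumour models to human renal
cell carcinoma (RCC) genomics. This vignette is the package's account of
its statistical machinery: what each procedure computes, the assumptions
it rests on, the conventions that were genuinely open and how they were
pinned down, and what the synthetic validation does and does not show.

## Ranked-list gene-set enrichment

Given a log2 expression matrix and two sample groups, `enrich()` runs:

1. **Welch t per gene** (`welch_t()`), group 2 minus group 1 in the
   numerator. The unequal-variance form is used because the two-group
   designs this targets (e.g. induced vs uninduced cultures) are small
   and give no reason to assume equal variances. Degenerate genes follow
   a fixed convention: zero variance in both groups with equal means
   gives t = 0; zero variance with unequal means gives ±Inf signed by
   the mean difference, so such genes sort to the extremes
   deterministically.
2. **Ranking** (`rank_by_t()`): descending t, exact ties broken
   lexicographically by gene identifier, so reruns are bit-identical.
3. **K–S uniformity per set** (`ks_uniformity()`): member ranks are
   mapped to u = rank/N and tested against Uniform(0, 1) with the
   two-sided one-sample Kolmogorov–Smirnov statistic. The simpler u =
   r/N convention is used rather than (r − ½)/N; the difference is
   O(1/N) and irrelevant at transcriptome scale, but the choice is fixed
   here for reproducibility. The null p-value is exact
   (Marsaglia–Tsang–Wang matrix algorithm) for sets of ≤ 35 in-list
   members and the asymptotic Kolmogorov series above that — the exact
   computation is O(k³ log m) in matrix size k and only worth its cost
   where the asymptotic approximation is still poor.
4. **Benjamini–Hochberg** across all tested sets at FDR 5%
   (`bh_adjust()`, delegating to `stats::p.adjust`).
5. **Partial AUC of the top 10%** (`partial_auc_top()`): walk positions
   1..k, k = ⌈0.10 N⌉; at each position the true-positive rate is the
   fraction of the set's in-list members seen so far; the score is the
   mean TPR over the walk. This normalizes the area by the cutoff so the
   score lies in [0, 1] regardless of the truncation fraction — an
   unnormalized 10% truncation would be bounded by 0.1 and a 0.25 call
   threshold would be incoherent. Under random placement the expectation
   is ≈ fraction/2 = 0.05, so the 0.25 default call threshold sits five
   times above chance.

The K–S test is two-sided (a set crowding *either* end departs from
uniformity) while the AUC is one-sided for the top of the list; "enriched
in group 2" therefore means both flags set with the default ranking, and
`direction = "down"` reverses the ranking for the opposite contrast.
Permutation-based weighted enrichment scores (GSEA-style) are
deliberately out of scope; this procedure is the package's native one.

## Signature Z-scores

`signature_scores()` defines a sample's raw signature score as the mean
of its gene-wise median-centred log2 values over the signature genes
present — the "score underlying the Z" is not standardized anywhere
upstream, so this definition is an explicit interpretation, documented
here. Scores are standardized across the cohort and activation is called
at Z > 1 (cohort standard deviations). A zero-variance cohort yields
all-zero Z and no calls, with a warning, rather than NaNs. Note the
cohort definition matters: the Z of a tumour depends on which samples
(e.g. tumours only, or tumours plus normals) form the cohort; the
function standardizes over whatever matrix it is given.

## Genotype stratification and survival

`classify_genotype()` maps the three alteration flags to V (VHL
inactivation alone), VM (VHL + MYC), VIM (VHL + MYC + CDKN2A); all other
combinations — including VHL + CDKN2A *without* MYC, which the scheme
never assigns — are `other`, so the labels partition any cohort. The MYC
flag can come from a copy-number amplification call or from a signature-Z
activation call; the classifier is agnostic (it consumes booleans), and
which source feeds it is the caller's documented choice — copy-number
when available is the recommended default, signature otherwise.

Survival machinery delegates to the `survival` package behind this
package's interfaces: `km_estimate()` (product-limit), `logrank_test()`
(unweighted log-rank; the unweighted variant is the standard reported
form), and `cox_fit()` (partial likelihood, Efron tie approximation —
the less biased of the two common choices, used absent any reason to
prefer Breslow). Genotype enters as indicator covariates with V as the
reference; stage and grade enter as ordinal integers 1–4, a deliberate
simplification of TNM/Fuhrman coding. Convergence is recorded on the
returned object and separation surfaces as a failed convergence flag
rather than a silent huge coefficient.

## Copy-number minimal common region

`minimal_common_region()` takes gene-level segmented copy values
(diploid = 2, 1-based inclusive coordinates). A sample is altered if any
gene crosses the threshold (default 2 ± 0.3 — a conservative margin on
the segmented-copy scale, configurable). Each altered sample's run is the
maximal consecutive block of beyond-threshold genes containing the
*cohort peak* gene (most extreme cohort mean); anchoring at the peak
keeps multi-peak chromosomes from conflating distinct regions. The MCR is
the intersection of the runs; if any altered sample's run misses the peak
the intersection is reported empty, with the per-sample runs returned as
diagnostics. This is a self-contained substitute for a full
significance-based region caller: the package does not model background
alteration rates, and whether intersection-of-runs reproduces a
GISTIC-style region on real data is not claimed. `percentile_rank()` uses
the strict-less fraction over the *other* region genes, so an
all-equal region scores 0 and a unique maximum scores 1.

## Cross-species comparison

`collapse_homologs()` keeps strict 1:1 pairs only — source and target
each appearing exactly once in the (deduplicated) map — because curated
homology tables contain many-to-many entries with no principled
resolution at the expression level; dropping them costs genes but no
correctness. `adjust_batches()` centres every gene on its within-cohort
median and concatenates cohorts. This removes exactly cohort-constant
offsets (platform, species, processing shifts that hit all of a cohort's
samples equally); it is a deliberately simple adjustment, not a
surrogate-variable method, and it cannot remove structured within-cohort
batch effects. Cohort centroids are per-gene medians (midpoint convention
for even cohorts), compared by Pearson correlation; co-clustering uses
average linkage on 1 − Pearson ("centred" correlation — profiles centred
on their means, which Pearson does by construction), optionally
restricted to the most-variable genes. "Most differentially expressed"
as a gene filter for co-clustering is interpreted as highest
across-sample variance, since no two-group contrast is available at that
stage. Adjustment always precedes centroid computation in this package's
pipelines.

Note one structural consequence of median-centring: a centroid computed
over an *entire* cohort after adjustment is identically zero. Centroids
meant for cross-cohort comparison must therefore be computed over
sub-cohorts (e.g. subtype within species), which is how the package's
pipelines use them.

## Normalization and differential expression

Upper-quartile normalization scales each sample so its 75th percentile of
*nonzero* counts equals the across-sample mean of those percentiles
(anchoring to the mean rather than a fixed constant keeps the output on
the data's own scale and makes the operation idempotent). DE calling is
the plain published rule — two-sided Welch t, B–H, |log2 fold change| >
1, q < 0.05 — applied to log2(upper-quartile-normalized counts + 1). The
input scale for the t-test is a documented package decision (pseudocount
1, the standard choice making zero counts map to zero); no
shrinkage or dispersion modelling is used because the rule itself is the
analysis, and the fold-change threshold is applied to the difference of
group means on the log2 scale, the standard reading of "greater than
two-fold".

## Synthetic cohorts: what they emulate, what they do not

`simulation_spec()` holds the generator defaults, which are also the
conditions of the package's validation experiments:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 5000 | transcriptome scale at which rank statistics behave realistically |
| `n_samples_per_group` | 10 | small-cohort regime of the targeted designs |
| `dispersion` | 0.1 | moderate NB overdispersion (variance = μ + 0.1 μ²) |
| `base_mean` | 500 | typical mid-expression count |
| `effect_log2fc` | 1 | +1 s.d. shift of the signal set (at `noise_sd` = 1) |
| `signal_set_size` | 100 | typical curated-set size |
| `noise_sd` | 1 | within-group s.d. on the log2 scale (Gaussian generators) |
| `censor_rate` | 0.3 | realistic administrative censoring fraction |
| `hazard_ratios` | V=1, VM=2, VIM=3 | ordered genotype effect for recovery tests |

Counts are negative-binomial with log-normal library-size factors
(sdlog 0.2) — the minimal generative model under which upper-quartile
normalization is meaningful. The gene-set cohort generator works directly
on the log2 scale with Gaussian noise so that "a shift of 1 s.d." is
exact by construction; its null sets are disjoint from the activated set
for clean type-I accounting. The cross-species generator shares latent
subtype centroids between species and adds a gene-wise, cohort-constant
species offset — precisely the structure the median-centring adjustment
is designed to remove — plus deliberate many-to-one homologs. The
copy-number generator plants per-sample gain intervals that strictly
contain a focal amplicon, making the truth MCR the intersection of the
sampled intervals; the baseline noise s.d. of 0.05 reflects the tight
scatter of gene-level values around a segment mean, and keeps the
probability of a noise gene spuriously extending an altered run
negligible (a crossing needs a 6-s.d. excursion at the default
threshold margin). Survival times are exponential with genotype-scaled
hazards and *independent* exponential censoring (rate matched in
expectation to `censor_rate`), keeping log-rank and Cox recovery targets
unbiased; stage and grade are drawn with genotype-dependent means so that
covariate adjustment has real structure to adjust for.

These generators emulate the *statistical* structure the analyses assume
— not real RNA-seq GC/length bias, not real segmented-copy noise spectra,
not real TNM/grade marginals. Passing validation therefore demonstrates
that the implementations are correct and well-calibrated under their
assumed models; it does not certify performance on any particular real
cohort.

## Validation scale and determinism

The validation experiments (the test suite and `scripts/acceptance.R`)
use: 100 seeded enrichment cohorts at the default sizes above (power and
K–S false-positive rate); 1,000 random instances each for the partial-AUC
and B–H brute-force oracles and 100 for the K–S reference comparison; 100
cross-species cohorts (2 species × 2 subtypes, signal-to-noise 3, 20%
non-1:1 homologs); 100 planted-amplicon cohorts (300 genes, 6 altered
samples, 21-gene amplicon); Cox recovery at n = 2,000 per fit for hazard
ratios 1, 2, 3; and 1,000 null log-rank cohorts of n = 100. These sizes
give the rates involved stable sampling behaviour while keeping a full
run in the minutes range on one CPU. Every generator takes an explicit
seed and restores the caller's RNG state, so identical spec + seed gives
bit-identical cohorts.

## Known limitations

- The batch adjustment removes only cohort-constant offsets; real
  surrogate-variable structure is out of scope.
- The MCR caller assumes a single focal region per chromosome arm of
  interest (peak anchoring) and does not model background alteration
  significance.
- The enrichment procedure tests rank uniformity; it does not estimate
  effect sizes per set beyond the partial AUC, and sets overlapping the
  contrast's DE genes heavily will co-score (no gene-overlap
  deconvolution).
- Signature Z activation depends on the cohort the matrix represents;
  the package does not decide cohort membership.
- Stage/grade enter the Cox model as ordinal integers; no spline or
  categorical coding is provided.
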