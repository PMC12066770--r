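---
title: "Cross-study consistency meta-analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-study consistency meta-analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wolbmeta)
```

## The question and the statistical model

Transcriptomic comparisons of *Wolbachia*-infected versus uninfected
*Aedes aegypti* have been published across two decades, platforms
(two-channel microarrays, RNA-Seq), tissues (whole body, head, muscle,
carcass, midgut) and bacterial strains (wMel, wMelPop). Each comparison
yields a per-gene log2 fold-change and p-value. The question wolbmeta
addresses is not "is gene g affected in some study" but "is gene g affected
in **every** study" — the genes and functions that transcend tissue, age and
strain are the most promising universal points of the symbiosis.

Formally, for trait $g$ (a gene or a gene set) with effect $\theta_{gk}$ in
contrast $k = 1, \dots, K$, the conjunction null is

$$H_0: \bigcup_k \{\theta_{gk} = 0\} \quad\text{vs}\quad
  H_a: \bigcap_k \{\theta_{gk} \neq 0\},$$

i.e. the null holds if the effect is absent in *at least one* contrast.
The maxP statistic is the largest of the $K$ per-contrast p-values. Under
the least-favorable configuration of the conjunction null (all $K$ nulls
true, independent tests), $\max_k p_{gk} \sim \mathrm{Beta}(K, 1)$, so the
combined p-value is the Beta CDF at the observed maximum:

$$p_g^{\text{comb}} = \left(\max_k\, p_{gk}\right)^K.$$

maxP is deliberately stringent: one unaffected contrast is enough to retain
the null. It is the natural choice when the scientific claim is "affected in
all studies". `maxp_combine()` implements this through `pbeta(max, K, 1)`;
combined p-values are then Benjamini–Hochberg adjusted within each trait
family (genes and gene sets separately, since they carry different FDR
cutoffs: 0.05 for genes, 0.01 for sets).

### Missing values

A gene absent from one platform cannot contribute a p-value to the
conjunction, and imputing one would fabricate evidence. Traits with a
missing statistic in any contrast are therefore excluded before combination
(`harmonize_contrasts()`), and the exclusion is logged per gene with the
contrasts it was missing from, so the reduction of the universe is always
auditable.

### Directional consistency

A significant conjunction p-value asserts non-null effects everywhere but
says nothing about their sign. Calling (`call_consistent_traits()`) adds:

* **genes** — BH-adjusted combined p ≤ 0.05, *and* all $K$ log2FC signs
  identical and nonzero, *and* at least $\lceil 2K/3 \rceil$ contrasts
  individually significant at raw $p < 0.05$ (8 of 12 in the reference
  twelve-contrast design);
* **gene sets** — BH-adjusted combined p ≤ 0.01 and at least
  $\lceil 5K/6 \rceil$ contrasts sharing one nonzero NES sign (10 of 12 at
  $K = 12$); sets are allowed a minority of discordant contrasts because
  enrichment directions are noisier than per-gene fold-changes.

Design choices worth making explicit:

* "Individually significant" uses **raw** per-contrast p-values; the FDR
  correction is applied once, at the combined level. Correcting twice would
  double-penalize.
* A log2FC (or NES) of exactly zero satisfies **neither** sign — the
  conservative reading of "always positive or negative".
* The ceilings $\lceil 2K/3 \rceil$ and $\lceil 5K/6 \rceil$ generalize the
  8/12 and 10/12 thresholds to other $K$ and reproduce them exactly at
  $K = 12$; both are overridable in `consistency_criteria()`.
* Fold-change summaries (`summarize_fold_change()`) average **linear
  magnitudes** $2^{|\mathrm{log2FC}_k|}$ and report mean ± sample SD; the
  direction is carried by the call, so printed fold-changes are ≥ 1 with the
  lower condition as reference. Averaging linear magnitudes (rather than
  back-transforming the mean log) matches how such tables are usually read;
  the choice matters little at small spreads but is stated here because the
  alternative exists.

## Pre-ranked gene set enrichment

Per contrast, genes are ranked by decreasing log2 fold-change
(`rank_by_logfc()`; ties broken lexicographically by gene id in byte order,
so rankings are reproducible across platforms). `enrichment_score()` is the
classic weighted running sum: walking down the list, a member gene ("hit")
adds $|s_i|^w / \sum_{\text{hits}} |s|^w$ and a non-member subtracts
$1/(N - N_h)$; the enrichment score (ES) is the signed maximum deviation
from zero and lies in $[-1, 1]$. When the positive and negative extremes tie
(within $10^{-9}$, absorbing accumulation-order rounding), the positive one
is taken.

The permutation null (`gsea_preranked()`) draws random same-size gene sets —
gene-label permutation, the standard null for pre-ranked enrichment. Sets of
the same effective size share one null stream seeded from (seed, size), so
p-values are reproducible and comparable within a contrast. The p-value is

$$p = \frac{1 + \#\{\text{sign-matched nulls with } |ES^0| \ge |ES|\}}
           {1 + \#\{\text{sign-matched nulls}\}},$$

with the +1 pseudo-count keeping $p \ge 1/(n_{\text{perm}}+1)$; the
normalized enrichment score divides ES by the mean $|ES^0|$ over
sign-matched permutations, so NES carries the set's direction. A set with no
sign-matched permutation is reported with $p = 1$ and `nes_defined = FALSE`
rather than dropped. Defaults — weight exponent $w = 1$, 1000 permutations,
effective set sizes 10–500 — are conventional for this statistic and all
configurable.

Two numerical remarks. For $w = 0$ the ES depends on hit positions only and
is invariant under monotone transformations of the scores. For permutations
the ES is computed from the sorted hit positions alone (an $O(m)$ identity
on the running sum extremes), which is exactly equivalent to the full
$O(N)$ scan and is cross-checked against it in the tests.

## What the simulator emulates — and what it does not

`generate_dataset()` draws $K$ independent two-group studies over a shared
universe of $G$ genes: per-gene baseline (shared across studies, normal on
the log2 scale around 7 ± 2, resembling typical log-intensity/VST ranges)
plus the planted effect $\theta_{gk}$ for infected samples plus Gaussian
noise. Planted structure:

* **consistent genes** (fraction `frac_consistent`): $\theta_{gk} = \pm$
  `effect_log2fc` in every study, sign alternating deterministically so
  up/down counts differ by at most one;
* **study-specific genes** (`frac_study_specific`): nonzero in exactly one
  study, assigned round-robin — the minimal violation of the conjunction
  alternative, and the decisive negative control for maxP;
* **nulls**: $\theta_{gk} = 0$ everywhere;
* **enriched sets** (`plant_gene_sets()`, labels cycling
  up/down/null): an enriched set draws 60% of its members from a dedicated
  pool of genes given a coordinated *mild* shift (± `set_shift_log2fc` in
  all studies) and 40% from untouched nulls; null sets are drawn uniformly.
  Mild-shift recruits are consistently shifted by construction, so the truth
  table labels them `consistent_up`/`consistent_down`; the configured
  `frac_consistent` counts only the strong-effect block. This mirrors the
  motivating scenario for enrichment analysis: coordinated moderate changes
  that per-gene calling misses.

Effects are constant-magnitude rather than drawn from a distribution, so
recovery thresholds stay interpretable. An optional per-study missingness
mask (`frac_missing`) emulates platform coverage differences and exercises
the exclusion path; it defaults to off. All randomness flows from one seed,
and identical configurations reproduce byte-identical output.

The simulator deliberately does **not** model read counts, library-size or
mean–variance effects, two-channel artifacts, batch effects, or correlated
genes. Passing its tests therefore demonstrates correctness of the
*meta-analytic machinery* under a clean Gaussian model — not robustness of
upstream differential-expression tooling, which this package ingests rather
than reimplements (`read_contrast_table()` accepts gene-level statistics
from limma, DESeq2 or any other tool). The built-in per-gene test,
`welch_t_contrast()`, matches that Gaussian model: Welch's t with
Satterthwaite degrees of freedom, with the convention that a gene with zero
variance in both groups gets $p = 1$ when the means agree (and 0 when they
do not).

## Calibration, recovery and problem sizes

The validation suite works at desk scale, with sizes chosen to keep the full
run in minutes on one core while leaving Monte-Carlo noise well below the
margins being tested:

* maxP closed form on 10,000 random p-vectors ($K$ = 1…12), agreement to
  relative $10^{-12}$;
* conjunction-null calibration at $K = 12$ with 50,000 uniform traits:
  combined p-values pass a Kolmogorov–Smirnov uniformity check (99% band
  $1.628/\sqrt{n}$) and reject at the 5% level within the binomial 99% CI;
* BH step-up against an independently coded oracle on 1,000 random vectors;
* enrichment scores against an exhaustive prefix-scan oracle on 500 random
  instances (universes ≤ 50, $w \in \{0, 1\}$), and — as an independent
  cross-check — against fgsea's statistic at $w = 1$; permutation p-values
  on 200 null sets are calibrated at the 5% level (the +1 pseudo-count makes
  them slightly conservative, which is the safe direction);
* end-to-end planted-signal recovery at $K = 12$, $G = 2000$, 5% consistent
  genes at |log2FC| = 1, six replicates per group, unit noise.

On the last point the package is deliberately candid. At those noise
settings the per-contrast Welch power at $\alpha = 0.05$ is about 0.35
(`power.t.test(n = 6, delta = 1, sd = 1)`), so requiring individual
significance in ≥ 8 of 12 contrasts makes gene-level calling extremely
stringent: in a 20-replicate pilot the procedure called a handful of genes
at most (sensitivity of order $10^{-2}$), always with the correct direction,
with zero study-specific genes called and an empirical FDR of 0. That is
the intended character of conjunction-based calling — near-perfect
purity, low power for effects near the per-study detection limit; genes
must be individually detectable in most studies to be called. Users wanting
sensitivity to mild consistent effects should look at the gene-set level,
which aggregates them by design, or lower `min_significant` consciously.
The test suite asserts the purity properties (FDR, direction, no
study-specific calls) at these exact conditions and documents measured
sensitivity via the acceptance script rather than hiding it.

## Pipeline and reproducibility

`run_pipeline()` chains simulate (optional) → per-contrast DE → per-contrast
enrichment → harmonization → meta-analysis, writing every stage artifact
(expression, groups and truth TSVs, contrast TSVs, GMT, enrichment TSVs,
exclusion log, per-trait meta tables) plus a machine-readable
`summary.json` recording the seed, K, criteria and call tallies. Every file
it writes is re-readable by the package's own readers, and identical
config + seed reproduce identical summaries byte for byte. Per-contrast
enrichment seeds are derived deterministically from the master seed, and the
permutation scheme, RNG and settings are recorded in each result's metadata.
The packaged design fixture (`extdata/design_table1.tsv`) encodes the
five-dataset, twelve-contrast, five-tissue layout of the analyzed collection
and is parsed and validated by `parse_design()`.

## Known limitations

* maxP assumes independent contrasts; contrasts sharing an uninfected
  reference group (as in multi-arm designs) are positively correlated, which
  makes maxP conservative rather than anticonservative, but exact error
  control under dependence is not claimed.
* The Beta(K,1) null is least-favorable: for traits null in only some
  contrasts the combined p is stochastically larger, another source of
  conservatism inherent to the conjunction formulation.
* Permutation p-values are discrete; at 1000 permutations nothing below
  ~0.001 is resolvable, and BH on such p-values is conservative.
* The simulator's Gaussian independence assumptions understate the
  between-gene correlation of real transcriptomes; calibration results on
  real data will be somewhat less clean than on simulated nulls.
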