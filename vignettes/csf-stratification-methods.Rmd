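---
title: "Methods: stratifying CSF 2-DE proteomic profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratifying CSF 2-DE proteomic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfstrat)
```

## The problem and the data model

Two-dimensional gel electrophoresis (2-DE) separates a proteome by
isoelectric point and molecular weight; each resolved protein species is a
*spot* whose volume (area × intensity) is a semi-quantitative abundance
readout. Because staining and loading vary between gels, the unit of
analysis is the percent volume,

$$\%Vol_i = 100 \cdot \frac{v_i}{\sum_j v_j},$$

the spot's share of the total matched-spot volume on its own gel. All
statistics downstream operate on %Vol.

The package targets the individual-CSF setting: one lumbar-puncture sample
per patient, run in technical triplicate, with a multi-year clinical
follow-up that assigns each patient an aggressiveness class derived from
the disease-modifying treatment (DMT) line ultimately needed — second-line
therapy means a highly aggressive course (`H`), first-line moderate (`M`),
no therapy low (`L`), and a stable untreated decade benign (`LB`, collapsed
into `L` for association tables). Primary progressive disease, death, loss
to follow-up and non-MS diagnoses are excluded from association tables but
always accounted for by name and reason.

## Pipeline stages and their parameters

**Replicate QC.** For each patient, per-spot variability across replicates
is `%SD = 100·s/\bar{x}` with the sample (n−1) SD, averaged over spots
matched in *all* considered replicates. The best pair (minimal mean %SD,
lexicographic tie-break) is aggregated into the patient profile
(per-spot mean ± SD; a spot seen in only one replicate of the pair keeps
its single value with SD = NA). Two thresholds are deliberately distinct
knobs: `best_pair_max = 0.30` flags a patient whose *best pair* is still
noisy, and `sd_accept_max = 0.32` is the acquisition-failure bound above
which a replicate set would be re-run in the wet lab; the pipeline flags
rather than drops, because dropping silently would bias the cohort.

**Representative spots.** The criterion behind "most representative spots"
in this kind of workflow is not standardized; the package uses a presence
fraction across patients with default `presence_fraction = 1.0` (spot
quantified in every profile). The resulting count is data-dependent, never
hard-coded.

**Clustering.** UPGMA (average linkage) on Euclidean distances over raw,
unstandardized %Vol values — no scaling is applied because none is implied
by the %Vol unit, and a z-score option would change which spots dominate.
Spots missing from a profile enter distances as 0 %Vol (absence on a gel
read as true low abundance); a pairwise-complete mode with rescaling is
available. Main clusters are extracted by cutting the tree at successively
finer levels, setting branches of at most `outlier_max_size = 1` patients
aside as outliers, until `k_main` clusters of real size remain; labels are
canonical (size, then smallest member), so results are invariant to input
order. UPGMA merge-height monotonicity is asserted on every run.

**Differential spots.** Per spot, a two-sided Mann-Whitney test on the
per-patient profile means — the patient, not the replicate, is the unit of
analysis — exact (full U null) when `min(n) ≤ 10` with no ties, otherwise a
mid-rank normal approximation with tie correction and no continuity
correction. The fold change is the ratio of cluster means folded to ≥ 1
with a direction flag. Selection is the *union* `p < 0.05 OR FC ≥ 1.5`:
published differential tables of this kind contain non-significant spots
retained on fold change alone and significant spots with negligible fold
change, so both flags are reported and an intersection rule is a one-line
filter. Significance is strict (`<`), matching the conventional "P<0.05"
phrasing. No multiple-testing correction is applied; the number of tests is
attached so users can apply their own.

**Discriminant functions.** Two-group LDA in classification-function form,
$f_k(x) = \mu_k^\top S^{-1} x - \tfrac12 \mu_k^\top S^{-1}\mu_k + \ln\pi_k$
with pooled within-group covariance $S$ and equal priors by default (no
prevalence information is assumed; prevalence priors are an argument). The
argmax decision provably equals thresholding the single linear function
$f_1 - f_2$, and this is tested algebraically on random models. The
published two-spot function pair ships as a fixture
(`dbp_discriminant_model()`); because its source does not say which
function belongs to which cluster, `map_discriminant_to_clusters()`
resolves the mapping at run time by scoring cluster centroids.

**Clinical evaluation.** Cross-tabulations report both conditionals:
`P(cluster | class)` (how a clinical class distributes over clusters) and
`P(class | cluster)` (the predictive value of cluster membership).
Predictive values default to within-cluster proportions; a Bayes mode
weighting `P(cluster | class)` by an explicit class-prevalence vector is
provided and coincides with the direct proportions when the observed
prevalence is used — the algebraic identity
$n_{kc}/n_{k\cdot} \propto P(k\,|\,c)\,\hat P(c)$ is verified numerically
in the suite. The χ² association is plain Pearson with asymptotic p, no
continuity correction and no pooling of small counts; this convention
reproduces the published 5-year p-value pair (0.027 and 0.002) from the
bundled tables, which is why it was chosen despite the small counts.

## The synthetic cohort: what it emulates, what it does not

`generate_cohort()` produces the *stated world* the pipeline assumes, with
a planted ground truth:

- **Marker model.** Per patient, total DBP abundance
  $T \sim \mathrm{LogNormal}(\log 0.35,\, 0.20)$ and a modified fraction
  $\varphi \sim \mathrm{Beta}(\mu_c k, (1-\mu_c)k)$ with class means
  $\mu_H = 0.70$, $\mu_M = 0.50$, $\mu_L = 0.30$ and concentration
  $k = 12$; spot `289` carries $T\varphi$ and spot `288` carries
  $T(1-\varphi)$. This is the mechanism behind the observed
  anti-correlation of the isoform pair: the two spots partition a common
  total, so for fixed $T$ their correlation is exactly −1, and dispersion
  in $T$ attenuates it. The free dispersion knob (the log-sd of $T$) was
  calibrated once, by the prescribed simulation, so that the median cohort
  Spearman correlation of the pair over 200 seeds falls near −0.49 (it
  lands at ≈ −0.48); it is not revisited.
- **ApoE spot** `469`: class-shifted log-normal (log-means
  $\log 0.28 / \log 0.13 / \log 0.08$ for H/M/L, log-sd 0.45).
- **Background**: 236 class-independent spots with log-normal baselines
  (baseline spread 1.0, patient-level spread 0.4 on the log scale), scaled
  so every latent profile sums to exactly 100 — %Vol renormalization is the
  identity in expectation, and in the noiseless limit profiles equal the
  planted truth exactly (tested).
- **Replicates**: each gel multiplies the profile by a log-normal total
  volume (which %Vol cancels) and per-spot multiplicative log-normal noise.
  The per-patient noise magnitude targets a mean %SD drawn uniformly from
  17–32%; because the sample SD of a triplicate underestimates σ by the
  factor $c_4(3) \approx 0.886$, the noise log-sd is set to
  $\sqrt{\log(1 + (c/c_4)^2)}$ so the *observed* mean %SD matches the
  drawn target. Background spots drop out of each gel with probability
  0.05; markers never drop out unless configured.
- **Determinism**: one global seed with a per-patient substream
  (`substream = (seed mod 10^6)·2000 + patient index`), so the same seed is
  byte-identical and appending patients never shifts earlier patients'
  draws.

The generator does **not** emulate gel warping, spot mis-matching,
IgG-driven outlier patients, or any real correlation structure among
background spots. A green recovery test therefore establishes that the
pipeline recovers structure *of the kind assumed*, not that it would
survive the artefacts of real gels.

Distributional forms are modeling choices, not claims inherited from any
data source: spot intensities have no published distribution in this
setting, and log-normal is the conventional default for strictly positive
densitometry.

## Numerical choices and degenerate inputs

- %SD uses the centered one-pass variance; the uncentered sum-of-squares
  form loses all precision at near-zero variance and is avoided.
- The sample SD of a pair is computed as $|x_1 - x_2|/\sqrt 2$.
- Exact Mann-Whitney p-values are two-sided as
  $\min(1,\, 2\min(P(U \le u), P(U \ge u)))$ over the tie-free U null.
- Spearman p uses the t approximation
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$, df $n-2$; at $\rho = -0.49$, $n = 24$
  this gives $p = 0.015$, which pins the convention to the published pair.
- Ties break deterministically everywhere: lowest replicate pair, first
  listed group, smallest member id for cluster labels.
- Degenerate inputs warn rather than fail where a partial answer exists
  (tree exhausted before `k_main` clusters; χ² on a collapsed table) and
  error where none does (empty groups, all-missing feature vectors,
  singular pooled covariance — reported with its condition number).
- Reports are byte-deterministic: no timestamps enter any output file, so
  identical inputs and configuration reproduce identical report
  directories. Stage timings, when wanted, belong to the console log.

## Known limitations

- The planted-class recovery acceptance bound (ARI ≥ 0.8 in ≥ 80% of
  default cohorts) is **not attainable** at the stated effect sizes and is
  left failing by design: with $\varphi$ class means 0.70/0.30 at
  concentration 12, about 7% of patients fall on the wrong side of
  $\varphi = 0.5$, so even an oracle reading the true latent fraction
  misassigns ~1.8 of 24 patients on average, while ARI ≥ 0.8 on a 12/12
  cohort tolerates one. Raising the concentration would pass the test only
  by changing the stated world.
- Fold changes are reported at 1-decimal rounding only for display; note
  that a ratio of 1.769 rounds to 1.8, not 1.7, so reproductions of
  published tables can differ in the last printed digit when the source
  truncated.
- The two-year association tables bundled with the fixtures cannot all be
  re-derived from the fixture memberships (a known off-by-one in the
  source material); only the five-year cells and the two-year aggressive
  column are asserted.
- UPGMA on 24 patients is sensitive to single-patient perturbations near
  cluster boundaries; the outlier rule (`outlier_max_size = 1`) is a
  stand-in for what was originally a visual judgement.
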