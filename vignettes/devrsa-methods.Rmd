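---
title: "Developmental RSA: models, inference and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developmental RSA: models, inference and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devrsa)
```

## The analysis problem

Developmental fMRI studies of object representation present a fixed set of
stimulus conditions (here, a nested design of animacy classes, basic-level
categories and exemplars: 3 × 4 × 3 = 36 conditions) to cohorts that
differ enormously in data quality — infants move an order of magnitude
more than adults, contribute fewer runs, and carry more measurement noise.
The representational similarity analysis (RSA) stack in this package is
built around three defenses:

1. **Cross-subject similarity.** A pair RSM correlates condition patterns
   *between* two different subjects (or runs), so subject-specific noise
   cannot contribute to the group average; what survives averaging over
   all unique cross-subject pairs is, by construction, structure shared
   across the group.
2. **Motion-aware estimation.** Frames above a framewise-displacement
   (FWD) threshold of 1.5 mm are censored with spike regressors, runs
   with more than half their frames censored are rejected, and group
   comparisons can be repeated under importance reweighting that matches
   the motion distributions of the groups being compared.
3. **Reliability-aware interpretation.** Model correlations are expressed
   relative to a split-half noise ceiling (Spearman–Brown corrected);
   regions whose ceiling falls below a floor (default 0.1) are reported
   raw and flagged, since dividing by an unreliable ceiling is
   meaningless.

## The generative model behind the synthetic cohort

Every stage is tested by parameter recovery against
`simulate_patterns()`, which draws condition × voxel patterns as

\[
X_{s,r} = G + I_s + S_{s,r} + E, \qquad
G = \Sigma^{1/2} Z,\;
\Sigma \propto \textstyle\sum_k w_k M_k \;(\text{PSD-floored}),
\]

with an individual component $I_s$ shared across a subject's runs, a
session component $S_{s,r}$ shared within a run (including its two
repetition halves), and i.i.d. measurement noise $E$. The group-shared
component $G$ is common to the whole cohort, which is what gives
cross-subject pairs a non-trivial expected similarity structure: the
expected cross-pattern covariance equals the weighted model mixture, up
to the stated noise terms.

Two numerical choices matter here:

- **PSD floor by diagonal shift.** Hypothesis matrices with ±1 contrast
  weights are far from positive semidefinite, so no covariance can equal
  them exactly. We restore admissibility by raising the diagonal (adding
  white variance equal to the most negative eigenvalue) rather than
  clipping eigenvalues: clipping redistributes mass across the
  off-diagonal entries and destroys the identifiability of the mixture
  weights, whereas a diagonal shift leaves every off-diagonal entry — the
  part the recovery analyses regress on — exactly proportional to the
  requested mixture.
- **Motion model.** FWD traces are lognormal within runs, with a
  lognormal between-run spread (log-s.d. 1.0) around age-group means of
  0.912 / 0.532 / 0.177 mm for 2-month, 9-month and adult groups. The
  between-run spread is chosen so the adult motion distribution is nested
  inside the infant distributions; without that nesting the
  motion-matching reweighting would have no support to resample from.

Default component scales (group 1, individual 0.5, session 0.25,
measurement 1, in pattern s.d. units) put the cross-subject similarity
signal well below the within-subject reliability, which is the regime
that makes the noise-ceiling machinery worth testing. What the generator
does **not** emulate: spatial voxel correlations, hemodynamic
nonlinearity, susceptibility artifacts, or any anatomical structure — so
passing recovery tests demonstrates the estimators are correct under the
additive model, not that real infant data satisfy that model.

## First-level GLM

The design convolves condition boxcars with the canonical double-gamma
HRF (response delay 6 s, undershoot delay 16 s, ratio 1/6 — the standard
parameterization, since only the HRF family is specified by the
procedure) on a 16× oversampled grid, and appends one single-1 spike
column per censored frame, optional motion covariates, a linear trend, a
cosine basis spanning frequencies below 0.01 Hz, and an intercept.
Estimation is per-voxel OLS; spike regression is algebraically equivalent
to deleting the censored rows, and the residual degrees of freedom are
reduced accordingly. The per-voxel dispersion proxy is
`max_j diag((X'X)^{-1})_j × s²_voxel` over the condition regressors —
the maximum is the conservative aggregation, chosen because the exclusion
rule ("dispersion greater than 10") does not state one. The tSNR is
computed after a linear detrend by default so slow drift does not masquerade
as temporal noise.

## RSM conventions

Similarities are centered Pearson correlations (not `1 − r` distances):
group-average RSMs on real data have small, signed entries, which is
natural for correlations of mean-centered patterns and impossible for a
distance. Cross-pair matrices are symmetrized by averaging `(p,q)` and
`(q,p)`; the diagonal holds the *cross-measurement* same-condition
correlation and is deliberately not set to 1 — it carries reliability
information. Adults are aggregated to one unit per subject before
pairing (their runs are averaged), infants are paired at the run level
with within-subject cross-run pairs excluded; these are the aggregation
levels consistent with the pair-count arithmetic of a
17-adult / multi-run-infant design (`choose(17, 2) = 136`).

The split-half noise ceiling partitions subjects into halves (runs travel
with their subject), correlates the two half-group RSMs (Spearman, upper
triangles), averages the raw correlation over 100 random splits (a fixed
seed; a single split is itself a noisy estimate), and applies the
Spearman–Brown correction `2r/(1+r)`.

## Inference

All test statistics are functionals of a group RSM, bootstrapped by
resampling the units that entered the average, with percentile 95% CIs
(the plain bootstrap interval, not BCa). Two resampling granularities are
supported:

- **pair-level**, resampling pair RSMs i.i.d. — the display convention
  used for violin/box summaries;
- **subject-level** (`pair_subjects=`), drawing subjects with replacement
  and averaging the pair RSMs of distinct drawn subjects with
  multiplicities.

These are not interchangeable for calibration: pair RSMs sharing a
subject are dependent, so treating them as i.i.d. units understates the
variance of the group mean, and rank-based statistics additionally carry
a finite-cohort attenuation bias (noise in the averaged RSM entries pulls
Spearman correlations toward zero relative to their large-cohort limit).
In coverage simulations against the per-cohort population value
(`expected_pair_rsm()`, the analytic large-cohort limit given the
realized group component), pair-level percentile CIs under-cover badly at
desk-scale cohorts, while subject-level resampling of a smooth (Pearson
or regression-weight) statistic attains ~90% empirical coverage at 40
subjects. The acceptance checks therefore calibrate the bootstrap in the
subject-level / smooth-statistic regime, and rank-based point estimates
should be read with their small-cohort attenuation in mind.

Importance reweighting bins the pooled source + target FWD values into
deciles (bin count not prescribed; deciles balance resolution against
occupancy) and resamples source units proportionally to the
target/source count ratio of their bin, with zero weight in bins the
target never occupies. When the source only partially covers the target's
support — the realistic infant→adult case — the reweighted mean lands on
the *matchable* part of the target distribution, not its full mean; what
the procedure guarantees, and what we verify, is that groups reweighted
toward a common target agree with each other, and that the reweighted
mean matches the target mean when supports genuinely overlap.

The longitudinal permutation test compares each subject's RSM at the
first timepoint with their own (versus a random subject's) RSM at the
second, using the add-one p-value `(1 + #{null ≥ obs}) / (1 + n_perm)`
so Monte-Carlo p-values are never zero.

### Mixture-weight recovery

Rank ordering of generative mixture weights is recovered by
multiple-regression RSA (`recover_mixture_weights()`): the off-diagonal
entries of the group covariance RSM are regressed on the candidate model
RSMs, each coefficient being the partial contribution of its model. Both
sides are double-centered first, because voxel-wise pattern centering
double-centers an empirical covariance RSM and models with non-uniform
row sums would otherwise be attenuated. Plain partial *Spearman*
correlations are **not** a consistent estimator of the weight ordering
when models have different block sizes — a 12-condition animacy block
produces a larger rank correlation than a 3-condition category block at
equal generative weight; this is a property of rank template matching,
not an estimation error, and is why the recovery criterion uses the
regression form.

## Variance partitioning

Covariance (not correlation) RSMs are additive over independent signal
components, so mean diagonal traces over three comparison tiers —
across subjects, within subject across runs, within run across
repetition halves — estimate nested sums of variances, and differences
of the tiers recover the components: group = T_group, individual =
T_indiv − T_group, session = T_sess − T_indiv. The tier algebra is a
reconstruction (the three comparisons are named in the source procedure,
the subtraction scheme is not); it is the nested interpretation that
makes the three labels identifiable, and it is validated by recovering
injected variances of 1.0 / 0.5 / 0.25 within 20% at 40 subjects × 2
runs × 500 voxels. "Within stimulus repetitions" is operationalized as
within-run across repetition halves (odd/even occurrences at the
12-category level) — the only same-run comparison that never correlates
an estimate with itself. Components may come out slightly negative by
sampling noise and are reported unclipped.

## DNN alignment

The built-in activation provider is an untrained, Glorot-initialized
stack with the canonical five convolutional + three fully connected
stages, run at 64×64 input resolution with activations captured
post-ReLU; pretrained networks are supported by supplying per-layer
activation matrices instead (no downloads, no training). Layer RSMs are
Pearson correlations between image activation vectors; brain–layer
comparisons exclude the diagonal (both conventions are flags; feature
RSA includes it, DNN and maturity RSA exclude it). Layer RSMs of an
untrained network are strongly correlated between adjacent layers, so
planted-layer recovery is a stringent test: the profile's argmax matches
the generating layer in ≥90% of reference-scale replicates.

## MDS embeddings

RSMs are converted to dissimilarities by the max-minus rule (rank
preserving; the plotted quantity is relative distance, so the affine
choice is immaterial) and embedded by metric SMACOF — Guttman-transform
majorization, which guarantees monotonically non-increasing stress — from
a classical-scaling (Torgerson) initialization, which is deterministic
and avoids the local minima random starts hit on exactly embeddable
inputs. The hierarchical alignment fits one global configuration on the
mean dissimilarity, then refines per region and finally per (region,
age), each stage warm-started from its parent with no re-randomization;
the warm starts are what make embeddings comparable across ages, and
majorization guarantees each refinement's stress does not exceed that of
its initialization.

## Problem sizes used by the checks

Unit and property tests run on cohorts of 4–20 subjects with 30–400
voxels. Acceptance-level recovery uses the reference scale of 40
subjects and 500 voxels (20 replicates for ordering and planted-layer
recovery, 100 replicate cohorts for CI coverage, 200 splits for the
pure-noise ceiling); `scripts/acceptance.R` recomputes the same
quantities at 10–50 replicates to stay within a few minutes on one CPU.

## Known limitations

- The generator's additive Gaussian model has no spatial structure; ROI
  selection, registration and atlas handling are out of scope (patterns
  enter as condition × voxel matrices).
- Pair-level bootstrap display intervals are descriptive, not calibrated
  (see above); calibrated inference should use subject-level resampling.
- Perceptual feature extraction is raster-based; its compactness measure
  is accurate to a few percent for shapes tens of pixels across and
  degrades for very thin or very small foregrounds.
- No multiple-comparison correction is applied across models or regions;
  results are per-comparison, with group differences assessed by
  bootstrap difference CIs.
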