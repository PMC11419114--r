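---
title: "Ethogram-based analysis of conditioned suppression and fear learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ethogram-based analysis of conditioned suppression and fear learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethofear)
```

## The problem and the data model

In Pavlovian fear conditioning with rats, a visual cue that predicts foot
shock reorganizes ongoing behavior: it suppresses reward seeking (nose
poking for food) and elicits a diverse repertoire of defensive behaviors
well beyond freezing. This package implements the full analysis pathway
for such experiments, from raw inputs to inferential results, for two
kinds of input data:

* **Frame-level behavior labels.** Video frames are captured at 5 frames/s
  from 5 s before cue onset through a 10-s cue to 2.5 s after cue offset:
  87 frames per trial, 4 trials per session. Each frame carries exactly
  one of 12 mutually exclusive behaviors — freeze, stretch, rear, light
  rear, scale, light scale, jump, locomote, backpedal, cup, port, groom —
  or `background` when no behavior can be discerned. Background is a
  first-class 13th label, not an absence: the scoring procedure assigns it
  explicitly, and it is needed for the conservation checks below. Frames
  are 1-based; frame 26 begins at cue onset (t = 0 s) and each frame spans
  200 ms, so baseline is frames 1–25, cue 26–75, post-cue 76–87.
* **Operant event logs.** Timestamped nose pokes, cue on/off pairs, and
  shocks per session, in seconds.

Trials are scored blind: `encode_trial()`/`decode_trial()` implement a
keyed format-preserving codec that turns (rat, session, trial) into an
opaque word+digit token (a wordlist word chosen by keyed hash, followed by
a keyed permutation of the identifier index and a keyed check code).
The underlying cipher is this package's own design — its goal is
reproducible, injective blinding, not cryptographic secrecy; wrong-key
decoding is detected through the check code and word, so a wrong key
raises an authentication error rather than returning wrong identifiers
silently (detection is probabilistic with failure odds below 1 in 10^5).

## Conditioned suppression

For each trial, the baseline poke rate is the poke count in the 20 s
before cue onset times 3, and the cue rate is the count during the 10-s
cue times 6 (both in pokes/min). The suppression ratio is

$$ r = \frac{b - c}{b + c} $$

with 1 complete suppression, 0 no change, and negative values elevated
poking during the cue. Two numerical conventions matter and are fixed
here: windows are half-open `[start, end)`, so a poke at exactly cue
onset counts toward the cue window; and a 0/0 trial (no pokes in either
window) is undefined — it is returned as `NA` and excluded from session
means, because imputing either 0 or 1 would bias group means in opposite
directions.

A consequence worth knowing: because the ratio is a nonlinear function of
two Poisson counts over windows of different lengths, *equal* baseline and
cue rates do not give an expected ratio of exactly zero. At 20 pokes/min
the exact expectation (by enumeration over the count pair) is +0.043. The
test suite asserts the pipeline against that enumerated value, not against
zero.

## Ethograms and the session feature map

`trial_indicator()` turns a trial into a 13 × 87 one-hot matrix (columns
sum to 1 by mutual exclusivity). `session_array()` averages the 4 trials
of one rat-session into a 12 × 87 matrix of behavior fractions —
background is dropped for the feature map but retained in ethogram plots
and conservation checks. With 4 trials every cell is a quarter multiple.
Flattened behavior-major (behavior 1 frames 1–87, then behavior 2, …) this
is the 1044-element feature vector used for classification; the
published array size (12 behaviors × 87 samples) is consistent only with a
per-bin across-trial reduction, and the across-trial mean is adopted as
the canonical choice. Classification results are invariant to the flatten
order (tested), but the order is fixed so files are bit-reproducible.

`group_ethogram()` gives percent behavior per 200-ms bin over any
selection of trials, and at every aggregation level the 12 behavior
percentages plus background sum to 100 per bin.

## Inter-observer reliability

Reliability is quantified as raw percent identical observations per
unordered observer pair (no chance correction — that matches how the
source analyses report agreement). Two conventions are deliberately
fixed where the verbal description is ambiguous: within a pair, the
lower observer ID is "observer 1" (the confusion-matrix row), and the
"number of behaviors present" in a trial counts distinct non-background
behaviors in the *union* of all observers' labels, which is
observer-independent. The 13 × 13 confusion matrix accumulates every
single-frame judgment of every pair; its trace over its total equals the
frame-weighted mean pairwise agreement, a consistency identity the tests
assert.

## The univariate statistical battery

Group differences per behavior are tested in 1-s windows: five-frame
windows 1–5 … 81–85 plus a trailing 2-frame window 86–87, which is kept
and flagged `partial` (the window tiling is not defined for the last
half-second by the source description; dropping data seemed worse than
flagging it). The unit of analysis is the rat: per window, percent
behavior is averaged over the rat's 4 trials before testing, consistent
with subject-based degrees of freedom. The test is Student's
pooled-variance two-tailed t (the era-typical reading of "independent
samples t-test"), with conventions t = 0, p = 1 when both groups are
constant and equal, and p = 0 with a warning when constant and unequal.

`split_plot_anova()` handles the suppression-ratio design: one
within-subject factor, up to three crossed between-subject factors, fully
balanced only. It is a thin wrapper over `stats::aov()` with an
`Error(subject)` stratum — between effects are tested against
subject-within-groups, within and interaction effects against the
subject × within residual, no sphericity correction. Unbalanced designs
raise an error rather than silently switching to an approximation. The
familywise correction for the 12 behaviors is Bonferroni:
0.05/12 = 0.004167.

Multivariate (Wilks-type) MANOVA is deliberately out of scope; the
univariate battery plus the classification analyses carry the inferential
content.

## Classification of fear-learning status

`fit_lda()` is a two-class linear discriminant from class means and
pooled within-class covariance with equal priors (groups are balanced by
design). With 64 sessions and 1044 features the pooled covariance is
certainly singular; the default mode uses its Moore–Penrose
pseudo-inverse, computed through the thin SVD of the within-class-centered
data, which is the standard pseudo-linear discriminant. If the mean
difference is orthogonal to the range of the pooled covariance (zero
within-class variance in every discriminating direction), the raw mean
difference is used, so perfectly separated degenerate data are still
separated. Shrinkage ((1−γ)S + γ(tr S/p)I) and diagonal modes are
available and recorded in the model object.

`repeated_cv()` runs 100 repetitions of stratified 10-fold
cross-validation: each repetition draws a fresh random partition
(stratification keeps the 16/16 group balance per training set and avoids
single-class folds), accuracy is 1 minus the classification loss — the
mean over folds of the held-out fraction correct — and the summary is
mean ± SEM over the 100 repetitions. Everything is reproducible from one
root seed, and because fold partitions depend only on the labels and the
seed, analyses that share a seed share folds, which is what makes
full-versus-subset comparisons paired.

Two nulls mirror the study design. *Session shuffling* permutes group
labels across sessions; in `repeated_cv(shuffle_labels = TRUE)` the labels
are freshly permuted at every repetition (the published SEM for the
shuffled condition is ~3× the intact one, which is what per-model
reshuffling produces; a single fixed permutation would concentrate far
from 50% by luck of that permutation). *Temporal shuffling* applies one
random permutation of the frame columns per session, jointly across the
12 behavior rows, preserving per-behavior totals while destroying when
things happened. In the full analysis grid (`run_full_analysis()`),
temporal shuffling is applied within the analyzed period, so the
baseline cell does not leak cue-period signal through the shuffle.

Feature subsets: periods baseline/cue/post (300/600/144 features) and
behavior categories Immobile {freeze, stretch}, Horizontal {locomote,
backpedal}, Vertical {rear, scale, jump, light rear, light scale}, Reward
{cup, port}; grooming belongs to no category.

## The synthetic-data generator

The original hand-scored frames are not public, so the package ships a
generator whose defaults reproduce the study design: 32 rats (16 paired /
16 unpaired, sex-balanced, two shock intensities 0.5/0.35 mA), 2 scored
sessions × 4 trials × 87 frames = 22,272 frames and 64 session arrays,
plus 8 six-observer comparison trials (696 frames) for the reliability
module.

Behavior sequences are semi-Markov: a behavior is held for a geometric
dwell with an explicit per-behavior mean (freeze 4 frames, so bouts honor
the ≥3-frame scoring definition of freezing; brief behaviors like jump
and backpedal 2 frames), then the next behavior is drawn from the active
period's transition matrix, built from a target occupancy distribution
(each row is the occupancy with the current behavior removed and
renormalized). Kinetics switch at cue onset and cue offset, where the
state re-anchors by a draw from the incoming period's initial
distribution — the synthetic analogue of cue- and shock-evoked behavioral
transitions. The occupancy targets encode the qualitative group structure:
shared reward-seeking/exploration baseline; paired-cue freezing and
locomotion with reward/rearing suppression; unpaired-cue light-directed
rearing and scaling; a paired shock-evoked locomote/jump/backpedal burst;
and an extinction post-cue pattern in paired rats that resembles the
shock response. The `effect_size` knob scales group divergence from the
shared baseline occupancy: `none` makes the groups exactly identical
(the null generator), `strong` uses the full targets, `moderate` (the
default) halves the divergence.

Two noise sources keep the data from being unrealistically separable:
per-rat gamma(6) multiplicative heterogeneity in occupancy (consistent
individual style across sessions), and a 6% chance per frame that the
observer cannot discern the behavior and scores background. Nose pokes
are a piecewise-homogeneous Poisson process at 20 pokes/min baseline,
suppressed by 85% during cues for paired rats and 15% for unpaired ones,
persisting in extinction. Sex is carried as metadata without kinetic
modulation. All values were fixed once, to qualitative plausibility
against the published ethogram structure; there is no claim of matching
the published percentages.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: temporal microstructure beyond geometric
dwells (real bouts have heavier-tailed durations), observer-specific
bias (all synthetic observers share one error rate), cross-behavior
confusion structure (real confusion concentrates on visually similar
pairs), within-session learning trends, and any dependence of behavior
on poking. Seeds split hierarchically (one root seed, keyed substreams
per rat/session/trial), so single trials are reproducible in isolation.

## Problem sizes and numerical choices

The packaged analyses and the test suite run the full study-sized design:
64 sessions × 1044 features with 100 CV repetitions per analysis cell.
Monte-Carlo checks use 200 simulated sessions (suppression), 1000
replicates (ANOVA type-I error), and 10,000 draws (shuffle fixed points);
effect-size monotonicity uses 50 repetitions per effect level. Tolerances:
conservation identities to 1e−9 or better, aggregation-path agreement to
1e−12, oracle equivalence of t/ANOVA to 1e−8–1e−10, and stochastic
assertions at 3 SEM (plus an explicit dataset-level allowance where a
single synthetic dataset's achieved accuracy fluctuates beyond the
CV-repetition SEM). Ties in the discriminant score go to the first class;
degenerate zero-variance inputs follow the documented t/ANOVA
conventions.

## Known limitations

* The published real-data numbers (mean reliability 72.41%, accuracies
  82.64/49.53/83.16%, the F statistics) depend on the original hand-scored
  frames and operant logs and are not reproducible here; the synthetic
  defaults land in qualitatively similar ranges by construction of the
  generator, not by fitting.
* The discriminant on a singular pooled covariance is one of several
  defensible choices; pseudo-inverse was chosen as the standard fallback,
  with shrinkage and diagonal modes for sensitivity analyses.
* `split_plot_anova()` supports only the balanced designs used here.
* Ethogram plots are quick looks, not publication figures.
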