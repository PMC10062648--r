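---
title: "Methods: stimulus validation scores, split-plot ANOVA and differential-entropy EEG features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus validation scores, split-plot ANOVA and differential-entropy EEG features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emostim)
```

`emostim` implements the statistical machinery of a two-stage
emotion-elicitation study: subjective validation of short-video stimuli
from 9-point Likert scales, and EEG-based verification of the selected
stimuli via differential-entropy features and classifier accuracy. This
vignette documents the models, the tunable parameters and their defaults,
the numerical conventions, and what the synthetic-data generators do and do
not emulate.

## Scoring model

Each participant rates each stimulus on two instruments: an emotional
evaluation scale (intensity 1–9 of the positive, neutral and negative
states, adapted from differential-emotions-style scales) and a SAM-style
scale (valence, arousal, and optionally dominance, liking, familiarity,
each 1–9).

For one stimulus with target valence $t$:

- **Intensity** is the mean of the target-state ratings; the reported SD
  uses the sample ($n-1$) denominator, as is standard for descriptive
  tables.
- **Hit rate** is the proportion of raters with
  $r_t \ge r_j + 1$ for *every* non-target state $j$. The boundary case
  (exactly one point higher) is a hit; a tie is a miss.
- **Success index** is $z(\text{intensity}) + z(\text{hit rate})$ with
  z-scores taken within a *scoring pool* using the population
  ($N$-denominator) SD. The population denominator is deliberate: it is the
  convention that reproduces the published per-pool indices exactly at two
  decimals, which the sample denominator does not. Indices therefore sum to
  zero within each pool, a property the test suite asserts to $10^{-9}$.

The pool is an explicit parameter (`pool_by` in `score_ratings()`). The
verified convention is the one used in the published verification tables:
all stimuli sharing a valence category within one rater group's stimulus
set (nine stimuli per pool). How the original 240-candidate screening
pooled its z-scores is not recoverable from the published material, so no
default is claimed for that setting; callers choose the pool.

Selection (`select_stimuli()`) keeps the top $k$ indices per
(gender, age band, valence) cell. Ties are broken by higher hit rate, then
higher intensity mean, then stimulus id — the first two reflect the
scoring rationale (elicitation reliability first), the last makes the
procedure deterministic. Degenerate pools (zero variance of either series)
raise an explicit error rather than silently scoring zero.

## Group-difference tests

Hit-rate contrasts between two groups use the 2×2 chi-square with Yates
continuity correction, always with df = 1:

$$\chi^2 = \frac{N\,(\max(|ad-bc| - N/2,\, 0))^2}{(a+b)(c+d)(a+c)(b+d)}.$$

The corrected numerator is clamped at zero so near-null tables report
exactly 0.00 — this matches the published zero rows, and the corrected
form (not plain Pearson, available via `correct = FALSE`) reproduces the
published nonzero values. Counts are reconstructed from printed hit-rate
percentages as `round(rate × n)` with n = 20 per group.

Intensity contrasts are available as pooled, Welch and paired t-tests, plus
a summary-statistics form. One published convention could not be pinned
down: the tables label their intensity contrasts paired-samples t-tests
*between* two independent groups, and the printed values match no unpaired
formula applied to the printed summaries (the pooled form gives 3.81 where
3.71 is printed), while the pairing key for a paired computation is not
stated. Both kinds are implemented; the package makes no claim about which
reproduces the printed column. Two degenerate conventions: identical paired
samples return $t = 0$, $p = 1$; a constant nonzero paired difference (or
two zero-variance samples) is an error, since the statistic diverges.

## Three-way mixed ANOVA

SAM ratings are first averaged per participant within each emotion
category (`category_means()`), then analysed in a split-plot design: age
band (3) and gender (2) between subjects, emotion category within, subjects
nested in the between cells. Between effects (age, gender, age×gender) are
tested against the subjects-within-groups mean square; the category effect
and its interactions against the category×subjects-within-groups residual.
Effect sizes are partial $\eta^2 = SS_\text{eff}/(SS_\text{eff} +
SS_\text{error-of-that-effect})$ with each stratum's own error term.

The decomposition is fitted with `stats::aov` and an
`Error(subject/category)` stratum — the standard R route for split-plot
designs — and is verified in the test suite against an independent
brute-force sums-of-squares computation from cell and marginal means on
balanced designs up to 3×2×8 with 10 subjects per cell (relative error
below $10^{-8}$). No sphericity correction is applied, matching the plain
degrees of freedom of the published F statistics; unbalanced complete
designs are accepted and use sequential sums of squares. When every
response is identical all sums of squares vanish; such effects are
reported as $F = 0$, $p = 1$ by convention rather than NaN.

Simple effects (one factor compared within slices of another) and
simple-simple effects (slices of two factors) compare cell means with the
omnibus error terms: within-factor comparisons use the within-stratum
residual; between-factor comparisons at a fixed within level use the
pooled between+within residual (summed SS over summed df), the standard
split-plot pooling for that case. `emmeans` was considered for this step
but multistratum `aovlist` support for the three-way within interaction is
fragile, and the direct computation keeps the error-term choice explicit.
Bonferroni correction ($p_\text{adj} = \min(1, m\,p)$) is applied within
each slice's family. Normality screening uses Shapiro–Wilk; the published
analysis states only that normality was verified, without naming a test,
so this is a package convention.

All reported statistics are rounded half-up to two decimals only at the
presentation layer (`round_half_up()`); internal computation and test
comparisons at tighter tolerances use full precision.

## EEG pipeline

The montage is the fixed 14-channel 10–20 subset of the consumer headset
used in the verification study (AF3, F7, F3, FC5, T7, P7, O1, O2, P8, T8,
FC6, F4, F8, AF4), canonical sampling rate 256 Hz.

**Filtering.** The 0.1–50 Hz band-pass is implemented as an order-2
Butterworth high-pass at 0.1 Hz followed by an order-6 Butterworth
low-pass at 50 Hz, each applied forward–backward (zero phase, so epochs
are not time-shifted). Orders were chosen from the filter-response
requirements at 256 Hz: the order-6 low-pass leaves under 5 % of a 60 Hz
tone's RMS (an order-4 design leaves ~12 %), while the gentle high-pass
avoids numerical trouble at the very low normalized corner
(0.1/128 ≈ 8·10⁻⁴). The notch is an order-2 band-stop at 50 ± 2 Hz:
the 50 Hz residual is ~2 % RMS while 45/55 Hz change by < 0.3 dB.

**Artifact screening.** The original study removed artifacts manually; the
package automates the step with thresholds as explicit stand-ins: a
1-second segment (trial-aligned) is flagged when any channel exceeds
±100 µV or a per-channel robust z (|x − median|/MAD) exceeds 5. The cap of
at most 10 % of the data removed is enforced as a hard invariant: if more
segments are flagged, only the most extreme up to the cap are removed and
the report says so. Flagged segments are recorded on the recording object
and dropped at epoching, which keeps trial bookkeeping exact.

**Epoching.** Each trial is cut into `floor(duration)` non-overlapping
1-second epochs; the trailing partial second is discarded; epochs inherit
the eliciting video's valence as label. Trials shorter than 1 s are an
error. Baseline segments are simply not included in the trial table;
no baseline normalization of features is applied (whether the original
analysis baseline-corrected is unstated, so the default does nothing).

**Differential entropy.** Per epoch, channel and band,
$DE = \tfrac12 \ln(2\pi e\,\hat\sigma^2)$ with $\hat\sigma^2$ the
mean-removed, $N$-denominator variance of the band-limited signal —
for a Gaussian band process this is its differential entropy and equals
log band power up to constants. The band variance is estimated by
periodogram integration over $[low, high)$ (Parseval sum of the FFT power
in the band), not by a second time-domain band-pass. This is a deliberate
design choice: re-filtering with an order-4 zero-phase Butterworth applies
the squared magnitude response twice and biases DE by about −0.06 nats
even in the passband, whereas the spectral estimator is exact on analytic
cases (a unit-variance band-limited Gaussian gives 1.4189 nats; a 10 Hz
sinusoid of amplitude 2 gives 1.7655; white noise of variance $\sigma^2$
gives band variance $\sigma^2\,2(f_h-f_l)/f_s$). Half-open band intervals
make the five bands non-overlapping at shared edges. A zero band variance
(e.g. an all-zero channel) is an explicit error, not −∞. Columns are
channel-major: for each channel the five bands δ, θ, α, β, γ in order,
70 columns in total.

## Emotion recognition

The split is stratified per class at the epoch level with a fixed seed
(8:2 by default). Epoch-level splitting can be optimistic when epochs from
the same video fall on both sides; the grouping columns of the feature
object (`trial`, `stimulus_id`) allow trial-grouped splits, and
`evaluate_group_sources()` keeps stimulus-source bookkeeping (specific /
comparison / film relative to the viewing group) explicit.

The default roster holds eleven classical classifiers including the
published winner (random forest): random forest, k-NN (k = 5), linear and
RBF SVM, multinomial logistic regression, Gaussian naive Bayes, a decision
tree, gradient boosting, LDA, QDA, and a single-hidden-layer MLP. The
original comparison names only its winner among "11 commonly used
classifiers", so the roster is a package choice of exactly eleven
standard methods spanning trees, kernels, linear/discriminant models and
neural networks. Scale-sensitive members receive features z-standardized
with training-set statistics; tree ensembles receive raw features.
Accuracy is plain top-1 percent. The aggregation table reports the
unweighted arithmetic mean per stimulus-source column, rounded half-up to
two decimals, and is permutation-invariant over groups.

## Synthetic data

The generators exist so that every pipeline stage has inputs with known
ground truth.

**Ratings** (`gen_ratings()`): each latent score is grand/category mean +
planted group shift + participant effect + stimulus effect + Gaussian
noise, clipped to [1, 9] and rounded to the integer grid. The default
configuration mirrors the qualitative pattern of the published descriptive
tables — neutral arousal ≈ 2.2 vs ≈ 6.2 for emotional categories, small
female > male shifts on valence and arousal with a larger female advantage
for tenderness, 20 raters per group cell — so ANOVA smoke tests resemble
the published effect *directions* without claiming its cohort-level F
values (the raw ratings are unpublished, so those are explicitly out of
reach). The clip-then-round response model is the simplest invertible-in-
expectation choice; it slightly inflates noise near the scale ends, which
is why planted-effect tests keep means mid-scale.

**EEG** (`gen_eeg()`): each channel is a sum of band-limited Gaussian
noise with configured per-band variances (defaults δ 8, θ 4, α 4, β 2,
γ 1 µV², a plausible resting spectrum), a $1/f^{\chi}$ background
(χ = 1, variance 2 µV²), and Poisson-timed 0.3-s raised-cosine blink
transients (400 µV at AF3/AF4, half at F3/F4, 6 per minute). Condition
effects multiply band variances — the default plants a γ-power contrast
across the three valence conditions — so the analytic DE difference
between conditions is $\tfrac12\ln(\text{ratio})$ when the background is
off, and the generator emits ground-truth blink windows for artifact
tests. This is a feature-level emulation, not a biophysical one: no
dipole/forward modelling, no channel covariance structure, no
non-stationarity beyond condition changes. Passing tests therefore show
the pipeline recovers planted spectral structure, not that it handles
every property of real EEG.

Both generators are seed-deterministic (same config + seed ⇒ identical
output), and seeds are single config values propagated everywhere.

## Problem sizes and runtime choices

The test suite runs the full property checks at sizes chosen to finish in
well under a minute on one core while keeping power: ANOVA oracle
equivalence on balanced designs up to 3×2×8 with 10 subjects/cell;
planted-effect recovery and between-factor type-I rates over 200 simulated
cohorts of 36 participants (3 within-categories, Δ = 2 latent points,
noise SD 1); DE analytic checks on 60-second signals; classifier chance
checks on 600 label-shuffled epochs; separability and monotone-trend
checks on generated recordings of a few minutes. The acceptance script is
deterministic and runs in seconds.

## File formats

Ratings travel as long-format CSV (one row per participant × stimulus)
with the documented column schema; wide formats are out of scope since the
long form composes directly with grouped statistics. EEG travels as
delimited CSV (samples in rows, channels in columns, one-line header of
channel labels) with a trial sidecar CSV (`trial_id, stimulus_id,
t_start_s, t_end_s`); condition labels are decoded from the stimulus
filename grammar. No EDF reader is bundled; the delimited format is the
package's supported interchange, and channel order is canonicalized to the
montage whenever the labels match it. Stimulus filenames are
case-sensitive on the valence word and case-insensitive on the `.MP4`
extension. Configuration is a single YAML file merged over
`default_config()`.

## Known limitations

- Cohort-level published statistics (ANOVA F values, descriptive means,
  absolute recognition accuracies) cannot be reproduced because the raw
  per-participant data are unpublished; the package verifies everything
  that is derivable from the printed tables and covers the rest with
  property-based checks against its own generators.
- The ANOVA uses sequential sums of squares for unbalanced designs and
  offers no sphericity correction.
- Simple-effect error terms assume homogeneity across slices (the pooled
  split-plot convention); heterogeneous-variance alternatives are not
  implemented.
- Artifact screening is threshold-based; ocular/muscle correction by ICA
  or regression is out of scope.
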