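---
title: "Methods: network-based sleep-wake staging from multi-region LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based sleep-wake staging from multi-region LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(electosleep)
```

This vignette is the package's account of its science: the models it fits,
the assumptions they make, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical choices made where more than one implementation
was defensible.

## 1. The problem

Rodent sleep is scored in three states. Wake shows low-amplitude,
mixed-frequency LFP with high muscle tone; NREM sleep shows high-amplitude
1–4 Hz (delta) activity with low tone; REM sleep shows 6–12 Hz (theta) and
higher-frequency activity with muscle atonia. The EMG is what
conventionally disambiguates wake from REM, since their cortical spectra
are similar. This package classifies states from the *network* of LFP
features alone — within-region power plus between-region synchrony across
an 8-region montage — so that staging survives EMG failure and applies to
recordings that never had an EMG.

## 2. Feature extraction

Channels are screened for saturation, and outlying samples are flagged
where the 30 Hz high-passed signal exceeds 20 median absolute deviations
of that channel (raw MAD, no normal-consistency constant; a constant
channel flags nothing but is reported suspect). Any 2 s window containing
a flagged sample in any LFP channel is dropped from analysis rather than
interpolated — the conservative choice, since artifact energy leaks across
the whole window's spectrum. Same-region channels are averaged sample-wise.

Each 2 s window is then transformed with Welch's method: 512-sample Hann
segments at 50% overlap (six per window), cross-spectra averaged per
ordered region pair, and the **magnitude** of the averaged complex
cross-spectrum stored. Three choices deserve notice:

* **Segment length 512.** At 1 kHz this gives a bin spacing of
  1000/512 = 1.953 Hz, and exactly 29 bins (k = 0…28) fall at or below
  54.7 Hz, reproducing the published feature grid. The grid starts at the
  DC bin, which is near zero after acquisition high-pass filtering.
* **Magnitude, not coherence.** The synchrony statistic is the magnitude
  of the averaged cross-spectral density — not coherence (which normalizes
  away amplitude) and not the real part (which can be negative). This
  keeps every feature non-negative, which the non-negative decoder of the
  classifier requires.
* **Estimator floor.** For truly independent signals the averaged
  cross-spectrum magnitude does not reach zero: with m effectively
  independent segments its expectation is ≈ √(π/4)/√m of the geometric
  mean power, ≈ 0.38 at six half-overlapping segments. Tests therefore
  validate the estimator against an independent direct-FFT oracle rather
  than against an unattainable zero.

Features are normalized by a single scalar per (subject, recording): the
median over all valid windows, region pairs and frequencies. One scalar —
rather than per-feature normalization — preserves the relative scale of
bands and pairs, and makes the features invariant to overall gain
(electrode impedance, amplifier settings) without reshaping spectra. A
per-feature variant is deliberately not the default. The full 8 × 8 × 29
tensor flattens, both symmetric copies retained, to d = 1856 features per
window.

## 3. EMG-informed labeling (training labels)

Where an EMG exists, training labels come from 2-D state maps: map 1 plots
per-window EMG power (sum over periodogram bins in 30–60 plus 60–250 Hz)
against the RMS of a reference region's trace; map 2 plots the band-power
ratios (0.5–4.5)/(0.5–9) Hz versus (0.5–20)/(0.5–55) Hz. These quantities
use a full-window 2000-sample periodogram (0.5 Hz resolution) because the
0.5 Hz band edges are not representable on the 1.953 Hz classifier grid.
Wake is the high-EMG cluster; of the low-EMG clusters, NREM has high and
REM low LFP RMS; map 2's high-delta cluster refines NREM membership only —
wake and REM mix in its lower cluster, so it cannot separate them, and a
window must satisfy both maps to be labeled NREM. Points outside the
polygons stay unlabeled, and ambiguous overlaps resolve by the priority
NREM > WAKE > REM.

The interactive polygon drawing of the original workflow is replaced by a
JSON polygon format plus an automatic initializer: 3-means clustering of
the log-scaled map-1 coordinates, seeded deterministically, with tiny
clusters (< 10 members, typically artifact windows) shed and the hull drawn
around each cluster's central 90%. A segment is marked unlabelable when
three clusters do not explain > 80% of the coordinate variance. Point-in-
polygon uses the even–odd rule with boundary points counted inside, so
results are orientation-independent and deterministic. On the default
synthetic cohort the automatic labeler leaves ~12–15% of windows unlabeled
and agrees with ground truth on ≥ 95% of labeled windows per state —
comparable to the inter-rater regime the labels are meant to stand in for.
Cohen's kappa quantifies agreement between any two label tracks.

## 4. The supervised autoencoder

The classifier minimizes, per labeled window,

$$\mathcal{L}\big(C(Ax+b),\,y\big) \;+\; \mu\,\lVert H\,\mathrm{softplus}(Ax+b) - x \rVert .$$

The encoder is deliberately linear-plus-nonlinearity: 32 latent scores,
of which the first three drive the state logits through the diagonal
3-row matrix C, while all 32 are rectified by softplus and decoded by the
entrywise non-negative H. Rows of H are non-negative rank-1
region × region × frequency factors; rows 1–3 are the supervised factors
and directly show which power/synchrony features the classifier uses for
each state.

Numerical choices (all exposed in `sae_config()`):

* **Reconstruction norm.** The objective is implemented with the plain
  Euclidean norm exactly as written, not its square; the squared variant
  (the usual NMF convention) is available via `recon_norm = "l2sq"`.
* **Optimizer.** Adam, learning rate 10⁻³, batch 256, up to a few hundred
  epochs; unspecified in the source method, chosen for robustness at desk
  scale. Gradients are analytic (hand-derived) and tested against central
  finite differences to < 10⁻⁴ relative error.
* **Non-negativity** of H by projection: entries clamped at zero after
  every optimizer step, the simplest projection satisfying the constraint.
  The invariant H ≥ 0 is asserted in tests after training.
* **Initialization**: A and H from small-variance (σ = 0.01) Gaussians (H
  clamped at init), b = 0, C's three trainable diagonal entries start
  at 1. Everything is seeded; two fits with the same data, config and seed
  are bit-identical.
* **Unlabeled windows** are excluded from both objective terms by default,
  and the cross-entropy is unweighted (balanced accuracy is the reported
  metric, but the loss follows the written objective).
* **Early stopping**, when a validation set is given, tracks validation
  balanced accuracy with patience 20 — accuracy rather than loss, because
  model selection in the surrounding protocol is accuracy-based.
* **Ties** in the predicted softmax resolve by state order
  (WAKE < NREM < REM), making `predict` deterministic.

Model selection uses leave-one-mouse-out nested cross-validation: each
mouse in turn is the outer test subject; the remaining mice are shuffled
three times into train/validation splits (6/2 when eight remain, otherwise
all-but-one/one) to score each μ on the grid {10⁻¹, 10⁻², 10⁻³} by mean
validation balanced accuracy; the winning μ is refit on the outer training
set and scored on the test mouse; after all folds, the grid value with the
best pooled inner score is refit on every mouse as the final model.
Single-region variants use the identical machinery on the 29 within-region
power features of one region.

## 5. Hypnogram smoothing and architecture

The SAE's per-window softmax probabilities serve directly as emission
likelihoods (no division by a prior — the smoothing is defined on the
classifier's output probabilities). A top-k list-Viterbi decoder under an
add-one-smoothed empirical transition matrix returns the k = 10 best state
sequences; the smoothed label track is the top-1 path, and the fraction of
the k paths agreeing with it at each window is reported as a per-window
confidence. Add-one smoothing keeps rare transitions (REM→WAKE)
representable; the initial distribution is the transition matrix's
stationary distribution, the neutral choice for long recordings; unlabeled
windows get uniform emissions so gaps are bridged by the transition model.
How the k paths should combine into final labels is not fixed by the
source description; top-1 with an agreement confidence is the minimal
reading and is recorded as a package decision. The top-1 path provably
never scores below the raw argmax sequence, and tests verify the decoder
against exhaustive enumeration on short instances.

Architecture statistics decompose the labeled windows into maximal
same-state runs (bouts); UNKNOWN windows break runs and are excluded from
the denominator, so statistics are invariant to unlabeled padding. Percent
time, bout counts, and mean/median bout durations are reported per state.

## 6. Group comparisons

Within a state, each subject contributes one vector: the mean feature
vector over that state's valid windows. Two groups are compared by 1856
per-feature two-sided t-tests — Welch's unequal-variance form, the robust
default where the source method states only "independent t-tests" — and
the p-values are combined into a single headline value with the corrected
harmonic mean p-value (HMP): ψ = (Σw)/(Σw/p), and the headline p is the
upper tail of 1/ψ under the Landau distribution with location
log L + 0.874367 and scale π/2, the asymptotically exact reference law for
the mean of L reciprocal uniform p-values. The Landau tail is computed by
direct numerical quadrature of its integral representations (density from
the characteristic function below the mode; an analytically integrated
tail form above it); its calibration was verified by simulation (null
familywise error ≈ 4.6% at α = 0.05 for both L = 50 and L = 1856) and
against an independent stable-distribution implementation at frozen probe
points. The HMP is robust to dependence between tests — essential here,
since neighboring frequency bins are strongly correlated. Individual
features are displayed at unadjusted α = 0.01 with the sign of the mean
difference, independent of the headline HMP; this mask deliberately
controls nothing — it is a visualization threshold, and the headline p is
the inferential quantity.

## 7. The synthetic cohort generator

No recordings ship with the method, so the generator is a first-class,
tested module that encodes exactly the structure the classifier assumes:

* A three-state Markov chain at 2 s resolution, self-transition-heavy
  (diagonal ≈ 0.96–0.98) with REM entered only from NREM, started from its
  stationary distribution. State changes land exactly on window
  boundaries; windows with mixed states are not modeled (the 2 s window
  was chosen in the source protocol to minimize multi-label windows).
* Per state, band-limited Gaussian components — not pure sinusoids, so
  Welch estimates carry realistic variance: NREM delta (1–4 Hz, amplitude
  3.0, weighted toward cortex and ventral hippocampus), REM theta/beta/low-
  gamma (6–12, 18–26, 42–50 Hz at 1.6/0.9/0.7), wake a weak broad 3–17 Hz
  component over a unit broadband floor. Each component mixes a
  region-independent trace with a shared across-region trace weighted by
  `shared_component_gain`, so off-diagonal synchrony rises monotonically
  with the gain and vanishes (to estimator floor) at zero.
* EMG as 30–250 Hz band-limited noise with state RMS 2.0/0.5/0.1
  (wake/NREM/REM) — muscle tone is the only EMG property the labeler uses.
* Per-(mouse, region) multiplicative log-normal gains (σ = 0.2), the
  between-subject scale variation that median normalization must remove,
  and isolated artifact samples (0.5/min/channel, 40 × MAD) that the
  outlier mask must catch.

Amplitudes are generator conventions, not claims about mouse biology: the
source descriptions are qualitative, so the exact values are free
parameters fixed once at what produces clearly state-typical spectra.
Defaults are desk-scale — 600 s per mouse at 1 kHz, six to nine mice — so
a full simulate→features→train→evaluate cycle runs in minutes on one CPU;
all sizes are configurable upward. What passing tests on this cohort
show is that every algorithmic stage is correct and that the pipeline
recovers planted structure (≥ 85% held-out balanced accuracy, delta-band
NREM factor, multiregion ≥ single-region); what they cannot show is
performance on real LFP, whose spectra are 1/f, nonstationary within
states, and corrupted by correlated artifacts none of which the generator
emulates. Real-data accuracy claims require real recordings.

## 8. Known limitations

* The generator's states are spectrally stationary within windows and
  cleanly separable; real transitional epochs (drowsiness, REM entry) will
  be harder than anything tested here.
* The corrected HMP's reference law is asymptotic in L; for very small
  test families (L < ~10) the correction is approximate (the raw HMP and
  the frozen-probe tests cover this regime).
* Polygon auto-initialization assumes three clusters exist in a segment;
  segments dominated by a single state are correctly refused rather than
  guessed at.
* Model serialization is plain JSON — portable and diffable, but not
  suited to models far larger than this architecture.
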