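---
title: "Decoding 3D arm trajectories from ECoG band-power envelopes: models and methods"
author: "ecogtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding 3D arm trajectories from ECoG band-power envelopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogtraj)
```

## The decoding model

`ecogtraj` implements a continuous decoder of arm kinematics from
electrocorticographic (ECoG) recordings.  The signal representation is the
set of within-band amplitude envelopes of the seven classical sensorimotor
rhythms (delta 0.5–4 Hz, theta 4–8 Hz, alpha 8–14 Hz, beta1 14–20 Hz,
beta2 20–30 Hz, gamma1 30–50 Hz, gamma2 50–90 Hz), extracted per channel
by a causal chain:

1. common average reference across channels,
2. 4th-order Butterworth band-pass per rhythm,
3. full-wave rectification,
4. 2nd-order Butterworth low-pass at 2.2 Hz,
5. decimation to 100 Hz,
6. z-scoring (population standard deviation, 1/N) with stored constants.

Each kinematic variable $Y(t)$ — the four joint angles $q_1\ldots q_4$ of
a shoulder–elbow model, or an elbow/wrist coordinate — is modelled as a
linear function of the past second of every envelope feature $z_i$:

$$ Y(t) \;=\; w_0 + \sum_{i=1}^{n\cdot 7}\ \sum_{j=1}^{m} w_{ij}\,
   z_i(t - j\,\Delta t), \qquad m = 100,\ \Delta t = 0.01\ \mathrm{s}. $$

Lags run over strictly past samples ($j \ge 1$); the decoder is causal by
construction, and so is the preprocessing, so the whole pipeline could run
online.  A zero-phase filtering mode (`filterMode = "zero-phase"`) exists
for offline exploration only.

The weights are fitted by sparse Bayesian linear regression with automatic
relevance determination (ARD): a zero-mean Gaussian prior with one
precision $\alpha_k$ per column, Gaussian noise with precision $\beta$,
and evidence-approximation fixed-point updates

$$ \Sigma = (\beta X^\top X + A)^{-1},\quad m = \beta\,\Sigma X^\top y,\quad
   \gamma_k = 1 - \alpha_k \Sigma_{kk},\quad
   \alpha_k \leftarrow \gamma_k / m_k^2,\quad
   \beta \leftarrow (N - \textstyle\sum_k \gamma_k)\,/\,\lVert y - Xm\rVert^2 . $$

Columns whose $\alpha_k$ exceeds `pruneThreshold` ($10^{12}$) leave the
active set with weight exactly zero, which keeps the linear algebra at
active-set size.  When the active set is larger than the number of rows,
the posterior moments are computed through the Woodbury (dual) form, so
the 10,000-column lagged designs of a 15-channel montage stay tractable
on one CPU.  The bias $w_0$ is an unpenalized coefficient, implemented by
centering the feature columns and target over the training rows; it is
never pruned.

Three numerical safeguards extend the bare update equations:

* **Noise-precision cap.**  On interpolating designs (columns ≫ rows) the
  raw $\beta$ update diverges as the training residual collapses, which
  freezes the $\alpha$ dynamics.  `betaCapRel` bounds the implied
  training signal-to-noise ratio at $\beta\,\mathrm{var}(y) \le 10^8$ —
  far above any physiological regime, and verified not to disturb
  ordinary-least-squares equivalence on well-posed problems
  (agreement to $\sim 10^{-9}$ relative).
* **Ill-conditioning jitter** of $10^{-10}\,\mathrm{tr}/K$ on the
  posterior-precision diagonal before each solve.
* **Relevance audit at convergence.**  The fixed-point iteration can
  stall at spurious finite $\alpha$ for columns whose evidence support is
  marginal.  Before declaring convergence the fit evaluates the
  per-column statistics $s_k, q_k$ (the sparsity/quality decomposition of
  the marginal likelihood) and drops columns whose retention buys less
  than 0.5 nat of log evidence — under a pure-noise column the evidence
  gain is $\tfrac12(r - 1 - \log r)$ with $r = q_k^2/s_k \sim \chi^2_1$,
  so roughly a third of null columns sit barely above the $r = 1$
  inclusion boundary and would otherwise be kept with tiny weights.
  The margin removes those while leaving genuinely supported columns
  (for which $r$ is orders of magnitude larger) untouched.

**Early stopping.**  Training terminates just before over-fitting: the
chronologically last `validationFraction` (default 0.1) of design rows is
held out, fitting stops after `patience` (default 3) consecutive
validation-MSE increases, and the snapshot with the best validation MSE
is returned.  The holdout is chronological, not random, because envelope
time series are strongly serially correlated — a random holdout would be
quasi-duplicated in the training rows and never rise.

## Trial segmentation

Movement trials are delimited where the elbow's tangential velocity
crosses 5% of maximum.  The per-trial-maximum rule is circular on its own
(the maximum needs boundaries), so segmentation is two-pass: candidate
bursts above 5% of the session maximum, merged across gaps shorter than
`minGap` (1 s), then each burst's boundaries refined against its own
maximum.  Intervals shorter than `minDuration` (2 s — task cycles run
15–20 s, so anything briefer is a twitch) are dropped.  Crossings are
resolved at sample resolution; the first crossing wins.  Speed itself is
a central-difference derivative smoothed by a causal 2nd-order 5 Hz
low-pass: raw differentiation of 100 Hz markers amplifies noise, and
reach dynamics live below ~2 Hz.  Trials in which a marker sweeps more
than 0.20 m along the sagittal axis can be excluded
(`excludeByDisplacement`), mirroring the torso-sway exclusion rule of the
source experiment.

## Kinematic model

The arm is a 4-DOF shoulder–elbow chain in a frame with x lateral (to the
patient's left), y anterior, z superior.  The zero posture has the arm
hanging along $-z$, palm anterior, elbow extended: $q_1 = q_2 = q_3 = 0$,
$q_4 = \pi$.  Rotations compose as $R = R_y(q_1) R_x(q_2) R_z(q_3)$;
because the upper-arm rest axis is $-z$, $R_z(q_3)$ leaves the elbow
invariant and acts only on the forearm plane — matching the
external/internal-rotation reading of $q_3$.  The forearm direction in
the upper-arm frame is $(0, \sin q_4, \cos q_4)$, so $q_4 = \pi$ is full
extension.  The published description fixes only the zero posture, not
the Euler sequence; this composition is an explicit package convention,
validated by the zero-posture anchor and by round-trip identities
(FK∘IK and IK∘FK to $10^{-9}$ away from singularities).

At full elbow extension $q_3$ is geometrically indeterminate; inverse
kinematics carries the last well-defined value forward (0 at series
start) and reports how many samples were affected.  Angle ranges are
$q_2 \in [-\pi/2, \pi/2]$, $q_1, q_3 \in (-\pi, \pi]$, with atan2-based
extraction fixing branch cuts.  Trajectories rendered from decoded angles
through forward kinematics satisfy the segment lengths exactly whatever
the decoder error — the property that makes angle-space decoding
attractive for 3D reconstruction.

## Evaluation

Evaluation is leave-one-out cross-validation over trials: for held-out
trial $k$, one decoder per target variable is fitted on all other trials'
samples and scored on trial $k$ by Pearson correlation (CC) and
normalized RMSE.  Scores are aggregated as mean ± SEM (sample sd /
$\sqrt{n}$) across trials.  Two leakage barriers are built in: z-scoring
constants are computed on training-trial samples only (default
`normalization = "foldwise"`; a whole-session mode exists and is
labelled), and design rows require their full lag history inside the
valid mask, so no row straddles a trial boundary and no history reaches
into the held-out trial.  Corrupting every sample of the held-out trial
provably leaves the training-fold models bit-identical (this is asserted
in the test suite).  One caveat is inherent to causal IIR filtering of
the continuous raw signal: a change to the *raw* signal inside one trial
propagates forward in time into later envelope samples.  The leakage
audit therefore lives at the decoder level — envelopes and targets —
which is where statistical leakage would matter for the cross-validated
scores.

The nRMSE normalizer is the actual trajectory's within-trial range
(max − min), the common convention in trajectory decoding; an
sd-normalized variant is available by flag.  Pearson CC of a constant
prediction is undefined and is reported as missing, never as zero;
aggregate means are taken over non-missing trials.  Per-band evaluation
(`perBandCV`) repeats the whole procedure with the design restricted to
one rhythm's features, quantifying each band's individual contribution.

## The synthetic-session generator

No recordings are distributed with the source experiment, so validation
runs end to end on synthetic sessions that emulate its structure: a
seated subject repeatedly repositions three blocks clockwise around the
corners of a 25 cm × 25 cm square, one self-paced cycle of three
transports per trial (~17 s), with still rest epochs between cycles.
Kinematics are generated as minimum-jerk interpolations *in joint-angle
space* between inverse-kinematics key postures (reach above the block,
lower, grasp, lift, arced carry, lower, release), which guarantees
IK-consistent, singularity-free trajectories; markers then come from
forward kinematics, so segment lengths hold exactly.  The three blocks
differ in height (0.10, 0.04, 0.14 m — a parallelepiped, a cube and a
cylinder), grasps happen on the block tops, and carries arc 0.15 m above
the plane: this vertical structure is what makes the z coordinate a
meaningful decoding target rather than a degenerate constant.

The neural signal is the generative inverse of the analysis chain:
per (channel, band), a unit-variance band-limited carrier (filtered noise
by default; a band tone as an option) is amplitude-modulated by an
envelope, channels sum their bands plus broadband 1/f noise.  For an
*informative* pair the envelope is a positive affine image of a sparse
random combination of the ten standardized kinematic variables evaluated
`trueLag` = 0.15 s later — the cortical envelope *leads* the movement, so
a strictly-past-lag decoder can use it.  Envelope noise is Gaussian in
the envelope domain at variance ratio `envelopeSnr`; negative excursions
are clipped at zero and counted.  Defaults (60 channels, 9 cycles,
`informativeFraction` 0.2, modulation depth 0.4, pink-noise amplitude
0.1) are fixed study conditions, not tuning knobs.

Two physical limits of this signal model are worth knowing when reading
test results.  First, rectify-and-smooth envelope extraction of a
*band-noise* carrier has irreducible estimation noise of relative order
$1/\sqrt{2 B T}$ (bandwidth $B$, smoother time constant $T$) that no
envelope-SNR setting removes; it is most severe for the narrow
low-frequency bands and for fast envelope components.  Decoding accuracy
of kinematic components without slow spectral content (notably wrist z)
is therefore bounded below 1 even at infinite envelope SNR — as in real
recordings.  Second, the delta band cannot carry its envelope
undistorted: any in-band carrier puts its rectification harmonic
($2 f_c < 8$ Hz) and part of the modulation sidebands inside 0.5–4 Hz
itself, so envelope recovery there is held to a looser bound (0.90
instead of 0.95) in the tests.  Sinusoid carriers are placed at
max(geometric band center, 0.8 × upper edge) so the harmonic clears the
2.2 Hz smoother wherever possible.

What the generator does **not** emulate: epileptiform or artifactual
activity, baseline drift and electrode noise nonstationarity, torso-sway
marker artifacts (beyond the constructed displacement-exclusion cases),
volume conduction between channels, or any nonlinearity between cortex
and kinematics.  Passing tests on these data show that the pipeline
recovers what its own model class can express — a correctness check of
the machinery, not evidence about decoding accuracy on real cortex.

## Problem sizes and numerical choices in the shipped experiments

The validation experiments are scaled so the whole suite runs comfortably
on one CPU; all sizes are package choices, stated here once:

* End-to-end recovery: 15 channels, 5 trials × 15 s, envelope SNR 10,
  decoder at full $m = 100$ lags with training rows thinned to every 8th
  sample (`designStride = 8`; envelopes are 2.2 Hz-smoothed, so 80 ms row
  spacing discards almost no information — measured CC changes < 0.01
  against stride 2) and `maxIter = 25`.
* SNR sweep: the same montage with 3 trials per session, wrist-coordinate
  targets, envelope SNR 10 / 1 / 0; five seeds per level in the test
  suite, three in the acceptance script.
* Sparse-truth recovery: 2 true + 18 null features, n = 200,
  σ = 0.01, run to convergence without a validation holdout.
* Kinematic round-trips: 10,000 uniform random postures with
  $q_4 < \pi - 0.05$.

Determinism: a fixed `seed` makes sessions bit-identical, and the fitting
path contains no random numbers, so simulate → evaluate twice reproduces
every reported figure exactly.

## Known limitations

* The evidence fixed point is not guaranteed monotone in pathological
  cases; the per-iteration trace (evidence, train/validation MSE, active
  count) is stored in every model for inspection.
* Weight-*mass* concentration on truly informative (channel, band) pairs
  is strong in enrichment terms (≈ 9× column share in the shipped
  experiment) but does not reach a majority of total $|w|$ mass when the
  design interpolates — many tiny residual weights survive early
  stopping.  Interpret `sparsityReport` output as a ranking, not a
  partition.
* The common average reference mixes $-1/n_\mathrm{ch}$ of every channel
  into all others; with few channels this leaks informative envelopes
  across the montage, which is physically faithful but blurs per-channel
  attribution in small synthetic montages.
* EDF support covers the standard 16-bit format with one sampling rate
  across channels — the subset the pipeline needs — not EDF+ annotations
  or variable-rate records.
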