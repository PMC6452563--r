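---
title: "Selecting HD-sEMG channels by multiclass CSP and mutual information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting HD-sEMG channels by multiclass CSP and mutual information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdsemgsel)
```

## The problem

A high-density surface-EMG grid — here 64 monopolar channels on a 5 × 13
array with 8 mm pitch, sampled at 5120 Hz — records the spatial pattern of
muscle activation during upper-arm motions. The spatial dimension is what
makes subtle motion classes separable and what makes the recording robust
to electrode shift, but a 64-channel stream overwhelms an embedded
prosthesis controller. The question this package answers: **which few
physical electrodes carry the class information**, so that the rest of the
grid can be switched off without giving up accuracy?

The key property of the approach is that the channel score depends only on
the per-class second-order statistics of the signal, not on the downstream
feature set or classifier: selection is decided once, from covariances, and
any feature/classifier combination can be used afterwards.

## The model

Let $x(t) \in \mathbb{R}^N$ be the channel vector and $c \in \{c_1,\dots,c_M\}$
the motion label. Within a class the signal is modelled as zero-mean with
covariance $\Sigma_i$; a spatial filter $\omega$ produces the scalar output
$y = \omega^\top x$ with class-conditional variance
$v_i = \omega^\top \Sigma_i \omega$.

**Multiclass CSP by joint diagonalization.** Classical CSP solves the
two-class problem: $W$ simultaneously diagonalizes $\Sigma_1, \Sigma_2$ with
$D_1 + D_2 = I$, so the leading filters maximize class-1 variance while
minimizing class-2 variance. With $M > 2$ classes no exact joint
diagonalizer exists in general; `ffdiag_jad()` finds an approximate one in
two steps:

1. whiten the prior-weighted mean covariance
   $\bar\Sigma = \sum_i p_i \Sigma_i$ exactly, which generalizes the
   two-class identity to $\sum_i p_i D_i = I$ and fixes the scaling the MI
   formula below requires;
2. find an orthogonal $Q$ by Jacobi sweeps with the closed-form rotation
   angle that minimizes the summed squared off-diagonal entries of all $M$
   whitened matrices. Each rotation minimizes its own 2 × 2 contribution,
   so the off-diagonal criterion is non-increasing by construction — the
   property the `offdiag_history` field records and the tests assert.

For $M = 2$ this reproduces classical CSP filters exactly (the tests verify
per-filter principal angles below $10^{-6}$ against the generalized
eigendecomposition route).

**Mutual information of a filter.** Under the class-conditional Gaussian
model, $y$ is marginally a zero-mean Gaussian mixture. With
$H(y \mid c) = \sum_i p_i \tfrac12\ln(2\pi e\, v_i)$ and the marginal
entropy approximated through negentropy,
$H(y) \approx \tfrac12\ln(2\pi e\,\sigma_y^2) - J(y)$,
$J(y) \approx k_3^2/12 + k_4^2/48$, one gets (the mixture is symmetric, so
$k_3 = 0$; scaling $\omega$ to $\sigma_y^2 = \omega^\top\bar\Sigma\,\omega = 1$
makes $k_4 = 3(\sum_i p_i v_i^2 - 1)$):

$$I(c, y) \;=\; -\sum_i p_i \ln\sqrt{v_i}
\;-\; \frac{3}{16}\Bigl(\sum_i p_i v_i^2 - 1\Bigr)^{\!2}.$$

Both terms are cheap functions of the $v_i$, so every filter column can be
scored in microseconds. The truncated cumulant expansion is accurate in the
moderate-contrast regime (class variances within roughly $[0.5, 2]$ of the
mixture variance; validated against a $10^6$-sample Monte-Carlo mixture
entropy to well under 0.05 nats). For extreme variance spreads the quartic
term dominates and the approximation can go negative even though true MI is
large; such values are clamped to zero with a warning. This is a real
limitation of the formula, not of the implementation — it is one reason the
synthetic generator (below) is built to live in the moderate-contrast
regime, as real grid recordings over an always-active muscle do.

An alternative per-eigenvalue score `score_eigenvalue()` maps a class
eigenvalue $\lambda \in (0,1)$ to
$\max\!\bigl(\lambda,\, 1/(1 + (M-1)^2 \lambda/(1-\lambda))\bigr)$, which
treats multiplicatively inverse variance ratios as equally discriminative,
has its fixed point at the uninformative value $\lambda = 1/M$, and reduces
to $\max(\lambda, 1-\lambda)$ for $M = 2$. The printed sources for this map
are typographically ambiguous; this reconstruction is the one under which
those stated properties hold, and a literal variant is kept behind
`form = "literal"` for comparison.

**Channel mapping.** Selection must return electrodes, not filters. Each
ranked filter column nominates the channel holding its maximum absolute
weight; duplicates are skipped, consuming further columns until $L'$
distinct electrodes are collected. How a column "names" a channel is a
genuine design choice — the peak-weight reading is the simplest consistent
one, and an aggregate |weight|-mass variant is available
(`mapping = "mass"`) for sensitivity analysis. Increasing $L'$ always
extends the previous selection (prefix property), and the whole path from
covariances to selection is deterministic.

## Features and classification

Each selected channel in each analysis window is decomposed by a full
wavelet-packet tree (sym5, depth $J = 4$, giving $2^J = 16$ uniform
subbands); the feature is $\ln(\mathrm{RMS})$ of each terminal node's
coefficients, floored at $10^{-12}$ so silent channels stay finite.
Boundary handling is periodized, which makes the filter bank exactly
orthonormal — total coefficient energy equals window energy to $10^{-9}$
relative, asserted against an explicit circulant-matrix oracle. Terminal
nodes are reported in frequency order (natural Paley order re-permuted by
the binary-reflected Gray code); `order = "natural"` is available.

Classification is deliberately standard: stratified $k$-fold cross
validation (default $k = 5$), features standardized with training-fold
statistics only, and four classifier families — RBF-SVM (cost 1), LDA,
KNN ($k = 5$), and a single-hidden-layer neural network (32 units, weight
decay $10^{-3}$; decay substitutes for early stopping, which `nnet` does
not provide). Kernel, neighbour count and architecture are exposed
defaults, chosen as the field's conventional baselines; the selection
method upstream does not depend on them.

## Analysis-window choice

Motions last 2 s; the analysis window within a motion is a free parameter.
The default is 0.25 s advanced by 0.125 s — short enough to yield 15
windows per motion (75 per class at 5 repetitions, comfortably feeding
5-fold CV), long enough that a 16-subband RMS estimate per channel is
stable. Windows never cross motion boundaries. Raw recordings can
optionally be band-passed (4th-order zero-phase Butterworth, 20–450 Hz)
before windowing; this is off by default since the synthetic sources are
already band-limited.

## The synthetic generator

No public HD-sEMG corpus matches the acquisition protocol this package
targets, so `generate_recording()` simulates it, and every end-to-end claim
in the tests is a claim about this generator. Its design mirrors what a
dense grid over an active muscle sees, in three additive parts plus noise:

* a **spatially smooth background field** (distant motor units; Gaussian
  spatial covariance, range 3 pitches, variance 0.5) common to all motions;
* **channel-local activity** (superficial units under each electrode;
  spatially white, variance 0.5), also common to all motions;
* a **class-specific source** mixed through a Gaussian blob of gains
  (spread 1.25 pitches) centred on the class's activation focus, amplitude
  0.7 — a modest recruitment increment over the background;
* **white sensor noise** at 10 dB SNR (mean channel signal power over noise
  power), everywhere including the unlabelled 0.5 s rest gaps.

All sources are stationary band-limited Gaussian processes (ideal band-pass
of white noise, 20–450 Hz, unit variance per motion interval). By default
8 motion classes share 5 activation foci: classes beyond the fifth reuse a
focus with the source amplitude stepped up by 1.6× (≈4 dB) per reuse. This
reflects the targeted protocol — motions of one muscle at different angles
activate the same regions at different intensities — and it is what makes a
5-electrode subset sufficient in principle. The 1.6 step makes an intensity
grade a ≈2-standard-deviation contrast in a single window's log-RMS at the
focus electrode, i.e. clearly but not trivially separable.

Two design points deserve emphasis:

* **The background is full-rank on purpose.** If class sources stood over
  near-silence (a low-rank background), an optimal spatial filter could
  null the background entirely and reach variance contrasts of 20× and
  more — a regime that is physiologically implausible for a grid over an
  always-active muscle and where the cumulant-truncated MI formula breaks
  down. The smooth-field + channel-local decomposition cannot be nulled by
  any filter, keeping contrasts moderate.
* **`generate_covariance_set()` is the analytic oracle.** It returns the
  exact covariances $K_{bg} + G_c G_c^\top + \sigma^2 I$ implied by the
  mixing model, bypassing simulation; spatial and information-theoretic
  stages are tested against it exactly, and empirical covariances from
  simulated recordings are tested to converge to it as duration grows.

What the generator does **not** emulate: motor-unit action-potential
waveforms and firing statistics, amplitude-modulation envelopes within a
motion, electrode-skin impedance drift, motion artifacts, or electrode
shift between sessions. Passing end-to-end tests therefore demonstrate the
pipeline's correctness and its behaviour under controlled spatial class
structure — not performance on any particular laboratory recording.

## Numerical choices

* Whitening adds a ridge of $10^{-9}\,\mathrm{tr}(\Sigma)/N$ only when the
  condition number exceeds $10^{12}$; singular inputs fail with a message
  suggesting regularization.
* Filter columns are sign-fixed (largest-|weight| entry positive) and
  eigenvalue ties are broken by original index, so all outputs are
  deterministic.
* Jacobi sweeps stop when the off-diagonal criterion's relative decrease
  falls below $10^{-12}$ (or hits numerical zero); `converged = FALSE` with
  the history attached otherwise.
* MI requires $|\omega^\top\bar\Sigma\,\omega - 1| \le 10^{-6}$ and errors
  otherwise rather than silently rescaling; `scale_filter()` is the
  explicit normalizer.
* Natural logarithms (nats) throughout.
* Fold assignment depends only on (labels, $k$, seed); reruns are
  bit-identical.

## Problem sizes used in the shipped validation

The test suite and `scripts/acceptance.R` run the full method at the
protocol scale (64 channels, 8 classes, 2 s motions at 5120 Hz) but keep
repetition counts modest: 3 repetitions per class for the 20-seed
planted-recovery and null-configuration experiments, the default 5
repetitions for the 5-seed top-5 vs all-64 comparison. These sizes were
chosen so the whole validation completes in minutes on one core while
leaving each class with 72–75 analysis windows, enough for stable
covariances and stratified 5-fold CV.

## Known limitations

* The closed-form MI is a truncated cumulant expansion; outside the
  moderate-contrast regime it under-estimates (and clamps). Ranking by it
  is then unreliable — by construction this does not arise under the
  intended acquisition conditions, but a pathological recording (e.g. a
  detached electrode with huge artifact variance) should be cleaned before
  selection.
* Channel nomination by peak weight assumes a filter's dominant electrode
  is meaningful; for strongly distributed filters the `"mass"` mapping is
  the more honest reading.
* Stratified CV at the window level lets windows of the same motion
  repetition appear in train and test folds; accuracies are therefore
  optimistic relative to a repetition-held-out protocol. This matches the
  conventional evaluation the pipeline mirrors, and the comparison of
  interest (5 channels vs 64) is affected on both sides equally.
* The generator's sources are stationary Gaussians; none of the
  non-stationarity that motivates wavelet features in real EMG is present,
  so the feature stage is validated for correctness, not for superiority
  over alternatives.
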