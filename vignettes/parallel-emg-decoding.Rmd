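---
title: "Parallel multi-joint sEMG intent decoding: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel multi-joint sEMG intent decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgfuse)
```

## The problem and the model

A transhumeral prosthesis user needs to command the elbow, the wrist and
the hand at the same time, but a flat 27-way gesture classifier scales
poorly and can never emit a combination absent from its training data.
`emgfuse` decomposes the decision: three classifiers run in parallel on
the same 30-dimensional feature vector, each solving a 3-class problem
for one joint — Class 1 and Class 2 are the joint's active states
(flexion/extension, supination/pronation, open/close) and Class 3 is
"other motions". Their output triple indexes the 27-class taxonomy
bijectively (`fuse_outputs()`), so each training example informs three
small problems and the fused decoder generalizes to unseen state
combinations by construction. The inverse mapping (`remap_label()`)
assigns each taxonomy member to exactly 9 of the 27 classes per output
class per joint, so balanced 27-class data yields balanced 3-class
training sets.

The assumptions behind this decomposition are that joint activations
leave separable, approximately additive signatures across the electrode
montage, and that a window's feature vector carries enough information
to decide all three joints simultaneously. Neither is guaranteed in
real recordings — deep or co-contracted muscles violate separability —
which is precisely what the offline F1 tables and real-time completion
metrics are designed to quantify.

## Signal segmentation and features

Windows are 150 ms with 100 ms overlap (50 ms step) at 1 kHz, the usual
compromise between feature stability and control latency: window `k`
covers samples `[k·step, k·step + L)` (0-based, half-open) and a
recording yields `floor((n − L)/step) + 1` windows. A window spanning a
class transition takes its modal per-sample label, ties broken toward
the label appearing earliest in the window; recordings of held gestures
make transitions rare, and rest periods carry the first-class `NM`
label so "no motion" is trained like any other class.

Five time-domain features are computed per channel:

* `EMAV = (1/L) Σ_{i=1..L} |x_i|^{p(i)}` and
  `EWL = Σ_{i=2..L} |x_i − x_{i−1}|^{p(i)}` with `p(i) = 0.75` when
  `0.2L ≤ i ≤ 0.8L` (1-based, real-valued inclusive bounds) and `0.50`
  otherwise, emphasizing the window's middle region. A fractional power
  of a signed sample is only defined through the absolute value, so the
  implementation reads the base as `|x|`.
* `SSC = (1/L) Σ_{i=2..L−1} 1[(x_i − x_{i−1})(x_i − x_{i+1}) ≥ τ]`,
  with threshold `τ = 0` by default (no value is conventional for
  clean synthetic signals; it is configurable). Note two deliberate
  literal readings: the `1/L` normalization is kept although SSC is
  classically an unnormalized count (`normalize = FALSE` restores the
  convention), and at `τ = 0` a flat triplet (product exactly zero)
  counts as a sign change because the test is `≥`.
* `RMS = sqrt((1/L) Σ x_i²)` and `VAR = (1/(L−1)) Σ x_i²`. The variance
  is computed without mean subtraction — the standard zero-mean-EMG
  convention, and the literal reading of the defining formula;
  `center = TRUE` enables subtraction for comparison.

Feature vectors are channel-major (five features of channel 1, then
channel 2, …), 30 values for six channels.

## Classifiers

**Logistic regression.** One binary classifier per output class
(one-vs-all), probability `g(θᵀx + θ₀)` with `g` the logistic function,
trained by minimizing the mean-form cross-entropy with an L2 penalty
`(λ/2m)‖θ‖²` on the weights only — the bias is never regularized, and
the mean form makes the implemented gradient the exact derivative of
the implemented cost (verified against finite differences to 1e−6).
The optimizer is a Polack–Ribière nonlinear conjugate-gradient scheme
with a line search based on quadratic/cubic polynomial interpolation
and extrapolation, Wolfe–Powell stopping conditions and slope-ratio
initial step sizes, capped at 150 iterations. Weights start at zero, so
training is deterministic. λ defaults to 1 and matters little on the
well-conditioned standardized features (tests cover λ ∈ {0, 0.01, 1,
100}); the binary decision threshold TH defaults to 0.5 and affects
only explicit binary use, since multi-class prediction takes the
arg-max of the per-class sigmoid scores without normalizing them
(normalizing would not change the arg-max ordering for monotone
reasons). Ties break to the lowest class index.

**LDA.** Closed form: class means `μ_c`, empirical priors `Π_c`, pooled
within-class covariance with the unbiased `m − C` denominator, and
per-class parameters `β_c = Σ⁻¹μ_c`,
`β₀_c = −β_cᵀμ_c/2 + ln Π_c`; prediction is the arg-max of the linear
scores, and the explicit binary form (`β = Σ⁻¹(μ₁−μ₂)`, score ≥ 0 →
class 1) agrees with the two-class arg-max algebraically, which the
tests confirm numerically. A shrinkage ridge `γI` keeps Σ invertible;
γ defaults to `1e−6 × mean(diag(Σ))`, small enough to be inert on
well-conditioned data, and `γ = 0` turns singularity into an
instructive error.

Both backends z-score features with training-set statistics stored in
the model. The probability model is scale-invariant only up to
optimizer conditioning, and standardization makes the conjugate
gradient well behaved; LDA is affine-invariant in exact arithmetic, so
sharing the policy across the three joint classifiers costs nothing
and keeps serialized models uniform. Constant features get unit scale
(they carry no signal either way).

## Offline and real-time evaluation

The 70/30 split is per class and **contiguous by default**: each
class's chronologically first 70 % of windows trains. Overlapping
windows share 100 ms of signal, so a shuffled split would leak test
information into training; the shuffled policy exists (seeded) for
comparison. Train size is `floor(0.7·n)` per class.

Offline metrics: per-class precision/recall/F1 from the confusion
matrix (rows = truth), macro F1 as the unweighted mean, a class with
`p + r = 0` scoring 0, misclassification error `1 − trace/total`, and
row-stochastic normalized confusion matrices (zero-support rows stay
zero with a warning).

The real-time simulator replays an attempt whose intent is known:
decisions are emitted every Δ = 90 ms, each from the most recent full
window, so decision `k` falls at `W + (k−1)Δ` with `W = 150 ms` — a
decision cannot exist before one full window, and onset is the start
of the replayed segment (cue-aligned; no EMG-threshold onset detector).
MST is the time to the first correct fused decision; MCT the time to
the 10th correct decision, counted **cumulatively** — the metric
definitions speak of the 10th correct classification, not of a
consecutive run — with a consecutive mode behind a flag; an attempt
completes iff MCT ≤ 5 s, and MCR is the completed percentage. Failed
attempts contribute no value to mean MCT (the aggregates report the
`n` actually used). With every decision correct, MST = 0.15 s and
MCT = 0.15 + 9 × 0.09 = 0.96 s, the floor values visible in the
synthetic protocol results.

LR and LDA are compared with the two-sided Mann–Whitney U test
(normal approximation, tie-corrected) and the rank-test effect size
η² = Z²/N, N the combined sample size — the common convention among
the candidate formulas (Z²/(N−1) differs negligibly at these sizes).
No continuity correction is applied by default, matching the closed
form η² ≈ 0.726 for fully separated 15-vs-15 samples; a corrected
p-value is available via `continuity = TRUE`. Exact small-sample
enumeration is out of scope.

## The synthetic generator: what it emulates, and what it does not

Human sEMG for this task is not publicly available, so the package
ships a generator that emulates the acquisition protocol: 27 classes ×
4 repetitions, 3 s holds separated by 2 s rests, 6 channels at 1 kHz,
presented in randomized order under a seed. The signal model is
amplitude-modulated Gaussian noise — the standard stochastic EMG
surrogate — with per-class per-channel standard deviation
`baseline_std + snr_scale × A[class, channel]`. The activation matrix
`A` is compositional: each primitive state dominates one channel
(hand open/close → channels 1–2, wrist supination/pronation → 3–4,
elbow flexion/extension → the biceps/triceps channels 5–6) at
amplitude 1, with 10 % cross-talk into the remaining channels — a
realistic bleed level for closely spaced forearm electrodes that makes
the per-joint problems non-trivially coupled; a combined class takes
the element-wise maximum of its primitives' rows and `NM` is all
zeros. Defaults `baseline_std = 0.05` and `snr_scale = 1` represent a
clean recording (dominant-channel SNR of 20:1 in amplitude), chosen
once as the generator's study condition. Optional 20–450 Hz band-pass
shaping imposes an EMG-like spectrum but is off by default because all
five features are amplitude-driven and the shaping slightly distorts
the closed-form amplitude expectations the tests rely on.

What passing tests on this generator demonstrate: the pipeline's
machinery is correct — windowing arithmetic, feature formulas, both
trainers, the fusion bijection, the metric bookkeeping — and the
decoder recovers the generator's class structure essentially perfectly
at the default SNR (held-out fused macro F1 ≥ 0.90 is the acceptance
property; in practice it saturates near 1.0, and accuracy collapses to
chance at `snr_scale = 0`, measured as macro-averaged per-class
accuracy ≈ 1/27, the imbalance-proof chance level). What they do not
demonstrate: performance on real muscle signals, whose
non-stationarity, electrode shift, fatigue, co-contraction and
motor-unit structure the Gaussian surrogate deliberately omits.
Reported human-subject figures for strategies of this family (per-joint
F1 around 90–96 %, mean MCT near 2 s, MCR near 90 %) cannot be
reproduced from synthetic data and are not targets of this package's
tests.

## Numerical choices and degenerate inputs

* Window/step sample counts round to the nearest integer; windows
  shorter than 2 samples, steps of 0, or `overlap ≥ window` are errors,
  as are recordings shorter than one window.
* Feature preconditions (`L ≥ 1/2/3` per feature) raise errors rather
  than returning NA; non-finite features abort training.
* Conjugate-gradient line-search failures fall back to steepest
  descent once; two consecutive failures terminate (the convex LR cost
  in practice converges long before the 150-iteration cap).
* Prediction ties (equal scores) break to the lowest class index in
  both backends, making decisions deterministic.
* Model JSON round-trips at full double precision, so reloaded models
  reproduce decisions exactly.

## Problem sizes used by the test suite

The unit and property tests run scaled-down protocols (1–2 repetitions,
0.5–1 s holds) totalling a few hundred windows each, sized so the full
suite runs in well under a minute; the acceptance checks additionally
train once on the full default protocol (4 repetitions, 3 s holds,
~10,800 windows, seed 1). These sizes are the package's choice of test
conditions; the generator's defaults themselves always remain the full
protocol.

## Known limitations

* The generator's amplitude-coded classes make the task easier than
  real sEMG; conclusions about absolute decoding performance do not
  transfer.
* Only cue-aligned replay is simulated; there is no onset detection,
  and no proportional-velocity control layer.
* The LDA backend assumes a shared covariance across the three output
  classes of each joint; strongly class-dependent covariances would
  favor quadratic discriminants, which are out of scope.
* Frequency-domain and autoregressive features, kernel/ANN baselines,
  and flat 27-way or hierarchical strategies are intentionally not
  implemented.
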