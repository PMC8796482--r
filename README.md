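# emgfuse

Simultaneous elbow–wrist–hand intent decoding from multi-channel surface
electromyography (sEMG), for researchers building pattern-recognition
myoelectric control systems and for anyone who needs a fully synthetic,
reproducible testbed for one.

Conventional myoelectric controllers decode one gesture at a time from a
flat list of classes. `emgfuse` implements a *parallel* strategy instead:
three small classifiers run side by side — an elbow classifier, a wrist
classifier and a hand classifier — each deciding among three output
classes (the joint's two active states, or "other motions"), and their
output triple is fused into one of **27 motion classes**: 6 discrete
motions (elbow flexion F / extension E, hand open O / close C, wrist
supination S / pronation P), 20 combined 2–3 DoF motions (FO, FCS, EOP, …)
and a no-motion class NM. Because the 3×3×3 output triples map bijectively
onto the taxonomy, the fused decoder can emit motion combinations it never
saw during training.

## The pipeline

1. **Windowing** — 150 ms sliding windows with 100 ms overlap over the
   6-channel signal sampled at 1 kHz.
2. **Features** — five time-domain features per channel (30 per window):
   enhanced mean absolute value `EMAV = (1/L) Σ |x_i|^p(i)`, enhanced
   waveform length `EWL = Σ |x_i − x_{i−1}|^p(i)` (with `p(i) = 0.75` in
   the middle 60 % of the window, 0.50 at the edges), slope sign change
   `SSC = (1/L) Σ 1[(x_i−x_{i−1})(x_i−x_{i+1}) ≥ τ]`, root mean square,
   and variance `(1/(L−1)) Σ x_i²`.
3. **Classifiers** — a from-scratch one-vs-all L2-regularized logistic
   regression, trained by Polack–Ribière nonlinear conjugate gradients
   (quadratic/cubic line search, Wolfe–Powell conditions, ≤150
   iterations), and a closed-form one-vs-all LDA
   (`β_c = Σ⁻¹ μ_c`, `β₀_c = −β_cᵀ μ_c/2 + ln Π_c` with pooled
   within-class covariance).
4. **Fusion** — `fuse_outputs(elbow, wrist, hand)` maps the per-joint
   triple to the 27-class decision.
5. **Evaluation** — per-class/macro F1, misclassification error and
   normalized confusion matrices on a per-class 70/30 split; a real-time
   stream simulator emitting a decision every 90 ms and scoring motion
   selection time (MST, time to the first correct decision), motion
   completion time (MCT, time to the 10th correct decision) and motion
   completion rate (MCR, % of attempts completing within 5 s); and a
   Mann–Whitney U comparison with η² = Z²/N effect sizes.
6. **Synthetic data** — a generator emulating a 27-class acquisition
   protocol (4 repetitions × 3 s hold × 2 s rest per class) with
   amplitude-modulated Gaussian noise and class-specific per-channel
   activation patterns.

## Worked example

```r
library(emgfuse)

rec   <- generate_protocol_dataset(repetitions = 2, hold_s = 1, rest_s = 0.5, seed = 42)
feats <- rec |> segment_windows() |> extract_features()
sp    <- split_train_test(feats, train_fraction = 0.7)
model <- train_parallel(sp$train, algorithm = "lr", lambda = 1)
evaluate_parallel(model, sp$test)$summary
#> # A tibble: 1 × 7
#>   algorithm elbow_macro_f1 wrist_macro_f1 hand_macro_f1 fused_macro_f1 fused_error n_windows
#> 1 lr                     1              1             1              1           0       486
```

Each joint classifier and the fused 27-class decoder classify every one of
the 486 held-out windows correctly — the synthetic activation patterns are
well separated at the default signal-to-noise setting, so this ceiling is
expected (lower `snr_scale` to make the task hard, or 0 to reduce it to
chance). The real-time protocol replays 27 classes × 2 attempts through
the decoder with a decision every 90 ms:

```r
rt <- run_realtime_protocol(model, repetitions = 2, attempt_s = 5, seed = 43)
summarize_realtime(rt)
#> # A tibble: 1 × 8
#>   mean_mst_s sd_mst_s n_mst mean_mct_s sd_mct_s n_mct mcr_percent n_attempts
#> 1       0.15        0    54       0.96        0    54         100         54
```

MST = 0.15 s is the first possible decision (one full 150 ms window), and
MCT = 0.15 + 9 × 0.09 = 0.96 s is the earliest possible 10th correct
decision, so every attempt completes (MCR 100 %). Fully separated samples
give the Mann–Whitney ceiling effect size:

```r
mann_whitney_eta2(1:15, 16:30)
#> # A tibble: 1 × 6
#>       u     z    p_value eta_squared   n_a   n_b
#> 1     0 -4.67 0.00000307       0.726    15    15
```

Models serialize to JSON (`write_parallel_model()` /
`read_parallel_model()`) with bit-faithful decisions, and a thin CLI in
`inst/cli/emgfuse.R` exposes `synth`, `train`, `predict`, `evaluate`,
`stream-sim` and `compare` subcommands.

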