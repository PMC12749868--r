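---
title: "Restoring contact-pressure-distorted PPG morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restoring contact-pressure-distorted PPG morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ppgrestore)
```

## The model

`ppgrestore` learns a mapping from contact-pressure-distorted wrist PPG
windows to windows with the ideal pulse morphology. The assumptions are:

* the distorted and reference streams are sample-synchronized, so a window
  pair shows the same beats;
* amplitude is not informative — every window is min–max normalized to
  [0, 1] and only the *shape* is restored (an enhanced stream is returned on
  the input's amplitude scale purely by bookkeeping, see *Stream
  recombination*);
* the reference carries the ideal morphology: per cycle one systolic peak
  (the maximum), one dicrotic notch, one diastolic peak at 30–90% of the
  systolic amplitude, and nothing else.

The generator is a U-shaped encoder–decoder. Each of the `depth` encoder
stages is a *PPG block* — twice (gated convolution → GroupNorm → ReLU), then
a squeeze-and-excitation (SE) stage — followed by ×2 max-pooling; the latent
stage is a single-layer bidirectional LSTM over time (channels as features),
whose doubled channel count a per-time-step dense layer projects back to the
top width; the decoder mirrors the encoder with ×2 linear-interpolation
upsampling, a convolution, concatenation of the same-resolution encoder
features, and a PPG block; a final 3-tap convolution and sigmoid produce a
[0, 1] output of exactly the input length. The discriminator reuses the
encoder stack with global average pooling and a dense scalar head; its raw
score feeds a hinge loss. All forward and backward passes are written in R
against BLAS matrix primitives (convolutions as one `im2col` matrix product);
the test suite checks every layer's gradient against finite differences.

Training alternates one discriminator and one generator AdamW step per batch.
The generator objective is `mean(L_C) − θ·mean(D(z))` where the custom loss
`L_C` has two regimes driven by `α`, the absolute difference in prominent
peak counts between the generated and reference window: a peak-count
mismatch multiplies the MSE by `1 + α` (pushing the output toward two peaks
per cycle), and once counts match a point-to-point term `β·L_P2P` refines the
amplitudes at the three fiducials. `L_P2P` reads each signal's amplitude at
its *own* detected fiducial within reference-delimited cycles and charges a
bounded penalty of 1.0 (the maximal normalized amplitude) for each fiducial
the estimate lacks — the bounded penalty keeps the loss finite where the
estimate has no notch at all. For gradients, peak counts and fiducial
locations are treated as piecewise-constant; only the MSE and the amplitude
reads propagate.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| window / stride | 8 / 1.6 | s | long enough for several cycles; the stride multiplies training data |
| filter | Butterworth order 5, 10 Hz cutoff, zero-phase | — | pulse energy sits below 10 Hz; forward–backward filtering avoids fiducial time shifts, to which the point-based metrics are sensitive |
| validity band | DP/SP ∈ [0.30, 0.90] | — | the morphological definition of a usable diastolic peak (bounds inclusive) |
| peak prominence | 0.05 | normalized units | minimal topographic prominence for a fiducial / counted peak |
| β, θ | 0.01, 0.01 | — | scales of the point-to-point and adversarial terms |
| optimizer | AdamW, lr 0.001, weight decay 0.005, β₁ 0.9, β₂ 0.999 | — | standard hinge-GAN practice; reduce-on-plateau (×0.5, patience 10, floor 1e-5) and early stopping (patience 20) on validation L_C |
| channels / depth | 32, 64, 128 / 3 | — | ≈ 1.0 M parameters; depth 3 balances capacity and cost |

## The synthetic study

No recorded data ship with the package; a seeded generator emulates the
paired-measurement design in which one sensor is held at optimal contact
pressure (the reference) while the other experiences varying pressure.

*Reference.* Each cycle is the sum of two positive Gaussian bumps (systolic
and diastolic) plus a small negative Gaussian that deepens the dicrotic
notch between them; positions and widths are fractions of the cycle, so
morphology is heart-rate invariant. Cycle lengths are `60/HR` seconds plus
Gaussian jitter. Per-subject parameters are drawn uniformly once per subject
(HR 55–90 bpm, diastolic amplitude 0.45–0.65 of systolic, systolic center
0.24–0.28 and width 0.08–0.09 of the cycle, diastolic center 0.58–0.62 and
width 0.10–0.12, notch depth 0.04–0.07, jitter SD 5–20 ms) — heterogeneity
across subjects, stability within. The ranges were chosen so that the ideal
morphology is valid *by construction* at sampling rates down to 32 Hz;
`pulse_template()` additionally verifies one high-resolution cycle
numerically and rejects geometries whose notch sinks to the onset level
(physiologically the notch sits well above the diastolic baseline). The
notch component is never narrower than two samples, or coarse sampling
aliases it into spurious wiggles.

*Distortion*, applied in a fixed order: (1) notch suppression — blend toward
a Gaussian-smoothed copy (σ = 0.12 s), removing notch and diastolic peak at
full strength; (2) systolic time shift (fractional delay, 0–50 ms);
(3) slow multiplicative amplitude modulation (0.2 Hz, depth up to 0.3);
(4) sinusoidal baseline drift (up to 0.3 of the pulse amplitude,
0.05–0.3 Hz); (5) white noise (SD up to 0.02). With all magnitudes zero the
distortion is the identity, sample for sample.

What the generator does *not* emulate: motion artifacts, optical/skin
physiology, respiratory modulation of pulse shape, arrhythmias, and
measurement dropouts. Tests passing on this data show that the pipeline,
losses, training loop and estimators behave as specified and that the model
can learn a realistic restoration map — not that the trained weights
transfer to any real recording.

## Numerical and design choices

* **Onset detection** is period-anchored: systolic peaks are found first
  (prominence ≥ 0.25 with a refractory separation of 0.7 of the beat period,
  the period taken from the first prominent autocorrelation peak in the
  30–220 bpm band), and each onset is the minimum between consecutive
  systolic peaks. A plain prominence threshold on minima cannot separate
  onsets from deep dicrotic notches — for strong diastolic waves the notch
  prominence overlaps the onset range — whereas the refractory rule makes the
  separation structural: notch and diastolic peak always fall well inside
  0.7 of a period of their own systolic peak. Using the *first* prominent
  autocorrelation peak (not the global maximum) matters at coarse sampling
  rates, where cycle lengths alternate between adjacent integers and the
  global maximum can sit at twice the period.
* **Within-cycle fiducials**: SP is the global maximum (earliest index on
  ties), DN the most prominent minimum after SP, DP the most prominent
  maximum after DN, at prominence 0.05 on the amplitude-normalized cycle.
  Absent features are reported `NA`, never fabricated.
* **Windows** use `W = round(win_s·fs)`, `S = round(stride_s·fs)`, 0-based
  half-open offsets; the count per fragment is `floor((L − W)/S) + 1`.
  Windows never span invalid-segment gaps (stitching would fabricate beat
  intervals). Constant windows (range < 1e−6) are dropped — min–max
  normalization is undefined there.
* **Filtering** pads by odd reflection (value- and slope-continuous) before
  the forward–backward pass, so edges carry no transients; the mean is
  removed before and after.
* **Areas** (SA, DA) integrate trapezoidally above the per-cycle minimum —
  the baseline convention is otherwise arbitrary.
* **DTW** is unconstrained, absolute-difference cost, normalized by the
  optimal path length so values compare across window lengths; ties in
  backtracking prefer the diagonal.
* **Kurtosis** is reported in the non-excess (Pearson) convention;
  population moment estimators (type 1) are used for both SQI moments.
* **SDRR** uses the sample (n−1) convention (population available via an
  argument); HF power integrates a smoothed periodogram of the 4-Hz
  linearly-interpolated interval series over 0.15–0.40 Hz.
* **HR** is `60·(V − 1)/(t_last − t_first)` over detected valleys —
  interval-normalized counting, unbiased under partial edge cycles, and
  identical to `60/mean(interval)`.
* **Stream recombination** after per-window enhancement is Hann-weighted
  overlap-add with the weights floored at 1e−6, so samples covered by a
  single window pass through exactly; each window's recorded (min, max)
  restores the input's amplitude scale. Near-constant segments bypass the
  model entirely.
* **Initialization**: He for convolutions, Glorot for dense layers, forget-
  gate bias 1, and a small positive bias (0.1) in the SE bottleneck so the
  channel-attention path never starts dead.
* **α aggregation** is per window (the loss is written per window pair), with
  the absolute count difference; the first branch multiplies the MSE by
  exactly `1 + α`.
* **Upsampling/downsampling operators** (max-pool down, linear-interpolation
  up + convolution), concatenation skips, GroupNorm group count
  `min(8, channels)`, sigmoid output activation, and the single-layer LSTM
  are deliberate choices where several alternatives exist; they keep the
  default parameter count near 1 M and the architecture parameter-free in
  its resolution changes. Arbitrary input lengths are reflect-padded to a
  multiple of `2^depth` and cropped back.
* **D/G update ratio** is 1:1 per batch; batch size 32.

## Problem sizes used in the checks

The test suite and the acceptance script run a scaled-down study chosen to
exercise generalization across subjects at desk scale: 6 synthetic subjects
× 7 minutes at 32 Hz (subject-disjoint 4/1/1 split, ≈ 500 training windows
of 256 samples), a generator with channels 8/16 at depth 2 and LSTM width 16
(≈ 15 K parameters), 30 training epochs. The full-size configuration
(128 Hz, channels 32/64/128, ≈ 1.0 M parameters) is exercised for its shape,
bound and parameter-count contracts, and is the default for real use. On the
scaled-down study the trained model typically halves the distorted waveform
MAE on the held-out subject and restores the diastolic peak in the vast
majority of notch-suppressed cycles; the exact numbers for a given seed are
what `scripts/acceptance.R` reports.

## Known limitations

* The synthetic distortions are stationary within a recording; real contact
  pressure varies with posture over time.
* The validity filter assumes one notch and one diastolic peak; morphologies
  of older or cardiovascular-disease populations (where even ideal-pressure
  recordings deviate) fall outside its "valid" class by design.
* Training in plain R is practical at the scaled-down study size; full-size
  training (≈ 1 M parameters, 128 Hz, thousands of windows) is possible but
  slow — the architecture code is intended as a faithful, testable reference
  implementation, not a performance-tuned trainer.
* `L_P2P` uses subgradients with fiducial locations held fixed; the loss
  surface is only piecewise smooth, which is handled by the α-regime
  schedule (MSE dominates until peak structure is right).
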