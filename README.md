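# ppgrestore

Restoration of contact-pressure-distorted photoplethysmography (PPG)
morphology.

## The problem

Wrist-worn PPG sensors measure blood-volume pulses optically. Even when the
wearer is perfectly still, sub-optimal contact pressure between sensor and
skin distorts the pulse shape: the dicrotic notch and the diastolic peak may
shrink or vanish, the systolic peak shifts in time, and the amplitude is
modulated. An ideal cycle carries three fiducial points — the systolic peak
(SP, the cycle maximum), the dicrotic notch (DN, the local minimum after it)
and a diastolic peak (DP) at 30–90% of the systolic amplitude — and
downstream estimators (heart rate, heart-rate variability, blood-pressure
features) depend on them. `ppgrestore` is for researchers in wearable
cardiovascular sensing who need to map distorted wrist PPG back to the ideal
morphology and quantify how much the restoration helps those estimators.

## The method

A U-shaped gated-convolutional encoder–decoder is trained adversarially on
synchronized pairs (distorted window `y`, ideal reference window `x`):

* **Generator** `G`: three "PPG blocks" per side — each block is
  two × (gated 1-D convolution → GroupNorm → ReLU) followed by a
  squeeze-and-excitation (SE) channel-attention stage — with ×2 max-pooling
  on the way down, a bidirectional LSTM plus a dense projection in the
  latent space, ×2 linear upsampling with concatenation skip connections on
  the way up, and a sigmoid output bounded to [0, 1]. Channel widths
  1 → 32 → 64 → 128 (≈ 1.0 M parameters at depth 3). A gated convolution
  computes `conv_a(x) ⊙ σ(conv_b(x))`.
* **Discriminator** `D`: the same encoder stack, global average pooling,
  and a dense layer emitting one raw score; trained with the hinge loss

  `L_D = mean[ max(0, 1 − D(x_i)) + max(0, 1 + D(z_i)) ]`, `z_i = G(y_i)`.

* **PPG-aware custom loss.** With `α = |#peaks(z) − #peaks(x)|` counted at
  prominence 0.05 on the normalized windows:

  `L_C = MSE·(1 + α)` if `α ≠ 0`, else `L_C = β·L_P2P + MSE` (β = 0.01),

  where `L_P2P` is the mean absolute amplitude difference at the three
  fiducials of each cycle (penalty 1.0 per missing fiducial). The generator
  minimizes `L_G = mean(L_C) − θ·mean(D(z))` (θ = 0.01) with AdamW
  (lr 0.001, weight decay 0.005) and early stopping on validation `L_C`.

The whole network and its backpropagation are implemented in R on BLAS
matrix operations; dynamic time warping is implemented in C.

Around the model the package provides the full pipeline: a seeded synthetic
generator of paired (reference, distorted) streams, zero-phase Butterworth
lowpass + DC removal, morphology-validity filtering (valley-to-valley cycles;
a cycle is valid iff SP, DN, DP appear in order with DP/SP ∈ [0.30, 0.90]
and no extraneous peaks or notches), 8-s/1.6-s sliding windows, per-window
min–max normalization, augmentation, waveform metrics (MAE, path-normalized
DTW, Pearson correlation, per-feature MAPE, skewness/kurtosis errors,
diastolic recovery rate), and valley-based HR/HRV/BP-feature estimators.

## Worked example

```r
library(ppgrestore)

# paired synthetic study: 6 subjects, subject-disjoint splits, 32 Hz
ds <- make_dataset(n_subjects = 6, minutes_per_subject = 7, fs = 32,
                   split = c(4, 1, 1), seed = 11)
ds
#> <ppg_dataset> 1295 window pairs (777 train / 259 val / 259 test), 6 subjects @ 32 Hz
ds$split$train <- ds$split$train[1:500]   # desk-scale training set

cfg <- generator_config(depth = 2, channels = c(8, 16), lstm_hidden = 16,
                        gn_groups = 4)
fit <- train_restorer(build_generator(cfg, seed = 1),
                      build_discriminator(cfg, seed = 2), ds,
                      train_cfg = train_config(max_epochs = 30,
                                               batch_size = 32,
                                               patience = Inf,
                                               lr_patience = Inf, seed = 1))

te <- ds$pairs[ds$split$test]
eh <- enhance_pairs(fit, te)
mean(abs(eh$distorted - eh$reference))   # 0.203  distorted-vs-reference MAE
mean(abs(eh$enhanced  - eh$reference))   # 0.086  enhanced-vs-reference MAE

evaluate_windows(eh$enhanced, eh$reference, fs = 32)
#> <metrics_report>
#>   overall: MAE 0.0865  DTW 0.0456  PCC 0.9241  (259 windows)
#>   MAPE (%): SP 1.22  SW 8.48  DW 4.13  DN 46.99  NT 7.31  DP 19.44  DT 7.84  SA 22.82  DA 10.15
#>   SQI MAE: skewness 0.3871  kurtosis 0.8085  (2280 cycles matched)

diastolic_recovery_rate(eh$enhanced, eh$reference, eh$distorted, fs = 32)$rate
#> 0.9995   # fraction of notch-suppressed cycles whose diastolic peak returns
```

On this run the enhanced windows cut the waveform MAE by 57% relative to the
distorted input, restore the diastolic peak in 99.95% of the cycles that had
lost it, and halve the valley-based heart-rate error (4.83 → 2.04 bpm MAE on
the held-out subject).

Enhancing a continuous recording and feeding downstream estimators:

```r
enh <- enhance_signal(sig, fit, win_s = 8, stride_s = 1.6)  # overlap-add
estimate_hr(enh)                        # beats/min
estimate_hrv(beat_series(enh))          # RMSSD, SDRR, PNN50, HF
bp_features(enh)                        # feature vector for a BP regressor
```

A thin command-line driver covering
`simulate | preprocess | train | transform | evaluate | downstream` is
installed at `system.file("cli", "ppgrestore", package = "ppgrestore")`.

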