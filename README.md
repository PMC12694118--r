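# fatiguecast

Forecasting driver fatigue from multichannel EEG and eyelid behaviour.

PERCLOS — the percentage of an observation window during which the eyelids
cover the pupils — is a standard behavioural index of drowsiness, bounded
in [0, 1] and rising as fatigue deepens. `fatiguecast` implements an
end-to-end pipeline that *forecasts* the next time-step PERCLOS value from
the recent history of windowed EEG features plus past PERCLOS, for
researchers working on physiological-signal time-series modelling and
driver-vigilance monitoring.

The pipeline mirrors the protocol of the 23-subject SEED-VIG
simulated-driving benchmark (17 channels, 1000 Hz decimated to 200 Hz,
non-overlapping 8-s windows, 885 timesteps per 118-minute session). Since
that dataset is access-restricted, the package ships a seeded synthetic
cohort generator whose EEG band structure and eyelid closure co-evolve
with a latent fatigue process, and all tests run against it.

## What's inside

* **Synthetic cohort generator** — latent fatigue as logistic drift plus a
  bounded random walk; five spectrally disjoint band-limited noise
  carriers per channel whose per-window powers are Welch-calibrated to
  targets that couple to fatigue (α, θ rise; β falls); eyelid closure as a
  noisy readout of latent fatigue.
* **Preprocessing** — zero-phase Butterworth-magnitude bandpass (1–75 Hz
  default) and polyphase rational resampling.
* **Windowed features** — band power (Welch, half-open bins), differential
  entropy `DE = ½ ln(2πeσ²)` per band (85 columns for 17 channels × 5
  bands), α/β band-power ratio `Pα/Pβ`, wavelet entropy
  `WE = −Σ pⱼ ln pⱼ` over a 5-level periodized db4 decomposition, and the
  Hurst exponent from rescaled-range analysis (OLS slope of log R/S vs
  log n over dyadic segment sizes) on band-reconstructed signals.
* **Dataset construction** — feature–PERCLOS concatenation
  (885 × 86 for DE), sliding windows `Xᵢ = D[i..i+L−1, :]`,
  `yᵢ = D[i+L, 86]` with L = 3, chronological 8:1:1 splits, and z-score
  normalization fit on training inputs only (targets stay on [0, 1] for
  the sigmoid head).
* **The network** — positional encoding → width-1 convolution (86 → 64) →
  one 4-head transformer encoder layer (feed-forward 64) → outer residual
  skip → 2-layer LSTM (hidden 32) → affine 32 → 1 + sigmoid. Forward and
  analytic backward passes are pure R matrix code, verified against finite
  differences; Adam, MSE loss, seeded determinism throughout. Ablations
  (`NO_CNN`, `NO_TRANSFORMER`, `NO_LSTM`, `NO_RESIDUAL`) and baselines
  (`CNN_ONLY`, `TRANSFORMER_ONLY`, `LSTM_ONLY`, `CNN_TRANSFORMER`).
* **Evaluation harnesses** — leave-one-subject-out cross-validation (lr
  0.001, batch 64, fixed 20 epochs) and cross-subject pretraining with
  within-subject fine-tuning (lr 0.001 → 0.0001, early stopping with
  patience 10, lr halving with patience 5), plus a window-length sweep.
  Reports are per-subject RMSE/MAE tables with an `Avg` row.
* **Reference tables** — the published per-subject benchmark metrics are
  bundled (`reference_metrics()`) for table-consistency checks.

See `vignettes/fatiguecast-methods.Rmd` for the model, its assumptions,
and every numerical choice.

## Worked example

Three synthetic subjects, strongly coupled EEG, leave-one-subject-out
evaluation of the full hybrid model on differential-entropy + PERCLOS
inputs:

```r
library(fatiguecast)

cohort <- generate_cohort(3, base_seed = 11, duration_s = 480,
                          coupling_strength = 1, noise_sd = 0.5)
report <- run_loocv(cohort, feature_kind = "de", variant = "FULL",
                    cfg = loocv_train_config(seed = 101))
print(report)
#>  subject   rmse    mae
#>        1 0.1106 0.0927
#>        2 0.2065 0.1804
#>        3 0.0991 0.0852
#>      Avg 0.1387 0.1194
```

Each row is one held-out subject: the model never saw that subject during
training, so RMSE/MAE measure zero-shot cross-subject generalization of
next-step PERCLOS prediction on the [0, 1] scale; `Avg` is the arithmetic
mean over subjects. Adding EEG features to past PERCLOS helps — the
multimodal direction the benchmark reports:

```r
uni   <- run_loocv(cohort, "perclos_only", variant = "LSTM_ONLY",
                   cfg = loocv_train_config(seed = 2))
multi <- run_loocv(cohort, "de", variant = "LSTM_ONLY",
                   cfg = loocv_train_config(seed = 2))
relative_reduction(report_avg(uni), report_avg(multi))
#> PERCLOS-only Avg RMSE: 0.1963
#> EEG+PERCLOS  Avg RMSE: 0.1340  -> relative error reduction 31.7%
```

A command-line interface wraps the same pipeline
(`inst/cli/fatiguecast.R`):

```sh
Rscript inst/cli/fatiguecast.R simulate --out-dir runs/demo --n-subjects 2 --duration 160
Rscript inst/cli/fatiguecast.R loocv --out-dir runs/demo --feature de --variant FULL
```

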