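# palmppg

Reconstruction of high-fidelity remote photoplethysmography (rPPG)
waveforms from palm-region video, for researchers working on camera-based
physiological sensing who care about the *waveform* — systolic upstroke,
dicrotic notch, second peak — and not only about average heart rate.

## What it does

The package implements the full chain from frames to evaluated waveform:

1. **Extraction** — the coarse trace is the ROI green-channel mean,
   `rPPG_raw(t) = (1/N) Σᵢ Iᵢ(t)`, over a user-supplied or
   threshold-derived palm mask.
2. **Baseline removal** — ensemble empirical mode decomposition (50
   trials, relative noise width 0.01, ≤ 8 IMFs); IMFs with fewer local
   extrema than `0.7 · n/fs` (0.7× the expected cardiac-cycle count) and
   the residual trend are discarded, and the mean is compensated exactly.
3. **Adversarial reconstruction** — a conditional 1-D U-Net generator
   (kernel 4 / stride 2, instance norm + PReLU, gated skip connections,
   Tanh output) against a convolutional discriminator (kernel 5 / stride
   3, LeakyReLU + instance norm, two-channel conditioned input), trained
   with the least-squares adversarial objective plus time-domain L1,
   1024-point FFT magnitude L1 (β = 0.3) and a peak-aware L1 at annotated
   systolic/notch/second-peak locations (γ = 0.5):

   `L_G = ½(D(ŷ,x) − 1)² + α‖y − ŷ‖₁ + β‖|Fy| − |Fŷ|‖₁ + γ‖y_pk − ŷ_pk‖₁`

   `L_D = ½D(ŷ,x)² + ½(D(y,x) − 1)²`

   The networks and backpropagation (including the FFT-magnitude loss
   gradient) are implemented in this package with RcppArmadillo kernels —
   no deep-learning framework is required.
4. **Evaluation** — MAPE/RMSE/Pearson ρ/cosine similarity, plus a
   morphology pipeline (valley detection, cycle segmentation with an
   automated quality screen, template averaging, the indices t1, t2, h1,
   h2, h3, and two-site comparison).
5. **Synthetic data** — paired (clean PPG, corrupted rough trace,
   optional palm-like video) records with exact ground-truth fiducials,
   so the whole pipeline is testable without access to clinical data.

See `vignettes/palmppg-methods.Rmd` for the models, parameter meanings
and design decisions.

## Worked example

```r
library(palmppg)

pulse     <- generate_clean_ppg(pulse_model_params(heart_rate_bpm = 72),
                                duration_s = 20, fs = 100, seed = 1)
rough     <- corrupt_signal(pulse, noise_params(), seed = 2)   # drift+noise
corrected <- remove_baseline(rough, eemd_config(seed = 3))     # EEMD

print(pulse)
#> <annotated_pulse> 2000 samples @ 100 Hz, 24 cycles
print(corrected)
#> <corrected_trace> 2000 samples @ 100 Hz; removed components: 6
compute_metrics(rough$samples,     pulse$samples)
#> <metric_report> MAPE 8.0569 | RMSE 0.3940 | rho 0.5723 | cosine 0.7959
compute_metrics(corrected$samples, pulse$samples)
#> <metric_report> MAPE 6.4837 | RMSE 0.1736 | rho 0.8509 | cosine 0.9488
```

Baseline removal alone lifts the correlation with the clean reference
from 0.57 to 0.85 (the removed component is the drift IMF); the GAN stage
then denoises the corrected trace — in the packaged acceptance benchmark
(white noise σ = 0.15, 100 records, 200 epochs, seed 7) held-out
reconstruction reaches mean ρ ≈ 0.99 versus ρ ≈ 0.88 for its input.

```r
avg <- average_waveform(build_cycle_set(pulse$samples, fs = 100))
morphology_indices(avg)
#> <morphology_indices> t1 0.185 s | t2 0.649 s | h1 0.998 | h2 0.357 | h3 0.495
```

t1/t2 are the rise/fall times of the averaged normalized cycle; h1/h2/h3
the main-peak, dicrotic-notch and second-peak amplitudes — here matching
the generator's template (rise 0.18 s, notch level 0.35, second peak 0.5).

Training and reconstruction:

```r
ds <- make_paired_dataset(noise = noise_params(), n_records = 100, seed = 7)
ck <- train_gan(ds, tcfg = train_config(epochs = 200, batch_size = 32,
                                        seed = 7))
y  <- reconstruct(ck, ds$records[[ds$split$val[1]]]$rough)
```

A command-line front end covers the same operations
(`inst/cli/palmppg preprocess|synth|train|reconstruct|evaluate|morphology`).

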