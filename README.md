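# hdsemgsel

Channel selection for high-density surface EMG (HD-sEMG) motion recognition.

High-density electrode grids (here: 64 channels on a 5 × 13 array, 8 mm
pitch, 5120 Hz) capture the spatial pattern of muscle activity and make
complex upper-arm motions separable — but streaming and processing 64
channels is exactly what an embedded myoelectric controller cannot afford.
`hdsemgsel` implements a recognition-optimization pipeline that reduces the
grid to a handful of physical electrodes while keeping the motion classes
separable:

1. **Per-class spatial covariances.** The labelled recording is windowed and
   each motion class `c_i` gets a channel covariance `Σ_i` (trace-normalized,
   per-window mean removal).
2. **Multiclass CSP by joint approximate diagonalization.** One filter matrix
   `W` approximately diagonalizes all class covariances at once:
   `ωⱼᵀ Σ_i ωⱼ = λ_i^j`. The mean covariance `Σ̄ = Σ p_i Σ_i` is whitened
   exactly, then an orthogonal joint diagonalizer is found by Jacobi sweeps
   minimizing the summed off-diagonal Frobenius norm. For two classes this
   reduces to classical CSP with `D₁ + D₂ = I`.
3. **Mutual-information ranking.** Each filter column (scaled so
   `ωᵀ Σ̄ ω = 1`) is scored by the closed-form mutual information between
   class label and filtered output under a Gaussian-mixture model:
   `I(c, y) = −Σ p_i ln √(v_i) − (3/16)(Σ p_i v_i² − 1)²`, `v_i = ωᵀ Σ_i ω`
   (nats; the quartic term is the mixture's negentropy approximated from its
   fourth cumulant).
4. **Channel mapping.** The top-ranked filters nominate physical electrodes
   (maximum-absolute-weight entry, duplicates skipped) until `L′` distinct
   channels are selected — a hardware-realizable subset, unlike PCA/ICA
   component mixtures.
5. **Features and classification.** Wavelet-packet transform (sym5, depth
   J = 4, periodized orthonormal filter bank) of each selected channel per
   analysis window; the log-RMS of the 2⁴ = 16 terminal subbands are the
   features. Stratified 5-fold cross validation with SVM, LDA, KNN or a
   single-hidden-layer neural network.

PCA (95% cumulative contribution) and symmetric FastICA spatial filtering
are included as the standard comparison pipelines, along with RMS
topography maps of the grid and a synthetic HD-sEMG generator with planted
spatial class structure for end-to-end validation.

## Worked example

```r
library(hdsemgsel)

# synthetic 64-channel recording: 8 motions x 2 s x 5 repetitions @ 5120 Hz
cfg <- synth_config(seed = 1)
rec <- generate_recording(cfg)
rec
#> <emg_recording> 64 channels x 512000 samples @ 5120 Hz; 40 labelled
#>   intervals (8 classes)

ep  <- segment_epochs(rec)              # 0.25 s windows, 0.125 s step
cov <- class_covariances(ep)            # 8 covariance matrices, 64 x 64
sel <- select_channels(cov, n_channels = 5)
sel
#> # A tibble: 5 x 3
#>   channel filter_column     mi
#>     <int>         <int>  <dbl>
#> 1      20            20 0.0378
#> 2      43            30 0.0375
#> 3      15            15 0.0339
#> 4      49            36 0.0157
#> 5      25            25 0.0128
planted_channels(cfg)
#> [1] 15 43 20 49 25
```

The five selected electrodes are exactly the five activation centres the
generator planted; the `mi` column is the information (nats) each
nominating filter carries about the motion class. Features and
classification:

```r
fm <- build_feature_matrix(ep, sel)     # 600 windows x (5 x 16) features
cv <- crossval_evaluate(fm, "SVM", k = 5, seed = 1)
cv
#> <cv_result> SVM, 5-fold CV on 600 samples: accuracy 0.968
glance(cv)
autoplot(cv)                            # confusion heat map

# accuracy as channels are added, all four classifiers
sweep <- channel_sweep(rec, l_values = c(1, 3, 5, 10))
plot_channel_sweep(sweep)
```

With 5 of 64 channels the SVM reaches ~0.97 accuracy on the default
synthetic protocol, within a few percent of the full 64-channel grid —
the working premise of grid reduction. An end-to-end run from a single
JSON config (input, method, L′, WPT, classifier) is `run_pipeline()`;
`inst/scripts/hdsemg.R` wraps it for the shell.

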