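# rwgtsc

Label-free single-cell classification from resonant waveguide grating
(RWG) biosensor adhesion kinetics, in R.

An RWG optical biosensor records the resonant wavelength shift (WS, in
picometres) across an 80x80-pixel sensor per well. Adhering cells appear
as compact peaks (1-4 px) whose time courses trace single-cell adhesion
kinetics — lag, sigmoidal spreading, plateau. `rwgtsc` is for researchers
who want to turn such recordings (or fully synthetic stand-ins) into
classified single cells: it implements the processing chain from raw
multi-well frames to per-cell *maxWS* signals, builds balanced
fixed-length datasets, trains six standard time-series neural classifiers
under stratified cross-validation, and explains their decisions with
grad-CAM.

## What is inside

| Stage | Functions |
|---|---|
| Synthetic wells & signals with ground truth | `synthetic_well_truth()`, `synthesize_well_video()`, `generate_labeled_dataset()`, `default_class_specs()` |
| Sensor pipeline | `load_raw_frames()`, `global_background_correct()`, `detect_cell_peaks()`, `assign_voronoi_rois()`, `extract_max_ws()`, `sensor_pipeline()` |
| Dataset construction | `zero_offset()`, `correct_batch_artifact()`, `cut_to_length()`, `stratified_kfold_split()`, `smote_oversample()`, `standardize_signals()` |
| Classifiers | `build_model()` (MLP, CNN, FCN, ResNet, MCDCNN, Inception), `train_config()`, `train_model()`, `predict_model()`, `cross_validate()`, `evaluate()` |
| Interpretation | `compute_gradcam()`, `gradcam_alpha_fd()`, `upsample_cam()`, `false_negative_distribution()` |
| Orchestration | `experiment_config()`, `run_experiment()`, `compare_models()` |

The cell signal is the **maxWS** trace: after global background
correction (per-frame mean of cell-free pixels subtracted), cells are
detected as 2D local maxima above a user threshold, the sensor area is
partitioned by Voronoi tessellation around the peaks, and the per-frame
maximum within each cell's region is monitored. Datasets are zero-offset,
batch-corrected, cut to 30/60/90/120/150-min lengths, SMOTE-balanced on
the training side only, and standardized with training statistics. The
classifiers follow the standard architecture table for this model family
(layer/conv counts 4/0, 4/3, 5/3, 11/9, 4/2, 7/6; optimizers AdaDelta /
Adam / SGD+momentum; cross-entropy; 500-epoch budget with early
stopping); grad-CAM uses the globally average-pooled gradient weights
`alpha_k^c` and `L^c = ReLU(sum_k alpha_k^c A^k)`.

The neural-network engine (forward/backward passes, the three optimizers,
batch norm, dropout, pooling) is implemented inside the package in plain
R over BLAS matrix products, with gradients validated against finite
differences in the test suite.

## Worked example

Synthesize a noiseless well with ground truth, run the extraction chain,
and check amplitude conservation:

```r
library(rwgtsc)

spec <- list(A = class_kinetic_spec("A", c(150, 600),
                                    onset_delay = c(5, 1),
                                    rise_time = c(3, 0.5)))
tg <- time_grid(150, delta_t_s = 9)
truth <- synthetic_well_truth(25, spec, drift_rate = 0.5,
                              artifact_jump = 10, seed = 3)
well <- synthesize_well_video(truth, tg, seed = 4)
res <- sensor_pipeline(well$video, threshold = 75)

res$peaks
#> <peak_set> 25 peaks (threshold 75 pm, min distance 2 px)
max(abs(sort(res$records$signals[, length(tg)]) -
        sort(truth$cells$amplitude)))
#> [1] 1.136868e-13
```

All 25 planted cells are recovered at their exact pixels, and after
background correction removes the drift (0.5 pm/min) and the 10-pm
injection step, the endpoint of each maxWS signal equals the planted
adhesion amplitude to machine precision.

A small end-to-end classification run:

```r
cfg <- experiment_config(list(
  seed = 11, n_per_class = c(HeLa = 12, `MC3T3-E1` = 12),
  lengths = 30, duration_min = 30, models = "MCDCNN",
  k_folds = 3, train = list(epochs = 2, early_stopping_patience = Inf)))
res <- run_experiment(cfg)
res$comparison[, c("network", "length_min", "accuracy_mean", "accuracy_sd")]
#>   network length_min accuracy_mean accuracy_sd
#> 1  MCDCNN         30         0.875      0.125
```

(Two epochs on 24 cells, for illustration; the HeLa and MC3T3-E1 default
specs differ mostly in amplitude range, so even a short training
separates them. Accuracy is the mean over the three fold test sets.)

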