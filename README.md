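# icgfa

Quantitative interpretation of indocyanine green fluorescence angiography
(ICGFA) for intestinal perfusion assessment. During colorectal resection the
surgeon chooses a transection (stapling) level by watching how the
fluorescent dye perfuses the bowel; this package turns that judgement into a
prediction problem. From paired white-light + near-infrared (NIR) video and
a line annotated across the perfusion boundary, it predicts for every
location along the line whether an expert surgeon would staple there
(`expert`), keep it as well-perfused margin (`good`), or reject it as
non-perfused (`poor`), and renders the in-theatre style green/red/blue
overlay.

The method:

- **Stabilisation** — each frame is registered to the first by a robust
  affine fit (Harris corners → patch descriptors → ratio-test matching →
  RANSAC), estimated on white light and applied identically to NIR.
- **Fluorescence extraction** — frames are reduced to a 72×96 grid of
  5×5-px cells (360×480 frames); overlay-mode displays are first inverted
  via the green-channel excess `clamp(G − max(R, B), 0, 255)`.
- **Curve milestones** — each cell's intensity–time curve over a 30-s
  window from inflow onset is summarised by maximum intensity, upslope
  `(I_max − b)/(t_max − t_onset)`, time to maximum, and time to
  50%-maximum.
- **Line condensation** — a 35-px rectangle perpendicular to the annotated
  line is sampled at every coordinate and condensed to one feature vector by
  the median.
- **Two classifiers** — a weighted k-nearest-neighbour point model with
  line-grouped 10-fold cross-validation, and a five-layer bidirectional LSTM
  (sequence input → bi-LSTM, 200 hidden units → fully connected → soft-max →
  classification output) trained with early stopping, in single-expert and
  three-expert variants.
- **Evaluation** — pixel-level expert-vs-rest metrics (accuracy, precision,
  recall, specificity, F1, DICE = 2|P∩G|/(|P|+|G|)) and object-level
  accuracy: does the true stapler-band centre fall inside the predicted
  expert zone (the longest contiguous expert run of ≥ 6 grid modules)?

A synthetic scene generator (gamma-variate bolus kinetics per perfusion
zone, imaging noise, affine camera jitter, both native-NIR and green-overlay
display modes) makes the full pipeline trainable and testable without
surgical data.

## Worked example

```r
library(icgfa)

cfg <- scene_config(frame_height = 120, frame_width = 300, fps = 2,
                    duration = 45, seed = 7)
scene <- render_scene(cfg)
scene
#> <icgfa_scene> 120x300 px, 91 frames @ 2 fps, mode native, perfused
#> <icgfa_annotation> 56 modules: 22 good | 12 expert | 22 poor
#>   stapler band modules [25, 37), centre 30.5

grid  <- build_grid_series(stabilize_sequence(scene))
feats <- normalize_features(featurize_grid(grid))
feats
#> <icgfa_features> 24x60 grid, onset 10.0 s, window 30 s, normalised

line <- condense_median(sample_rectangle(feats, scene$annotation$line))
head(line[, c("position", "col", "i_max", "upslope", "t_max", "t_half")], 3)
#>   position   col i_max upslope t_max t_half
#> 1        1     3 0.989   0.867 0.433  0.150
#> 2        2     4 0.993   0.869 0.433  0.151
#> 3        3     5 0.994   0.839 0.45   0.150
```

The line starts in well-perfused bowel: near-maximal peak intensity and
upslope, early half-rise. Train the sequence model on a few scenes and
evaluate on held-out ones (including a poor-perfusion segment, where the
correct behaviour is an explicit no-prediction):

```r
cfgs <- sample_scene_configs(8, seed = 7, frame_height = 120,
                             frame_width = 300, fps = 2, duration = 45)
dataset <- scenes_to_dataset(cfgs, split = list(train = 1:6, validation = 7:8),
                             seed = 7)
model <- train_bilstm(dataset, epochs = 40, seed = 7)
model
#> <icgfa_bilstm> sequence input -> bi-LSTM -> fully connected -> soft-max -> classification output
#>   200 hidden units/direction, stopped at epoch 25 (best 20, val loss 0.1967)

test_scenes <- lapply(sample_scene_configs(3, seed = 99, n_poor = 1,
                                           frame_height = 120, frame_width = 300,
                                           fps = 2, duration = 45), render_scene)
evaluate_suite(model, test_scenes)
#> <icgfa_eval> 3 scenes (2 with stapler annotation)
#>   pixel: acc 0.994  prec 0.960  rec 1.000  spec 0.993  F1 0.980  DICE 0.980
#>   object-level accuracy: 1.000
```

Object-level accuracy 1.0 means the true stapler-band centre fell inside the
predicted expert zone on both perfused test segments; the poor-perfusion
segment produced a no-prediction and does not enter the denominator.
`autoplot()` methods visualise feature grids, training curves and metric
summaries; `render_overlay()` draws the clinical green/red/blue display.

A command-line front end wraps the same workflows:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "icgfa.R", package = "icgfa"))')" \
  simulate --config conf.yaml --seed 1 --out out/
```

with subcommands `simulate`, `featurize`, `train`, `predict`, `evaluate`.

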