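# wbcdetect

Detection, classification and counting of white blood cells in stained
bone-marrow smear microscopy images, implemented entirely in R.

Differential cell counts on marrow smears — locating every cell in a
field, assigning it to one of seven classes (Granulocyte, Erythrocyte,
Lymphocyte, Megakaryocyte, Plasma cell, Monocyte, Others) and tallying
them — are slow and fatiguing to do by eye. `wbcdetect` frames the task
as two-stage object detection:

* a five-stage residual backbone with an **augmented feature pyramid**:
  the classic top-down pathway with lateral connections (`P2..P5`) plus a
  bottom-up fusion pathway (`N2..N5`, `N[i+1] = conv(conv_s2(N[i]) + P[i+1])`)
  that carries localization detail back up to the semantically strong levels;
* an anchor-based **region proposal network** over every pyramid level,
  with the standard center/log box-delta code
  (`tx = (cx_g − cx_a)/w_a`, `tw = log(w_g/w_a)`, …) and the
  0.7/0.3 IoU interval rule with 1:1 positive/negative sampling;
* a **soft-attention localizer**: scaled dot-product attention
  `alpha = softmax(beta·QKᵀ/√d_k)`, `context = alphaᵀV` over pyramid
  positions with a GRU hidden state as query and an LSTM on the weighted
  feature stream, generating proposals at the attention peak, ranking
  candidates by IoU, and refining the chosen box with an **actor-critic
  agent** rewarded by per-step IoU improvement
  (`r_t = IoU(b_t) − IoU(b_{t−1})`, terminal bonus on correct
  classification at IoU ≥ τ);
* an **RoIAlign head** (quantization-free bilinear sampling, 7×7 cells)
  with an 8-way softmax (7 classes + background) and per-class box
  refinement, followed by a 0.7 confidence threshold, multi-class NMS and
  per-class counting;
* **COCO-protocol evaluation**: 101-point interpolated AP over the
  0.50:0.05:0.95 IoU grid, AP50/AP75, area-stratified APS/APM/APL, and AR
  at a 100-detection budget.

Every layer (convolutions, GRU/LSTM cells, attention, RoIAlign) and its
analytic gradient is written in plain R on BLAS matrix operations, so
training and inference run on one CPU with no external deep-learning
runtime. Because the clinical datasets this method targets are
hospital-private, the package includes a seeded generator of synthetic
marrow-smear fields (class-conditional cell sizes and stain colors,
illumination gradients, touching cells, COCO ground truth) used by the
tests and examples; see the methods vignette
(`vignettes/wbc-detection-methods.Rmd`) for what that does and does not
demonstrate.

## Worked example

Generate a synthetic dataset, train the tiny (CPU-scale) detector for a
few minutes, evaluate on a held-out split and count cells:

```r
library(wbcdetect)

spec <- smear_spec_tiny(seed = 1)              # 128 x 128 fields
dir  <- file.path(tempdir(), "smears")
ds   <- generate_smear_dataset(spec, 60, dir)  # PNGs + COCO JSON
print(ds)
#> COCO dataset: 60 images, 417 annotations, 7 categories
#>   Granulocyte    101
#>   Erythrocyte    115
#>   Lymphocyte     71
#>   Megakaryocyte  19
#>   Plasma cell    35
#>   Monocyte       46
#>   Others         30

sp    <- split_dataset(ds, train_fraction = 0.9, seed = 1)
cfg   <- default_config(tiny = TRUE, seed = 1)
model <- train(cfg, dataset = sp$train, image_dir = dir, iterations = 300)

evaluate_model(model, sp$test, dir)
#> COCO-protocol detection metrics
#>    AP  AP50  AP75   APS   APM   APL    AR
#> 0.124 0.304 0.104 0.145 0.000    -- 0.288
#> (6 images, 192 detections, 42 ground-truth boxes)

dets <- detect_images(model, dir, sp$test)     # deployment threshold 0.7
count_cells(dets)
#> Cell count report — 48 cells in 6 image(s)
#>   Granulocyte    23
#>   Erythrocyte    5
#>   ...
```

AP50 of 0.30 after 300 iterations on 54 images is a deliberately small
demonstration; the suite's 450-iteration run on 180 images reaches AP50 >
0.4, and the tiny-mode default budget is 2,000 iterations (an untrained
model scores ≈ 0). `AP` is the COCO headline metric (mean over classes
and IoU thresholds 0.50–0.95); `--` marks strata with no ground truth,
which are excluded from means rather than zero-filled. The count report
tallies only detections above the 0.7 confidence threshold.

The attention localizer is trained and exercised separately:

```r
ep <- actor_critic_episode(feats, gt_box, gt_class,
                           model$params$localizer, model$attention_cfg,
                           stride = 4, image_size = c(128, 128))
sum(ep$rewards)   # telescopes to IoU(final) - IoU(initial) (+ bonus)
```

## Command line

A thin launcher (`inst/cli/wbcdetect.R`) exposes the same pipeline:

```sh
Rscript inst/cli/wbcdetect.R synth    --n 200 --out data/ --seed 1 --tiny TRUE
Rscript inst/cli/wbcdetect.R convert  --via project.json --out coco.json
Rscript inst/cli/wbcdetect.R train    --data data/ --out run/ --seed 1
Rscript inst/cli/wbcdetect.R detect   --checkpoint run/checkpoint.rds \
                                      --images data/ --out dets.json
Rscript inst/cli/wbcdetect.R count    --detections dets.json --out counts.csv
Rscript inst/cli/wbcdetect.R evaluate --gt data/annotations.json --results dets.json
```

All commands take `--seed`; `train` and `detect` also take `--config`
(YAML overriding `default_config()`).

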