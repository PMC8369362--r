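# dbtdet

Single-phase lesion detection and FROC evaluation for digital breast
tomosynthesis (DBT), in R.

## What this is for

DBT delivers a stack of reconstructed cross-sectional slices per view
(LCC/RCC/LMLO/RMLO). Radiologists mark biopsied masses and architectural
distortions with one rectangle on the lesion's central slice. Building and
evaluating a detector for these lesions requires a chain of fairly
specific conventions — window-level preprocessing and breast-region
masking, a rule for turning a 2-D center-slice box into a 3-D training
target, a grid detector with losses that survive extreme
foreground/background imbalance, volume-level inference with box-merging
NMS, and a free-response ROC (FROC) analysis with a custom true-positive
criterion. `dbtdet` implements that whole chain, plus a seed-deterministic
DBT phantom simulator so the pipeline can be trained, tested, and
benchmarked end to end on one CPU with no patient data.

The audience is researchers building computer-aided detection baselines
for DBT (or similar slice-stack modalities) and anyone who needs the
evaluation half — volume-based and breast-based FROC with bootstrap
confidence intervals — for predictions produced elsewhere.

## The model in brief

A fully convolutional dense-block network scores a grid of 96 × 96-px
cells on each (2× downscaled) slice. Cell output is 5 numbers: a
confidence `p ∈ (0,1)` that the cell contains a lesion-box center, and a
box parameterization relative to the cell and a square 256 × 256 anchor:

    center = cell_center + 96 · offset,   offset ∈ [−0.5, 0.5]
    dims   = 256 · exp(scale)

Objectness losses: BCE, prevalence-weighted BCE, focal
`−α(1−p_t)^γ log p_t`, and reduced focal (BCE below `p_t = 0.5`, scaled by
`((1−p_t)/0.5)^γ` above). Localization is MSE at positive cells; total
loss is `objectness + λ·localization`.

Training samples positive slices only — the slice span of a lesion is
`round(sqrt((w+h)/2))` slices centered on the annotated slice (halved for
validation) — with random 1056 × 672 crops containing the whole box, Adam
(lr 0.001, batch 16), early stopping by sensitivity at 2 FP/slice.
Inference averages per-slice grids over each volume half, decodes, drops
boxes with < 50 % of their area inside the breast mask, and merges box
pairs with score ratio < 10 and IoU > 0.5. A prediction is a true
positive when its center is within `max(GT_diagonal/2, 100 px)` of the
GT center and its slice within `±25 %` of the volume around the GT
center slice.

## Worked example

Simulate a phantom dataset, train a small detector, predict, evaluate
(about two minutes on one CPU at the `tiny` preset):

```r
library(dbtdet)

dir <- tempfile()
dbt_main(c("simulate", "--counts", "4,0,2,2", "--preset", "tiny",
           "--seed", "29", "--out", dir))

cfg <- file.path(dir, "train.json")
jsonlite::write_json(list(batch_size = 4, patience = 10,
                          crop = c(96, 96), loss = list(kind = "focal")),
                     cfg, auto_unbox = TRUE)
run <- file.path(dir, "run")
dbt_main(c("train", "--annotations", file.path(dir, "annotations.csv"),
           "--index", file.path(dir, "volume-index.csv"),
           "--config", cfg, "--epochs", "40", "--seed", "5",
           "--out", run))
#> epoch   1  loss 4.80269  val sens@2FP/slice 1.000  val loss 4.70966
#> epoch   2  loss 4.67492  val sens@2FP/slice 1.000  val loss 4.53422
#> ...
#> epoch  34  loss 0.01453  val sens@2FP/slice 1.000  val loss 0.00770
#> ...
#> epoch  40  loss 0.01199  val sens@2FP/slice 1.000  val loss 0.00918
#> best epoch 34, val sensitivity 1.000

dbt_main(c("predict", "--checkpoint", file.path(run, "checkpoint.rds"),
           "--index", file.path(dir, "volume-index.csv"),
           "--out", file.path(dir, "predictions.csv")))
#> wrote 32 predictions
dbt_main(c("evaluate", "--predictions", file.path(dir, "predictions.csv"),
           "--annotations", file.path(dir, "annotations.csv"),
           "--index", file.path(dir, "volume-index.csv"),
           "--mode", "breast", "--fp", "2", "--bootstrap", "200",
           "--seed", "7", "--out", file.path(dir, "report.json")))
#> breast-based sensitivity at 2 FP/volume: 1.000
```

The evaluate report (`report.json`) holds the FROC curve points, the
sensitivity at the requested FP rate, and the bootstrap CI; for this run
it reads `"sensitivity": 1, "n_lesions": 4, "n_volumes": 32,
"ci": [1, 1]` — all four phantom lesions (hence all four annotated
breasts) are found before the first false positive, so the interval
collapses. `sensitivity` is the fraction of breasts with at least one
detected lesion (any lesion, any view) at an operating point allowing 2
false positives per volume on average; at desk scale on easy phantoms it
saturates at 1.0 — the package's acceptance benchmark (20 normal + 6
lesion studies, held-out evaluation, 3-seed median) requires ≥ 0.8.

Note the failure mode visible if you train too briefly (say 10 epochs):
the confidence head fires but the scale regression still decodes
anchor-sized 256 × 256 boxes, which the breast-coverage filter then
rejects — `predict` writes 0 predictions. The localization term needs a
few dozen epochs at this scale.

The same stages are callable as functions (`generate_dataset()`,
`preprocess_volume()`, `train()`, `predict_volume()`, `froc_volume()`,
`froc_breast()`, `bootstrap_ci()`, ...); see the methods vignette
(`vignettes/dbtdet-methods.Rmd`) for the model, its assumptions, every
tunable parameter, and the package's numerical choices.

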