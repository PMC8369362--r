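---
title: "Single-phase lesion detection in digital breast tomosynthesis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-phase lesion detection in digital breast tomosynthesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Digital breast tomosynthesis (DBT) reconstructs a stack of cross-sectional
slices per view (LCC, RCC, LMLO, RMLO). Biopsied masses and architectural
distortions are annotated by radiologists as a single 2-D rectangle on the
lesion's central slice. `dbtdet` implements a complete baseline pipeline
for detecting such lesions: preprocessing, ground-truth construction,
a single-phase fully convolutional grid detector with a choice of four
class-imbalance losses, volume-level inference with merge-based NMS, and
FROC evaluation with the field's custom true-positive matching -- plus a
phantom simulator so every stage runs and is testable without patient
data.

## Preprocessing

Each slice is window-leveled using the DICOM header window (linear map of
`[center - width/2, center + width/2]` onto `[0, 1]`, clipped), downscaled
by 2 with a 2x2 local mean, and the breast is segmented by eroding the
nonzero pixels with a discrete disk of radius 5 px (skin removal) and
keeping the largest 8-connected component. Numerical choices the narrative
order of the source protocol leaves open, fixed here once:

* the erosion disk is `{(di, dj): di^2 + dj^2 <= 25}`;
* masking is per-slice (the detector is slice-wise), not volumetric;
* components are 8-connected;
* the step order is window -> downscale -> erode/segment;
* when header window tags are missing, the fallback is
  `(min + max)/2` / `max - min` of the pixel data.

Coordinates everywhere are 0-based, `x` along columns, `y` along rows,
boxes half-open `[x, x + w) x [y, y + h)`. Annotations live at full
resolution and are divided by 2 (floor) when mapped onto preprocessed
images.

## Ground truth

The 2-D annotation expands to 3-D by phase-specific rules:

* **training**: the slice span is `round(sqrt((w + h)/2))` (round half to
  even -- base R's rounding -- clamped to >= 1), centered on the annotated
  slice with the extra slice below the center for even spans, clipped to
  the volume without shifting. "Average dimension" is read as the
  arithmetic mean of the full-resolution width and height as drawn;
* **validation**: the same span halved (`max(1, round(count/2))`);
* **evaluation**: the box is assumed to span `round(0.25 * n_slices)`
  slices before and after its center slice.

Targets are encoded on a grid of 96 x 96-px cells: the cell containing a
box center is positive and regresses offsets `(center - cell_center)/96`
(in `[-0.5, 0.5)`) and log scales `ln(dim/256)` against a square
256 x 256-px anchor (in downscaled pixels, since all model I/O is
downscaled). One box per cell; collisions keep the larger box. The
parameterization is exactly invertible, which the round-trip tests
exploit.

## The detector

A fully convolutional network with a dense-block backbone: a 3x3 stem,
four dense blocks (each layer a 3x3 convolution producing `growth_rate`
channels, ReLU, concatenation), 2x average pooling after the stem and
after each block, a final 3x pool, and a 1x1 head with 5 channels per
cell: one confidence logit (sigmoid), two offsets (`tanh/2`, bounded to
`[-0.5, 0.5]`), two unbounded log scales. The pooling schedule realizes
the total stride of 96 exactly (2^5 * 3), so the output grid is
`(H/96, W/96)` for any input -- an invariant under test. Exactly four
dense blocks are required; other depths cannot realize stride 96 with
this schedule and are a configuration error.

Weights are Kaiming-initialized; the head uses a small normal
initialization (sd 0.01) and its confidence bias is set to
`-log((1 - pi)/pi)` with prior `pi = 0.01`, the standard dense-detector
trick that keeps a fresh network's confidence near the foreground
prevalence so the first epochs are not swamped by background gradient.
The default width (`growth_rate = 8`, blocks `2,2,2,2`) is sized for CPU
training on phantoms; the published networks' exact sizes are not
reproduced. Forward, backward and Adam are implemented on im2col + BLAS
primitives in the package's own compiled code, because no deep-learning
runtime is assumed in the target environment; gradients are verified
against finite differences in the test suite for all four losses.

## Losses

For objectness, four options treat the extreme foreground/background cell
imbalance: binary cross-entropy; weighted BCE with inverse-prevalence
weights normalized to `w_pos + w_neg = 2`; focal loss
`-alpha (1 - p_t)^gamma log p_t` (defaults alpha 0.25, gamma 2, the cited
convention -- the source protocol's exact values are in an appendix not
reproduced here, so they are configuration); and reduced focal loss,
which equals BCE while the true-class probability is below 0.5 and scales
it by `((1 - p_t)/0.5)^gamma` above, continuous at the threshold.
Localization is mean squared error over the four regression channels at
positive cells only. The total loss is `objectness + lambda *
localization` with `lambda = 1` by default (the weighting is not
specified by the source protocol). Probabilities are clamped at `1e-7`.

## Training protocol

Adam (framework-default betas), initial learning rate 0.001, batch size
16, up to 100 epochs with early-stopping patience 25; crops of
1056 x 672 px drawn uniformly among offsets that contain the whole
ground-truth box, on a slice drawn uniformly from the training span. An
epoch is one pass over the positive lesions only -- background cells
inside the crops supply the negatives; no negative mining is performed
and actionable-group volumes (which carry no boxes) are excluded from
training. Validation uses deterministic fixed crops (center slice of the
halved span, crop centered on the box) and the metric is 2-D sensitivity
at 2 false positives per slice.

One desk-scale reality: with small crops the 100-px matching floor makes
that validation sensitivity saturate at 1.0 within an epoch, which would
freeze early stopping on the first checkpoint. The model-selection rule
therefore breaks metric ties by the validation loss: an epoch improves
when its sensitivity is strictly higher, or equal with a strictly lower
validation loss. The kept checkpoint is never below the best observed
metric, and with a discriminative metric the rule reduces to the plain
protocol. Across losses, candidates are compared by 3-D
sensitivity-at-2-FP/volume on full validation volumes, ties broken by the
lower FP rate at which that sensitivity is reached, then by listed order.

## Inference

Slices are zero-padded bottom/right to the grid. The volume is split into
halves `[0, N/2)` and `[N/2, N)`; per-slice confidence and regression
grids are averaged elementwise within each half (both channels -- whether
averaging covers regression too is unstated in the source; both is the
simpler and smoother choice), each averaged grid is decoded at threshold
0.05, and each box receives the half's middle slice as `z` (the source
does not state a z-assignment; the middle is the natural representative,
and with the 25%-of-slices evaluation window it is provably within the
window of any lesion in the half). Boxes with fewer than half their
pixels inside the breast mask are discarded (exactly half is kept), then
merge NMS runs per volume to a fixed point: while any pair has score
ratio < 10 and IoU > 0.5, the highest-IoU pair (ties: higher max score,
then first) merges into the higher-scoring member's geometry with the max
of the two scores. Keeping the winner's geometry (rather than a union)
avoids box inflation; the merge order is fixed and oracle-tested since
the source specifies only the pair rule.

## Evaluation

A prediction matches a ground-truth lesion when its 2-D center is within
`max(gt_diagonal/2, 100 px)` of the GT center and its slice lies in the
evaluation slice window. The stricter variant that additionally requires
the predicted center inside the GT rectangle (mentioned in the source's
discussion but not its methods) is available as
`match_criteria(require_center_in_gt = TRUE)` and off by default.
Matching is greedy by descending score with one-to-one GT assignment
(nearest eligible GT first); the assignment scheme is unspecified in the
source, and the greedy builder is tested for equality against an
exhaustive per-threshold oracle on 1000 random scenarios. Sensitivity is
per lesion (volume mode) or per breast -- any lesion on any view counts
(breast mode) -- while the FP denominator is always per volume over all
evaluated volumes including lesion-free ones. `sensitivity_at()` reads
the curve as a step function without interpolation. Bootstrap CIs
resample patients (not volumes, to respect within-patient correlation;
the source states only "bootstrapping") with 2000 replicates and
percentile intervals; resamples with no ground truth are redrawn and
counted.

## The phantom generator

Phantoms are statistical look-alikes, not physically simulated
tomosynthesis: a half-elliptical breast attached to the chest-wall edge,
constant across slices, with Gaussian texture (mean 300, sd 50 in raw
units), a bright skin rim (mean + 8 sd) of ~6 px, and additive lesions --
masses as 3-D Gaussians (in-plane sd `size/4`, z sd `size/8`), and
architectural distortions as 8-16 radial spicules (lengths 0.4-0.6 of
the size per side, 1-2 px wide) with a faint Gaussian core. Biopsied
lesions draw contrast 4-6 noise sd; actionable-group lesions are subtle
(1.3 sd) and unannotated, mirroring that group's role. The lesion's true
z extent follows its own Gaussian profile and deliberately differs from
the square-root training rule, so that rule's effect is observable. The
realistic raw geometry (~2048 x 1024 x 60+) is too slow for CPU test
loops, so the `small` preset is a scaled stand-in (768 x 512 x 40, breast
semi-axes 400/330) and `tiny` (256 x 192 x 16) serves unit tests.

What a green end-to-end test establishes: the pipeline can learn and
localize bright, compact or spiculated structures against textured
background at the stated sizes and contrasts, with the whole
preprocessing/training/inference/evaluation chain intact. What it does
not establish: performance on real DBT (reconstruction artifacts, tissue
superposition, vendor differences, subtle lesions), for which the source
study's external data would be required.

## Desk-scale benchmark choices

The acceptance benchmark trains on a fixed-seed phantom dataset of 20
normal + 3 benign + 3 cancer studies (small preset) and evaluates
breast-based sensitivity at 2 FP/volume on a held-out set (8 normal +
2 benign + 2 cancer studies, disjoint seed), median over three training
seeds. Desk-scale parameters, fixed before measuring and sized to one
CPU: detector `growth_rate = 6`, `stem_channels = 8`; crops 192 x 288
(multiples of 96 that cover the downscaled phantom); batch size 4 (12
positive lesions per epoch make batches of 16 degenerate); at most 30
epochs, patience 10; focal loss. Normal-group training volumes are part
of the stated dataset but are never read by the training protocol
(epochs iterate positives), so they are not materialized -- the held-out
normals are, since they feed the FP denominator.

## Known limitations

* The DICOM layer is a deliberate subset (explicit VR little endian,
  uncompressed 16-bit grayscale, the ~20 tags used here); it is
  round-trip tested against itself, not against a reference DICOM
  implementation, because none is available in the target environment.
* The detector is 2-D slice-wise by design; no 3-D convolutions,
  multi-anchor heads, or cross-view fusion.
* Training at paper scale (768-model grid search, 19k volumes) is out of
  scope; the configuration surface supports a reduced grid.
* Phantom realism is intentionally minimal (no projection/reconstruction
  model, no calcifications, no implants/markers).
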