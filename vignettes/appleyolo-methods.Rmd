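---
title: "appleyolo: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{appleyolo: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Fruit-picking robots need a detector that runs on embedded hardware in an
orchard: apples appear at many sizes, overlap each other, hide behind
branches and leaves, and are photographed under changing light. `appleyolo`
implements a one-stage anchor-based detector of the YOLOv5-nano family for
this task, together with a lightweight variant that (a) replaces every C3
cross-stage-partial bottleneck with a partial-convolution "C3-light" block
and (b) inserts parameter-free SimAM attention on the three neck outputs.
The package's contribution is the *whole stack*, reimplemented from first
principles in R: the layer blocks with exact parameter/FLOP cost models, the
assembled detector graphs, CIoU + BCE training with hand-derived backward
passes, the mAP evaluation suite, the VOC/YOLO annotation pipeline with an
eight-way augmentation set, IoU-distance k-means anchors, and a synthetic
orchard generator so that everything is testable on one CPU without any
download.

No deep-learning framework is assumed: convolutions run as im2col GEMM
through BLAS (`src/ops.cpp` provides im2col/col2im and max-pool kernels),
and every node type carries an analytic backward pass. A composite model is
a flat DAG of primitive nodes (conv, pconv, maxpool, upsample, concat, add,
simam), which is what makes one forward/backward engine, one parameter
counter and one FLOP counter serve every architecture variant.

## Architecture

The baseline is the standard v7.0 nano layout: a 6x6 stride-2 stem (pad 2 —
the one place where "pad = k %/% 2" does not apply, because the kernel is
even), four stride-2 stages with C3 blocks repeated (1, 2, 3, 1) times at
depth multiple 0.33, channel widths (16, 32, 64, 128, 256) at width multiple
0.25 (rounded up to multiples of 8), SPPF with three chained 5x5 max-pools,
a PAN neck with two upsample and two downsample paths, and three 1x1
detection heads predicting `3 * (5 + nc)` channels at strides 8/16/32.

A C3 block splits its input into a bottleneck path (`n` bottlenecks of
1x1 conv then 3x3 conv, residual in the backbone, plain in the neck) and a
1x1 bypass, concatenates and mixes with a final 1x1 conv.

**C3-light layout.** The reference account specifies *that* the bottleneck's
spatial convolution becomes a partial convolution with ratio 1/4 and
pointwise mixing, but not the exact internal wiring; the printed per-module
parameter totals are the arbiter. The layout that reproduces them exactly —
summed over all eight C3 instances, 972,096 parameters for C3 versus
664,464 for C3-light — is FasterNet-style:

```
PConv(3x3, c_p = c/4, weights only, no norm/activation)
  -> 1x1 conv c -> 2c, BN + SiLU
  -> 1x1 conv 2c -> c, no BN, no bias, no activation
(+ residual add in the backbone form, none in the neck form)
```

PConv convolves only the **first** contiguous `c/4` channels (both ends are
admissible in principle; "first" is fixed for reproducibility) and passes
the rest through untouched, so its multiply-accumulates are `(c_p/c)^2 =
1/16` of a dense convolution of the same kernel.

**SimAM** computes, per channel, the energy
`E = (x - mu)^2 / (4 (sigma^2 + lambda)) + 0.5` with mean and variance over
the spatial positions (variance with divisor `h*w - 1`) and returns
`x * sigmoid(E)`. It has zero learnable parameters; `lambda` defaults to
`1e-4`, the value used by the original attention formulation (the source
account never states it). A 1x1 spatial map has undefined variance and
raises an error (documented choice over a silent identity fallback). Three
SimAM nodes sit on the three neck outputs of the light variant.

With the stock 80-class head the three builds count 1,872,157 (baseline)
and 1,564,525 parameters (light variant, with or without SimAM) — the
reference accounting uses the stock head even though training uses one
class; both are a single `nc` switch here.

## Cost accounting

Parameters count learnable arrays only: convolution weights and biases and
BN affine pairs; BN running statistics are buffers. FLOPs at a stated input
size use one fixed convention, chosen as the only one consistent with the
reference one-decimal baseline figure (4.5 GFLOPs at 640):

* convolution / partial convolution: 2 x multiply-accumulates
  (+1 op/element for a bias);
* inference-time BN affine: 2 ops/element;
* SiLU: 4 ops/element (exp, add, divide, multiply);
* k x k max pool: k^2 - 1 comparisons/element;
* residual add: 1 op/element; SimAM: 10 ops/element;
* nearest upsample / concat: 0 (memory copies).

Under this convention the baseline totals 4.546 GFLOPs and the light+SimAM
variant 3.769 at 640x640, i.e. 4.5 and 3.8 at the printed precision, whose
rounded values give the headline 15.56% reduction. Conv-only 2xMAC counting
would give 4.47/3.68 (a 3.7 print), which contradicts the reference pair;
headline percentages are therefore always computed from one-decimal GFLOPs.
Relative changes are `100*(a-b)/a` (reduction) and `100*(b-a)/a`
(improvement), rounded to two decimals; the denominator is always the
reference value, so exchanging arguments does not negate the result.

## Data pipeline

Pascal VOC XML is read/written with `xml2`; pixel corners are treated as
0-based and half-open after conversion, so a box's normalized width is
`(xmax - xmin)/width`. YOLO TXT labels are `class cx cy w h` at six
decimals; read is the exact inverse of write at that quantization. Images
travel as Netpbm PPM/PGM (P2/P3/P5/P6) because the target environment has
no PNG/JPEG reader; everything downstream operates on plain arrays.

The eight augmentations use the reference parameter ranges: Gaussian blur
sigma (0.5, 3.0); average blur k (2, 11); colorspace — interpreted as a hue
rotation of (10, 50) degrees; brightness (-50, 50) grey levels; Gaussian
noise, whose bare parameter "3" is read as sigma = 3 grey levels;
horizontal and vertical flips (which remap box centers, `cx -> 1 - cx` /
`cy -> 1 - cy`); and resize with factor (0.5, 0.8) (normalized boxes are
scale-free). A 500-image corpus expanded to 2700 is not an integer multiple
of one image's augmentations, so `build_augmented_dataset()` uses a
cumulative-rounding schedule: image `i` of `n` receives
`round(i*e) - round((i-1)*e)` augmented copies with `e` the mean extra
count, hitting the target total exactly for any multiplier.

`split_dataset()` computes validation and test sizes as `round(n*r/sum(r))`
with the remainder to train (2700 at 8:1:1 gives 2160/270/270), sorts before
the seeded shuffle so the split is invariant to input order.

`kmeans_anchors()` runs Lloyd's algorithm on pixel (w, h) shapes under the
shape-aware `1 - IoU` distance (no genetic refinement — only k-means is
claimed by the source). Lloyd is initialization-sensitive, so ten seeded
restarts are run and the lowest-cost solution kept; on separable shape
distributions this reproduces a brute-force multi-restart oracle to 1e-6.
Centroids are sorted by area into three groups of three.

## Synthetic orchard scenes

The generator emulates the conditions the real corpus varies — fruit size,
fruit-on-fruit overlap, branch/leaf occlusion, day/dark/overexposed
lighting, blur — with shaded radial-gradient ellipses plus a specular spot
on a textured background, and branch/leaf occluders drawn on top. It tracks
per-pixel ownership, so ground-truth boxes are tight around the *visible*
pixels of each apple, and a box is culled when less than `min_visible`
(default 0.25) of its apple remains visible. `min_sep` controls how close
apple centers may fall (0.6 of the radius sum by default, which allows
partial overlap; values >= 1 keep apples disjoint — the "trivially easy"
configuration). Everything is deterministic per seed, and per-scene seeds
are recorded in a JSON manifest.

What a green test on these scenes does **not** establish: photorealism,
natural texture statistics, the class imbalance and annotation noise of
real orchard photos, or the reference accuracy numbers — those require the
original image corpus and GPU-scale training, which are out of scope by
design.

## Training

Targets follow the stock anchor assignment: a ground-truth box matches an
anchor when `max(w/aw, aw/w, h/ah, ah/h) < 4`, and is placed in its
containing grid cell plus up to two neighbor cells (those whose center is
within half a cell of the box center). The loss is the weighted sum of

* a CIoU box term over matched anchors (`1 - CIoU`, with the center
  distance and aspect-ratio penalties; `alpha` is treated as constant in
  the gradient, per the usual formulation),
* BCE objectness over every cell (target = clamped CIoU of the matched
  box, 0 elsewhere), per-scale means with balance weights (4, 1, 0.4),
* BCE classification over matched cells — retained for `nc = 1` so the
  loss keeps its three-term structure; with a single class it saturates
  immediately and costs nothing.

Default term weights are the stock balance (box 0.05, obj 1.0, cls 0.5).
Per-image scale-mean losses are **summed** over the mini-batch before the
SGD step (the stock batch-scaled convention; with plain averaging the
effective learning rate is batch-size too small). BCE gradients are
analytic; the box term's gradients with respect to its four logits are
central finite differences of the CIoU (exact to O(eps^2) with eps = 1e-4;
matched anchors are few, so the extra function evaluations are negligible
— an intentional robustness-over-elegance choice).

The learning rate follows `lr(e) = lr_floor + (lr0 - lr_floor) *
(1 + cos(pi e/E))/2` — 0.01 at epoch 0 and 0.0001 at the final epoch with
the reference defaults — plus a short linear warmup over the first batches.
The reference parameter table lists a second "learning rate 0.0001" row
that could be either the cosine floor or the (separately stated) weight
decay; both are set to 0.0001 here, which is consistent with either
reading. SGD momentum is 0.937; weight decay applies to convolution weights
only. Detection-head biases are initialized to the standard low-objectness
prior.

**Batch normalization.** The engine processes images one at a time, so BN
statistics are per-image spatial statistics. Running EMA buffers are
tracked, but they average normalizers of individual images and proved
uncalibrated for inference; inference therefore defaults to the same
per-image statistics (`bn = "batch"`), with the folded-affine running mode
available as `bn = "running"`. This is the one deliberate deviation from
the reference detector's inference behavior, forced by the single-image
engine, and it keeps train and test distributions identical.

## Evaluation

Detections decode as `xy = (2 sig(t) - 0.5 + cell) * stride`,
`wh = (2 sig(t))^2 * anchor`, confidence = objectness x best class score,
filtered at the confidence threshold (default 0.25) and reduced by greedy
class-agnostic NMS at IoU 0.5 (class-agnostic because the task has one
class; ties break toward the lower box index). Matching to ground truth is
greedy one-to-one in confidence order at the evaluation IoU. Precision,
recall and F1 use the zero-denominator conventions P = 0 with no
detections, R = 0 with no ground truth. AP integrates the
precision-recall curve by all-point interpolation (monotone precision
envelope, sum of recall-step rectangles); a 101-point variant is available
behind `interp = "101"`. mAP0.5:0.95 averages the ten IoU thresholds; with
one class mAP equals AP. The PR sweep uses a 0.001 confidence floor so the
integral sees the full ranking, while P/R/F1 are reported at the operating
threshold — the field's convention.

## The learning-sanity experiment

The acceptance suite trains the light+SimAM variant (nano width, 160x160
input, `nc = 1`) from scratch on 48 easy synthetic scenes (1-3 large
disjoint apples, no occluders, day light), with k-means anchors from the
training labels: SGD, lr 0.02 cosine to 0.002 over 36 epochs, batch 8 —
about nine minutes on one CPU. It must reach AP0.5 >= 0.9 on 12 held-out
scenes (the run used for calibration reached 0.99) with a monotonically
falling 9-epoch-smoothed training loss. The learning rate differs from the
reference 0.01 because that value belongs to a 200-epoch full-resolution
transfer-learning run; a 36-epoch from-scratch schedule is a different
optimization problem, and the learning rate is a knob of the stand-in, not
a reported quantity. This experiment validates that the implemented blocks,
assignment, loss, gradients, decoding and metrics cohere end to end; it
does not claim any reference accuracy number.

## Numerical choices and limitations

* BN eps 1e-5, momentum 0.1; SiLU everywhere except the final C3-light
  pointwise conv and the heads.
* Weight init: Kaiming-scaled Gaussians, seeded; builds are bit-reproducible
  per seed, and every public source of randomness takes a seed argument
  (never wall-clock).
* Max-pool ties resolve to the first element in scan order; NMS ties to the
  lower box index; `>=` at the confidence threshold.
* The checkpoint format is RDS (a run-time artifact, not a data format).
* Single-image processing makes training O(batch) in memory but forgoes
  cross-image BN; see above.
* R-level loops over graph nodes put a constant factor on top of BLAS; the
  engine trains small models comfortably but is not a GPU framework, by
  design.
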