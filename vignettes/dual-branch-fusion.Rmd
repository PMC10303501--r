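---
title: "Dual-branch CNN feature fusion for pod and seed images: methods and design"
author: "PodSeedFusion authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch CNN feature fusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Mutant lines derived from a single parent cultivar by mutagenesis are far
more similar to one another than ordinary varieties are: the betweeen-line
differences visible in any one organ are subtle, and a classifier trained on
seed images alone (or pod images alone) confuses specific line pairs. The
idea implemented here is *organ fusion*: extract a deep feature vector from
a pod image and one from a seed image of the same line, concatenate them,
and classify the joint vector. Pairs of lines that are indistinguishable in
one organ but not the other become separable in the fused representation,
which is where the accuracy gain comes from.

`PodSeedFusion` implements the complete workflow: scanner-image
segmentation, class balancing and stratified splitting, CNN feature
extraction, concatenation fusion, SVM classification, evaluation, and the
downstream analyses (Grad-CAM, t-SNE, clustering trees) used to interpret
which lines confuse and why. Because the real scanner datasets used for
this kind of study are rarely deposited, the package ships a parametric
synthetic generator that reproduces the *structure* of the problem
(near-duplicate sibling lines, organ-complementary signal) with exact
ground truth, so every stage is testable offline.

# Segmentation and canvas normalization

A scan contains many seeds or pods of one line on a black background
(flatbed scanner with the cover open). The pipeline is classical:

1. luminance grayscale (ITU-R BT.601 weights 0.299/0.587/0.114);
2. binarization, by default Otsu's between-class-variance maximization on a
   256-bin histogram (a fixed threshold is available for reproducibility
   work);
3. connected components (8-connectivity by default; 4 available) with a
   minimum area of 64 px to reject debris, ordered row-major by
   bounding-box corner so outputs are deterministic;
4. each object is pasted, centred, onto a 300 x 300 black canvas, with
   every pixel outside the object mask exactly (0,0,0).

The canvas step is the important design point: resizing each crop to the
network input would destroy true size information, one of the few traits
that separates near-isogenic lines. The canvas preserves absolute scale and
defers resizing to a single, common bilinear step at the network input.
Objects larger than the canvas either raise an error (default) or are
downscaled aspect-preserving with a warning.

Touching objects are *not* separated (no watershed): the acquisition
protocol this emulates removes adhered objects manually, and the synthetic
generator enforces a minimum gap. `dropBorderTouching` and `minAreaPx` are
the automated analogues of that manual cleaning.

Images are stored as numeric arrays in `[0, 1]` (the convention of R's
PNG/TIFF readers); the 8-bit value 255 corresponds to 1.0. PNG and TIFF are
supported; JPEG is not.

# Augmentation and splitting

Groups (class x organ) are balanced to a target count (default 1000) by
seeded geometric augmentation: rotation (default 90/180/270 degrees, exact;
arbitrary angles use nearest-neighbour resampling), shifts of at most 10%
of the canvas (capped so content never leaves the canvas), vertical flip
and horizontal mirror. Photometric augmentation is deliberately out of
scope: colour is a discriminative trait here, and jittering it would change
the task.

The stratified split is 8:1:1 with floor allocation and the remainder to
train: 1000 images yield exactly 800/100/100, 1001 yield 801/100/100.

Augment-then-split (the classical order) lets near-duplicates of one
original land in both train and test, which inflates test accuracy. The
default mode therefore splits *first* and augments only the training
partition to its 8/10 share; `mode = "augment_then_split"` reproduces the
classical order for comparison. This is the one place where the package
intentionally deviates from the classical recipe by default; the escape
hatch keeps the comparison honest.

# Backbones and the CNN engine

No deep-learning framework is assumed: the package contains a compact CNN
graph engine (im2col/col2im convolution kernels in C++, max/average
pooling, inference-mode batch norm, residual adds, inception concats, fully
connected and softmax layers) with forward and reverse-mode backward passes
for every layer type. That is exactly the functionality feature
extraction, head retraining and Grad-CAM need, and nothing more: this is
not a general training framework, and large-scale GPU training is a
non-goal.

Five backbones are registered, mirroring the classical transfer-learning
quartet plus a test network:

| backbone  | input        | spatial layer               | pooling (fusion) layer   | softmax layer    |
|-----------|--------------|-----------------------------|--------------------------|------------------|
| alexnet   | 227x227x3    | `fc8` (= K)                 | `relu7` (4096)           | `prob` (K)       |
| googlenet | 224x224x3    | `inception_5b-output` (50176) | `pool5-7x7_s1` (1024)  | `prob` (K)       |
| resnet18  | 224x224x3    | `res5b_relu` (25088)        | `pool5` (512)            | `prob` (K)       |
| resnet50  | 224x224x3    | `activation_48_relu` (25088) | `avg_pool` (2048)       | `fc1000_softmax` (K) |
| tiny      | 64x64x3      | `relu3` (16384)             | `avg_pool` (64)          | `prob` (K)       |

Two table-fidelity notes. Published layer tables for this architecture
family sometimes print AlexNet's `fc8` as 1 x 4096; a retrained K-class
head necessarily has K outputs, so `fc8` is K here and `relu7` is the
4096-dimensional AlexNet fusion layer. Similarly, a printed value of
1 x 50176 sometimes attached to ResNet50's `activation_48_relu` belongs to
GoogLeNet's `inception_5b-output`; in a standard ResNet50 the 48th ReLU is
the 7 x 7 x 512 activation before the final residual addition, i.e. 25088
values, and that is what the package declares and emits.

Weights are seeded He-normal by default (`weights = "random"`), which is
also what the test suite uses: every structural contract (layer shapes,
fused widths, determinism) is independent of the weight values.
`weights = "pretrained"` loads a user-supplied RDS parameter file; no
weights are bundled and nothing is downloaded. Local response
normalization of the original AlexNet is omitted — it changes no shape and
post-AlexNet practice dropped it.

Fine-tuning (`finetuneBackbone()`) uses seeded mini-batch SGD with
momentum 0.9, batch size 32, learning rate 3e-4 and validation every 64
steps by default — the classical transfer-learning recipe. The published
recipe freezes "several preceding" convolution layers; since that phrase
does not pin down a layer set, the default here is the clean extreme
`freeze_all_conv` (train the head only, provably leaving every convolution
parameter bit-identical), with `freezePolicy = "none"` running full
backpropagation. Input normalization defaults to the identity so that the
black canvas stays exactly zero through the input (appropriate for
random/from-scratch weights); ImageNet channel statistics are available via
`imagenetNormalization()` for pretrained weights.

Feature vectors are activations flattened row-major (a fixed, tested
convention), and the extractor enforces the declared dimensionality.

# Pairing, fusion and the SVM

Pod and seed images are physically unrelated objects, so same-class members
must be paired explicitly before concatenation — a step the workflow needs
but published descriptions rarely state. The default is a deterministic
round robin over path-sorted lists (cycling the shorter list); seeded
random pairing and capped exhaustive pairing exist for sensitivity checks.
`pairsPerClass` defaults to the smaller organ count per class.

Fusion is plain concatenation, pod block first: two 2048-wide
global-average-pool branches give a 4096-wide fused vector. The classifier
is a one-vs-one soft-margin SVM (libsvm via `e1071`), linear kernel by
default — the sensible choice in thousands of dimensions with hundreds of
samples — with C = 1. Before the SVM, features are z-scored per dimension
with a standardizer fitted on the training pairs only; the fitted
`FusionClassifier` freezes those constants, so the standardizer cannot be
refit on test data through any public interface. Concatenated activations
from different layers have very different scales, which is why
standardization is built in rather than optional.

# Evaluation

Confusion matrices are stored with rows = predicted class and columns =
true class, so column sums are the per-class test counts. Per class,
`P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, with the 0/0 case
defined as 0 (with a warning and an `excluded` flag for classes absent from
both truth and prediction). Macro averages are unweighted means over
classes; micro averages are reported alongside. Accuracy is the trace over
the total.

Replicate results are summarized as mean ± SE with SE = sample SD
(n − 1 denominator) / sqrt(n) by default. Published ± values in this
literature do not always state their convention (some are closer to a
population SD without the sqrt(n)); a `population` option covers the
SD-over-sqrt(n) variant, and the choice is explicit in the API rather than
guessed.

# Analysis tools

**Grad-CAM.** The gradient of a class logit is backpropagated to a chosen
spatial layer; channel weights are the spatial means of those gradients,
the heat map is the ReLU of the weighted activation sum, min-max normalized
and bilinearly upsampled over the input. Two analytic regression tests pin
the implementation: a zero-weight head yields an all-zero map, and a head
reading a single channel yields exactly that channel's normalized
activation. Heat-concentration checks (fraction of heat inside the object
mask) are meaningful when the object occupies a reasonable share of the
input frame (roughly 20%+); for a small object on a large canvas the
receptive-field halo around the object dilutes the fraction, which is a
property of CNN geometry, not a defect of the map.

**t-SNE.** An exact O(n²) implementation (perplexity calibration by
per-point binary search, early exaggeration, momentum descent with
adaptive gains), deterministic given its seed. It is intended for the
scale at which it is used here — hundreds of samples or class centroids —
and refuses n ≤ 3·perplexity. Perplexity defaults to 30 in the embedding
API; the pipeline uses smaller values consistent with its sample counts.

**Clustering trees.** Class-level trees are built over per-class mean fused
feature vectors. "K-means clustering tree" is an ambiguous recipe (k-means
yields partitions, not trees), so the package implements two explicit
modes: the default is agglomerative clustering (Ward, `ward.D2`, on
Euclidean distances) directly on the centroids; an optional divisive mode
recursively bisects classes with seeded 2-means, with merge heights equal
to the within-cluster sum of squares of the split cluster. A `via3d`
option first reduces centroids to 3-D with t-SNE, mirroring workflows that
cluster a 3-D embedding; it requires K > 3·perplexity and is therefore off
by default at the small K used in the bundled experiments (direct Ward on
centroids is also deterministic, which the embedding route is only per
seed). Trees export to Newick via `ape` for interoperability.

# The synthetic generator: what it emulates and what it does not

`generatePhenotypes()` draws K parametric class phenotypes: seeds are
speckled shaded ellipses with a darker hilum patch (axes ~16–24 x 11–17 px,
HSV colour with saturation 0.4–0.75 and value 0.55–0.95, speckle density up
to ~1%); pods are curved chains of 2–4 lobes with a connecting spine and a
longitudinal sinusoidal texture (half-length 40–60 px, width 10–16 px).
Hues are spread around the colour wheel so unrelated classes are clearly
distinct. Saturation/value floors keep objects well above the black
background, as in real cover-open scans — the generator emulates scans on
which threshold segmentation *works*, and a luminance floor of 0.2 plus the
spine guarantee objects binarize to single components.

Two structures control difficulty:

* **Sibling pairs** emulate near-indistinguishable line pairs: the partner
  shares the class's colour and differs only by a small multiplicative size
  delta (default 1.5%), deliberately inside the ~5% per-object size jitter.
  Under the default delta, sibling phenotypes sit at under 10% of the
  median inter-class parameter distance. Siblings are expected to show the
  lowest per-class recall and to merge first in the clustering tree.
* **Complementary pairs** carry the fusion signal: the two partners have
  *identical* parameters in one organ and differ clearly in the other, so
  any single-organ classifier confuses them at chance while the fused
  classifier separates them. The `complementarity` knob sets the fraction
  of non-sibling partner pairs that behave this way, alternating which
  organ is informative.

Scans place objects by rejection sampling with gap-padded tight bounding
boxes (minimum 3 px gap), guaranteeing non-touching objects and exact
ground-truth masks, boxes and counts; a placement that cannot be satisfied
raises a capacity error rather than silently overlapping.

What the generator does *not* model: photorealistic seed/pod texture,
shadows and specular highlights, colour calibration drift, touching
objects, or any genetics of mutagenesis. Consequently, passing tests show
that the *pipeline machinery and its statistical behaviour* are correct
under controlled conditions — count recovery, leakage-free bookkeeping,
fusion superiority when signal is organ-complementary, sibling
confusability — not that any particular accuracy will be attained on real
scanner data.

# Problem sizes used in the bundled experiments

The test suite and the acceptance script run the full pipeline at
deliberately modest scale, chosen as the smallest sizes at which the
studied effects are comfortably resolved: the fusion experiment uses K = 8
classes at complementarity 0.5, 5 scans x 10 objects per class per organ
(50 objects per class-organ; 40/5/5 after the 8:1:1 split), the tiny
backbone, and 3–5 seeds; the sibling experiment uses K = 6 with one
sibling pair at the same per-class sizes; bookkeeping checks augment two
classes to 1000 images each. With these sizes a single pipeline run takes
tens of seconds on one CPU. The same code runs unchanged at larger K,
image counts and backbones.

# Numerical and degenerate-input choices

* Otsu operates on a 256-bin histogram; the threshold is the upper edge of
  the arg-max bin, and foreground is strictly greater than the threshold.
* Empty masks segment to empty lists, not errors; an empty scan is valid.
* ROI ordering is row-major by bounding-box corner; ties break by column.
  Coordinates are 0-based, half-open on max edges.
* Split groups smaller than 3 are an error (cannot populate three splits).
* SVM standardizer: zero-variance dimensions get scale 1 (they carry no
  information and must not produce NaNs).
* t-SNE distances are clamped at 0 before the Student-t kernel; P and Q are
  floored at 1e-12.
* All randomness flows through explicit seeds; derived stream seeds stay
  below 2^31. Reruns of a pipeline config are bit-reproducible, including
  the metrics JSON.

# Known limitations

* The CNN engine is single-image (no batching) and CPU-only; it is sized
  for feature extraction and small fine-tuning jobs, not for training deep
  backbones from scratch.
* `weights = "pretrained"` requires the user to provide converted weights;
  none ship with the package, so transfer learning from ImageNet is a
  bring-your-own-weights affair.
* JPEG input is unsupported (no JPEG reader among the package's
  dependencies); convert to PNG or TIFF first.
* Fusion is unweighted concatenation by design; learned or weighted fusion
  and more than two branches are out of scope.
* The augmentation set is geometric only, matching the task's semantics.
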