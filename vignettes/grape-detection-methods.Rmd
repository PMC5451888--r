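---
title: "Methods: weighted grayscale conversion, HOG-SVM berry detection and simplex-grid tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted grayscale conversion, HOG-SVM berry detection and simplex-grid tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grapedetect)
```

## The detection problem

The detector classifies 40 × 40 px RGB *object images* cut from vineyard
photographs into two classes. A window is **positive** when it contains a
circular berry of diameter between 30 and 40 px whose center sits within
±1 px (Chebyshev) of the window center; everything else is **negative**.
Negatives come in two kinds that matter for evaluation: *environment*
windows share no pixel with any target berry disc, while *grape* windows
touch an in-range berry disc without satisfying the positive criteria
(off-center or cut berry fragments).

The vision pipeline has three stages:

1. **Image preprocessing** — one of four variants:
   `O` (BT.601 grayscale conversion + linear contrast normalization to
   [0, 1]), `S1` (conversion only), `S2` (no preprocessing), and `R`, the
   *robust* variant, which generalizes the conversion to a weighted mean

   $$I^* = w_R I_R + w_G I_G + w_B I_B,\qquad
     w_R + w_G + w_B = 1,\; w_i \in [0,1],$$

   turning the fixed BT.601 triple (0.299, 0.587, 0.114) into one point of
   a tunable family on the unit 2-simplex.
2. **HOG descriptor** at a fixed configuration: unsigned gradients voted
   linearly into 9 orientation bins over 0–180°, 6 × 6 px cells, 2 × 2-cell
   blocks with one-cell overlap. On a 40 × 40 window this gives
   6 × 6 cells → 5 × 5 blocks × 4 cells × 9 bins = a 900-dimensional
   feature vector.
3. **Soft-margin SVM** with a linear or Gaussian kernel,
   $k(u,v) = \exp(-\lVert u-v\rVert^2 / 2\sigma^2)$, regularization
   constant $C$ and kernel width $\sigma$.

`grape_detector()` fits the whole pipeline and returns a classed object
with `predict`, `print` and `summary` methods.

## Numerical choices in the descriptor

The descriptor configuration is fixed, but several details are
underdetermined by "standard settings" and had to be pinned:

* **Gradients**: centered differences `[-1, 0, 1]` in each direction, edge
  replication, no pre-smoothing. Orientations are folded modulo 180°.
* **Cell grid on 40 px**: 40 is not divisible by 6, so the descriptor uses
  the central 36 × 36 px region (a symmetric 2-px crop). This keeps the
  berry center aligned with the descriptor center.
* **Orientation voting**: each pixel's magnitude is split linearly between
  the two nearest bin centers (10°, 30°, …, 170°, wrapping across 180°).
  Votes therefore conserve total magnitude per cell, which is tested.
* **Block normalization**: L2-Hys — L2 normalization with guard
  $\varepsilon = 10^{-6}$, clipping at 0.2, renormalization. Zero-gradient
  blocks map to zero vectors. Note that renormalization after clipping
  legitimately pushes individual entries above the 0.2 ceiling (they stay
  in [0, 1]); the invariants that hold are block norm ≤ 1 and entry
  non-negativity.
* **Multi-channel input** (variant `S2` feeds RGB straight to the
  descriptor): per pixel, the channel with maximal gradient magnitude
  supplies both magnitude and orientation — the standard multi-channel HOG
  convention.
* **Concatenation order**: row-major blocks, row-major cells within a
  block, ascending bins. Any consistent order would do, since the
  classifier trains and predicts on the same layout.

Intensities live on a real [0, 1] scale internally; 8-bit PNGs are divided
by 255 on read. Images are treated as stored (no gamma linearization).

## The classifier contract

The SVM optimizer is not this package's contribution, so the solver is
libsvm (via e1071) at a pinned tolerance of $10^{-3}$ with kernel caching.
The Gaussian kernel is parameterized by the width $\sigma$; the single
conversion point to the solver's $\gamma = 1/(2\sigma^2)$ is centralized in
`sigma_to_gamma()` and unit-tested, so the $\sigma$ grid
{1, 10, 20, 30, 40, 100} maps onto the solver consistently. A decision
score of exactly zero resolves to "negative": the detector should not
assert a berry without positive evidence.

## Performance measures

With confusion counts TP, FN, FP, TN:

* accuracy $= 100\,(TP+TN)/(TP+FN+FP+TN)$ — percent scale,
* precision $= TP/(TP+FP)$ and recall $= TP/(TP+FN)$ — unit scale,

mirroring the mixed convention of the field's result tables. Zero
denominators yield `NA`, never 0, so undefined measures stay visible in
reports and drop out of any argmax.

## Dataset construction and rotation augmentation

Positive samples are expanded by exact quarter-turn rotations
($\varphi \in \{0, \pi/2, \pi, 3\pi/2\}$, pixel permutations, lossless), a
×4 augmentation that probes the descriptor's rotation sensitivity. Set
types enforce their compositional rules both on build and on load:

* `T` (training): unique positives and negatives, equal counts, no
  augmentation (default quota 288 + 288);
* `tuning`: positives ×4, negatives split between environment and grape
  kinds (default 1000 → 4000 / 4000). Only an even representation of the
  two kinds is required; an exact 50/50 split is enforced here;
* `E`/`EX` and `G`/`GX`: augmented positives with environment-only or
  grape-only negatives (default 500 → 2000 / 2000);
* `SX`: unique samples only — untouched by the rotation distortion
  (default 2000 / 2000).

Manifests are tab-separated text plus individual PNGs; samples are
quantized to the 8-bit grid on construction so write-then-read reproduces
a set bit-exactly. Train/tuning/test pools are built from disjoint scene
seed ranges, and `assert_disjoint()` additionally compares content keys, so
leakage is caught even for coincidentally identical windows.

## The tuning methodology

Tuning searches the space $\Theta$ of settings
$\theta = (C, \sigma, \mathbf{w})$:

1. choose measures and priorities (default: accuracy > recall >
   precision);
2. form the grids — $X_C$, $X_\sigma$, and the simplex lattice $W$ of all
   weight triples at integer multiples of $\Delta w = 1/p$
   ($|W| = (p+1)(p+2)/2$; 231 members at $p = 20$);
3. train on the training set and evaluate on the tuning set for every
   $\theta$ (features are computed once per weight triple and shared
   across the $(C, \sigma)$ grid; records are cacheable on disk keyed by a
   content hash of inputs and setting);
4. –5. review the per-$(C,\sigma)$ ternary surfaces and eliminate
   anomalous settings. The expert-review step is made reproducible as a
   chance-level filter: a $(C, \sigma)$ pair is eliminated when more than a
   threshold fraction (default 0.5) of weight triples score within 0.5
   accuracy points of the 50% chance level — the degenerate
   near-chance-with-isolated-peaks patchwork that small kernel widths
   produce. An explicit exclusion list can override or extend the filter,
   and the surfaces remain available for human inspection;
6. take the per-measure argmax over the surviving space, ties broken
   lexicographically by $(C, \sigma, w_R, w_G, w_B)$ ascending;
7. resolve the global optimum by priority: measures whose score range over
   the surviving space is below a flatness tolerance (default 0.005 on the
   unit scale) are dropped as non-discriminating; coordinates on which all
   retained optima agree are fixed; the rest come from the
   highest-priority measure's optimum. The full decision trace is kept on
   the returned object.

Both the filter threshold and the flatness tolerance replace qualitative
expert judgments that have no canonical numeric values; the defaults are
this package's declared choices. Fixed-conversion versions (`S1`, `S2`,
`O`) skip the surface-review step, which only exists for the weight
simplex.

## Ternary surfaces

A ternary diagram shows one measure over the weight simplex at fixed
$(C, \sigma)$. The axis convention: the red weight is read on the left arm
and increases downwards, green on the bottom arm increasing rightwards,
blue on the right arm increasing upwards — which places the $w_R = 1$
vertex bottom-left, $w_G = 1$ bottom-right and $w_B = 1$ on top of a
point-up equilateral triangle. Rendering shades the triangle by
barycentric interpolation over the regular lattice triangulation;
undefined scores render as gaps; `lookup()` reads the nearest member's
score with lexicographic tie-breaking. Output is drawn on a cairo PNG
device, so regenerating a figure from the same records is reproducible.

## The synthetic scene generator

No study imagery was deposited, so the package generates its own:
low-frequency smoothed-noise backgrounds with Lambertian-shaded circular
berries (radius-dependent shading plus an off-center highlight, half-pixel
anti-aliased rim), berry diameters drawn from [30, 40] px. Berry centers
snap to the half-integer pixel lattice so a 40-px window can center a
berry exactly and integer jitter maps to exact offsets {−1, 0, 1}. The
per-channel `contrast` triple scales the berry/background difference per
channel; a zero-contrast channel carries no berry signal at all, which is
what the weight-recovery experiments exploit. All randomness is fixed by
the scene seed; identical parameters give bit-identical scenes.

What the generator does *not* emulate: leaves, stems, specular clutter,
illumination gradients, perspective, camera noise statistics, or the
capture conditions of real vineyard photography. Passing tests on this
imagery therefore demonstrate that the pipeline, bookkeeping and tuning
machinery behave as specified and that the weighted conversion recovers
channel-confined signal — not that the detector attains any particular
accuracy on real vineyard photographs.

## Study conditions used by the experiments

The weight-recovery experiment confines the berry contrast to one channel
(triple (0.35, 0, 0) for red, mirrored for blue) over background noise of
amplitude 0.25 at texture scale 4 px. These values were chosen by
profiling accuracy against the signal-channel weight: at this noise level
accuracy rises monotonically from near-chance (≈53% at weight 0) to ≈94%
(weight 1), so the weight axis is informative; at low noise the task
saturates and the argmax degenerates to the tie-break rule. The recovery
runs use reduced grids ($p = 10$, $X_C = \{1, 10\}$,
$X_\sigma = \{20, 40\}$ for the Gaussian kernel) with a 100 + 100 training
set and a 200 + 200 tuning set (50 unique positives × 4 rotations + 100
environment + 100 grape negatives); the linear-kernel mirror runs at
$p = 5$. Combinatorial checks (surface counts, lattice size, augmentation
factors) use the full published grids, since enumeration is cheap; only
the training-evaluation sweeps are scaled down.

## Worked example

```{r example, eval = FALSE}
# build small disjoint pools from synthetic scenes
train_pool <- synth_pool(n_pos = 50, n_env = 25, n_grape = 25, seed = 1)
test_pool  <- synth_pool(n_pos = 50, n_env = 25, n_grape = 25, seed = 900)

train <- build_set("T", train_pool$positives, train_pool$negatives,
                   name = "train")
test  <- build_set("SX", test_pool$positives, test_pool$negatives,
                   name = "test")

fit <- grape_detector(train, version = "R", weights = c(0.95, 0.05, 0),
                      kernel = "rbf", C = 10, sigma = 30)
evaluate_detector(fit, test)
```

## Known limitations

* Full-scene scanning (sliding-window acquisition with non-maximum
  suppression) is out of scope; the detector classifies given 40 × 40
  windows.
* The descriptor implements the stated HOG *configuration* from scratch;
  bit-for-bit equivalence with any particular HOG library is not claimed.
* The anomaly filter and the flatness tolerance are reproducible stand-ins
  for qualitative expert judgments; their defaults are this package's
  choices.
* Multi-resolution grid refinement and cross-validation tuning are
  deliberately not implemented.
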