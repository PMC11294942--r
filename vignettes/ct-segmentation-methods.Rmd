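---
title: "Intensity-mixture and encoder-decoder segmentation of lung CT slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity-mixture and encoder-decoder segmentation of lung CT slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(ctmixseg)
```

## The model

`ctmixseg` segments grayscale CT slices by modeling the marginal
distribution of pixel intensities as a finite mixture of a logistic-type
location-scale family. With $z = (y - \mu)/\sigma$ the component density is

$$
f(y;\mu,\sigma,p) \;=\; \frac{3}{3p + \pi^2}\,
\frac{(p + z^2)\, e^{-z}}{\sigma\,(1 + e^{-z})^2},
$$

a symmetric curve with heavier tails than the Gaussian: the kernel is the
standard logistic density reweighted by $(p + z^2)$. Because the logistic
density integrates to 1 with second moment $\pi^2/3$, the constant
$3/(3p+\pi^2)$ is the exact normalizer — this is the reading of the density
we adopt, the unique one under which that constant is correct (the
*two-parameter* family fixes the shape at $p = 4$, where the constant
specializes to $3/(12+\pi^2)$). Two consequences matter in practice:

* the family's standardized variance is $(p\pi^2 + 7\pi^4/5)/(3p+\pi^2)
  \approx 8.04$ at $p=4$, so a component's standard deviation is about
  $2.84\,\sigma$ — the scale parameter is *not* the SD. Separations quoted
  "in sigmas" are therefore much smaller in SD units; a pair of components
  $6\sigma$ apart is only $\approx 2.1$ SDs apart and produces a *unimodal*
  pooled density.
* there is no closed-form CDF; `pltype`/`qltype`/`rltype` use trapezoidal
  integration on a 4,099-point grid over $\mu \pm 40\sigma$ (denser on the
  central $\pm 8\sigma$), with linear interpolation. The tail mass beyond
  the grid is below $10^{-14}$, and the induced quantile error is orders of
  magnitude below Monte-Carlo noise at any sample size used here.

A $K$-component mixture $\sum_i \alpha_i f(y;\mu_i,\sigma_i,p)$ is fitted
by EM (`ltmix()`). The E-step computes posterior responsibilities in log
space, so well-separated components never underflow. The M-step updates
weights as mean responsibilities and each $(\mu_i, \sigma_i)$ by
numerically maximizing the responsibility-weighted log-likelihood (BFGS in
$(\mu, \log\sigma)$ with the analytic score). We prefer the numerical
M-step because the family's location score has no closed-form root; a
fixed-point rearrangement of the scale score equation,

$$
\sigma^2_{\text{new}} =
\frac{\sum_s r_s (y_s-\mu)\,\sigma\,(2\Lambda(z_s)-1)}
     {\sum_s r_s \left(1 + \dfrac{2(y_s-\mu)^2}{p\sigma^2 + (y_s-\mu)^2}\right)},
\qquad \Lambda = \text{logistic CDF},
$$

is available as `ltmix_control(scale_update = "fixed_point")` (with a
responsibility-weighted mean for $\mu$). Either way each step is guarded:
the optimizer starts at the current parameters and falls back to them if no
improvement is found, so the observed-data log-likelihood is monotone — a
property the tests verify on every seeded run.

Defaults follow the model's stated estimation error: convergence when the
largest absolute parameter change drops below $10^{-3}$, at most 500
iterations. Initialization is equal weights $1/K$, locations at the
$(i-\tfrac12)/K$ sample quantiles (or seeded k-means centers), and scales
from the within-group SD *converted to scale units* (divided by
$\sqrt{8.04}$). The conversion matters: seeding scales with raw SDs starts
EM in a basin where both components go broad and the fit stalls at a
visibly worse likelihood. Scales are floored at $10^{-3}$ and a component
whose mean responsibility falls below $10^{-8}$ raises a collapse error
rather than producing a singular fit.

The segment count, when not fixed, is estimated from the smoothed intensity
histogram (`estimate_k()`): modes of a `stats::density()` estimate whose
topographic prominence exceeds 5% of the tallest peak. This counts genuinely
separated intensity populations and deliberately ignores shoulder bumps;
because of the SD/scale distinction above it will — correctly — report one
segment for mixtures whose components overlap heavily, so pipelines that
know their class count should set it explicitly.

Segmentation is max-posterior labeling (`classify_pixels()`), ties broken
toward the lower component index; labels are 0-based, matching the mask
convention (background = 0) used throughout.

## Preprocessing

The CT preparation chain (`preprocess_pipeline()`) applies, in configurable
order: Hounsfield display windowing (presets: lung = center $-600$, width
$1500$ HU; soft tissue = center $50$, width $400$ HU), CLAHE, adaptive
Wiener denoising, bilinear resizing, and min-max normalization. The default
order is window → CLAHE → Wiener → resize → normalize.

CLAHE follows the textbook algorithm: per-tile histograms over 256 bins,
clipped at `clip_limit` (default 1%) of the tile pixel count, the excess
redistributed uniformly over all bins (one pass; bins may end at
clip + excess/nbins, the documented residual), and per-pixel bilinear
blending of the four surrounding tile-center mappings. With one tile and an
unbounded clip the procedure reduces exactly to global histogram
equalization, which the tests exploit as an independent oracle. The Wiener
filter is the local adaptive form
$\hat x = m + \frac{\max(0, v-\nu)}{\max(v,\nu)}(x-m)$ over an odd window
(default $3\times3$) with reflective borders and, by default, the noise
variance estimated as the mean local variance. Tile grid, bins, clip,
window, and noise are all config-exposed since the source material specifies
none of them.

Rotation augmentation produces eight copies at 45° steps; axis-aligned
angles are exact grid permutations, oblique angles use inverse mapping with
reflective padding — bilinear for images, nearest-neighbor for masks, so
label sets survive.

## The network

The segmentation network is a small U-Net-style encoder-decoder
(`unet_spec()`, `build_unet()`): per encoder level two $3\times3$
convolutions (stride 1, pad 1, ReLU) then $2\times2$ max-pooling; filter
counts double from 8 per level (8-16-32-64-128 at depth 5 — anchored by the
one stated count, eight first-layer filters); dropout 0.5 at the
bottleneck; a decoder of $2\times2$ stride-2 transposed convolutions (with
ReLU), skip concatenation and two convolutions per level; a $3\times3$
head with sigmoid (binary) or channel softmax. The decoder mirrors the
encoder back to the input resolution so predictions are scoreable against
full-size masks. `skip_mode = "nested"` instead builds the dense
nested-skip lattice in which node $X^{l,j}$ concatenates all previous
same-resolution nodes with the upsampled deeper node. L2 weight decay
(default $10^{-3}$) applies to all convolution weights.

No deep-learning framework is involved: the package implements the forward
pass, reverse-mode gradients and Adam directly over `(N, H, W, C)` arrays,
with convolutions expressed as nine shifted matrix products. The tests
check every layer's gradient against central differences (agreement to
$\sim 10^{-10}$), which is the strongest correctness statement a desk-scale
implementation can make.

Training (`train_unet()`) minimizes the soft Dice loss
$1 - (2\sum pt + \varepsilon)/(\sum p + \sum t + \varepsilon)$ with
$\varepsilon = 1$ (the standard smoothing that makes empty pairs
well-defined), Adam at learning rate $10^{-3}$, batch size 32, 100 epochs
by default, with seeded shuffling and dropout so runs are bit-reproducible.
`split_dataset()` partitions samples 70/15/15 after a seeded shuffle; the
best-validation-Dice epoch is checkpointed.

## Evaluation

`evaluate_masks()` computes overlap metrics (Dice, IoU, and the
confusion-matrix family — accuracy, sensitivity, specificity, precision,
F1), and the partition-comparison metrics under their canonical
definitions: the Rand-index form of the probabilistic Rand index (a single
ground truth), Meilă's variation of information in bits, and Martin's
global consistency error. Conventions: both-empty masks score Dice/IoU 1;
$0/0$ confusion ratios are reported as `NA` rather than raised; ROC/AUC
sweeps unique score values with ties moving together and integrates by
trapezoid. An optional ROI mask restricts all metrics to a region, which is
how region-of-interest evaluation is exposed. Aggregation reports per-metric
mean ± population SD, the presentation used by segmentation benchmarks.
Every partition metric is tested for exact agreement with brute-force
pairwise/pixel-wise oracles on all partition pairs of sets up to size 6.

Because mixture labels are arbitrary up to permutation,
`relabel_to_truth()` aligns a segmentation with a reference by exhaustive
permutation search (up to 8 labels; greedy majority matching beyond), and
the EM pipeline applies it before scoring.

## Synthetic phantoms

`generate_lung_phantom()` builds seeded slices: two jittered ellipse lung
fields on a body background, 1-3 disc nodules placed fully inside the lung
fields by rejection (radius 4-10 px at $128\times128$), per-class
intensities drawn from logistic-type distributions, additive Gaussian
sensor noise (SD 2), clamped to 0-255. The default class locations put the
lung interior at 60.54 and surrounding tissue at 121.98 with scales
$\sqrt{94.2568}$ and $\sqrt{128.784}$ — the two-component regime the
mixture model is designed around — and nodules brighter at 185. The
generator exercises the statistical structure the model assumes (distinct
per-region intensity distributions, noise, simple anatomy-like geometry);
it does not attempt anatomical realism, 3-D continuity, scanner artifacts,
or the morphological diversity of real nodules, so green tests here say the
*method* works where its assumptions hold, not that it meets clinical
performance on real CT.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in minutes on one CPU: EM property checks at
$n = 5{,}000$-$10{,}000$ pixels; pipeline checks on ten $64\times64$
two-class phantoms; the network overfit check on eight $32\times32$
phantoms at depth 3 for 200 epochs (about two minutes). The overfit
criterion is read as the best epoch within the first 200, since eval-mode
Dice oscillates within half a point of its plateau once converged.
Quadrature tolerances ($10^{-6}$ for density normalization, $10^{-12}$ for
the two-/three-parameter family identity) reflect the accuracy of
`integrate()` and exact algebraic identity respectively.

## Known limitations

* The mixture model ignores spatial structure entirely (no smoothing or
  Markov-random-field prior); segmentations can be speckled at class
  boundaries, which the evaluation metrics duly punish.
* Model selection is histogram mode counting only; no information-criterion
  sweep.
* The network trains at phantom scale on CPU; nothing here speaks to
  full-dataset GPU training, and the published benchmark numbers for real
  lung-CT collections are out of scope by design.
* `estimate_k()` is calibrated for clearly separated intensity populations;
  heavily overlapping components are reported as one segment.
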