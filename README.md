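# ctmixseg

Intensity-based segmentation of lung-CT slices in R: a finite mixture of
logistic-type location–scale distributions fitted by EM, a CT preparation
chain (Hounsfield windowing, CLAHE, adaptive Wiener denoising), a small
U-Net-style encoder–decoder trained with Dice loss, partition-comparison
evaluation metrics, and a seeded phantom generator so the whole toolchain
runs and is testable without any imaging data.

## Who this is for

Researchers prototyping intensity-model-based segmentation of grayscale
medical images, and anyone who needs honest, oracle-tested implementations
of the surrounding machinery: CLAHE with an explicit clip contract, the
local adaptive Wiener filter, Dice/IoU, the probabilistic Rand index (PRI),
variation of information (VOI), Martin's global consistency error (GCE),
and ROC/AUC.

## The model

Pixel intensities $y$ in each image region are modeled by the logistic-type
density, with $z = (y-\mu)/\sigma$:

$$f(y;\mu,\sigma,p) = \frac{3}{3p+\pi^2}\,\frac{(p+z^2)\,e^{-z}}{\sigma(1+e^{-z})^2},$$

the "two-parameter" family fixing $p = 4$. An image is a $K$-component
mixture $\sum_i \alpha_i f(y;\mu_i,\sigma_i,p)$; `ltmix()` fits it by EM
(log-space responsibilities, numerically maximized M-step with a monotone
ascent guard) and `predict()` labels each pixel by maximum posterior.
The network path trains a small encoder–decoder (8 first-layer 3×3
filters, doubling per level, dropout-0.5 bottleneck, L2 10⁻³, Adam at
10⁻³, Dice loss, 70/15/15 split) with backpropagation implemented in the
package and verified against numerical gradients.

## Worked example

Fit the mixture to a two-class phantom and score the segmentation:

```r
library(ctmixseg)

ph  <- generate_lung_phantom(
  phantom_spec(size = c(64, 64), n_nodules = c(0, 0)), seed = 42)
img <- wiener_filter(ph$image, window = 3)   # denoise, as the pipeline does
fit <- ltmix(img, K = 2)
fit
#> Logistic-type mixture fit (EM)
#>   n = 4096 pixels, K = 2, shape = 4
#>   log-likelihood -18932.732 after 11 iteration(s); converged
#> Logistic-type mixture parameters (K = 2, shape = 4)
#>            comp1    comp2
#> weight    0.3619   0.6381
#> location 73.8955 125.5698
#> scale     6.6282   4.4672

seg <- relabel_to_truth(predict(fit, type = "class"), ph$mask)
round(evaluate_masks(seg, ph$mask,
                     metrics = c("dice", "iou", "pri", "voi", "gce")), 4)
#>   dice    iou    pri    voi    gce
#> 0.9166 0.8460 0.9001 0.5067 0.0903
```

The two components separate the dark lung fields from the brighter tissue
(the generating locations are 60.5 and 122; the fitted lung component is
pulled upward by boundary pixels that the denoiser blends), and the
max-posterior labeling recovers the lung field with Dice ≈ 0.92. VOI is in
bits (0 = identical partitions) and GCE is in [0, 1] (0 = one partition
refines the other).

The same flow is available as a configured pipeline (`run_em_pipeline()`,
`run_train()`/`run_eval()`) driven by a YAML file — see
`inst/examples/em-run.yaml` — and as a command-line tool:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","ctmixseg",package="ctmixseg"))')" \
  segment-em --config inst/examples/em-run.yaml --out results/
```

## Layout

- `R/ltd-distribution.R`, `R/ltmix.R` — the distribution family and the EM
  mixture model (`ltmix()` and its methods)
- `R/preprocess.R` — windowing, CLAHE, Wiener, resize, rotations
- `R/unet.R` — network spec, graph builder, backprop, Adam, training
- `R/metrics.R` — Dice/IoU, confusion statistics, PRI/VOI/GCE, ROC/AUC
- `R/synthetic.R` — phantom generator
- `R/pipeline.R` — image/config I/O and end-to-end runs
- `vignettes/ct-segmentation-methods.Rmd` — the methods notes: model,
  assumptions, parameter choices, limitations
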