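# gradflow

Structural and neuromodulatory shaping of dynamic functional-connectivity
gradients.

## What this package is for

Resting-state functional connectivity (FC) can be compressed into a few
*gradients* — smooth spatial axes obtained by diffusion-map embedding of the
FC matrix — whose leading pair typically separates sensorimotor from visual
cortex and unimodal from multimodal cortex. `gradflow` is a research
pipeline for asking, on region-parcellated BOLD data paired with a directed
tracing connectome and a receptor gene-expression atlas:

- how strongly structural-connectivity similarity (**SC**) and
  neuromodulatory expression similarity (**NS**) explain FC, via the
  pairwise model `FC = b0 + b1·SC + b2·NS` with leave-one-scan-out
  cross-validation, single-variable upper bounds, and shuffle-based
  reduced-model lower bounds (`ΔR²`);
- how the gradients reorganize with arousal: a pupil-based behavioral
  arousal index, an fMRI template-projection index, frame-resolved dynamic
  connectivity by a two-stage GARCH/DCC estimator, equal-count arousal
  binning, per-bin gradients aligned by orthogonal Procrustes, gradient
  flow in gradient space with a scan-shuffled null, FC entropy, and
  second-order (U / inverted-U) trend fits;
- which individual receptors carry the neuromodulatory effect, using
  variogram-matched spatial-autocorrelation-preserving surrogate maps,
  right-tailed surrogate tests, and Benjamini–Hochberg FDR control.

A first-class synthetic-cohort generator (`make_cohort()`) produces every
input the pipeline consumes — scans, pupil traces, a directed log-normal
tracing matrix, a receptor-by-region expression matrix, region coordinates —
with planted gradients, a latent arousal process, U-shaped neuromodulatory
modulation, and labelled null receptors, so each stage is testable against
known ground truth. See the methods vignette
(`vignettes/gradient-dynamics.Rmd`) for the model and every numerical
choice.

## Worked example

```r
library(gradflow)

# a synthetic study: 4 scans of 512 frames (TR 2 s), 116 regions,
# 55 tracing targets, 12 receptors of which 4 are nulls
ch <- make_cohort(n_scans = 4, seed = 1)

# static gradients of the mean FC
fc  <- Reduce(`+`, lapply(ch$scans, compute_fc)) / 4
g   <- connectivity_gradients(fc, n_components = 4)
round(100 * g$explained_variance, 1)
#> [1] 29.2 25.4 16.3  6.3

# recovery of the planted maps (sign/rotation resolved by Procrustes)
al <- procrustes_align(g$components[, 1:2], ch$truth$gradient_maps)
round(abs(diag(cor(al, ch$truth$gradient_maps))), 3)
#> [1] 0.997 0.997

# arousal: pupil -> template -> frame-wise index
beh  <- lapply(ch$pupil, behavioral_index, fps = ch$fps, tr = ch$tr)
tmpl <- arousal_template(ch$scans, beh, tr = ch$tr)
idx  <- fmri_arousal_index(ch$scans[[1]], tmpl)
round(cor(idx$index, ch$arousal[[1]]), 2)
#> [1] 0.74

# variance partition over region pairs
sc <- tracing_similarity(ch$tracing)
ns <- expression_similarity(ch$expression)
vp <- partition_variance(lapply(ch$scans, function(s)
        vectorize_pairs(compute_fc(s))), list(SC = sc, NS = ns),
        n_shuffles = 200, seed = 2)
round(c(full = vp$full$mean, dSC = vp$delta$SC$delta_r2,
        dNS = vp$delta$NS$delta_r2), 3)
#>  full   dSC   dNS
#> 0.701 0.271 0.349
```

The first two gradients dominate the spectrum and match the planted maps at
|r| ≈ 0.997; the frame-wise arousal index tracks the latent arousal
process (r = 0.74 against the raw latent state, ~0.9 against its
HRF-convolved expression); and the partition attributes substantial unique
explained variance to both predictors on top of their shared part, as
planted. The whole
pipeline runs from one configuration with `run_pipeline()` (YAML or list;
a shell wrapper ships in `inst/scripts/run_pipeline.R`).

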