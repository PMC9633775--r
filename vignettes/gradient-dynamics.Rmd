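---
title: "Methods: arousal-dependent connectivity gradients and their structural and neuromodulatory drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arousal-dependent connectivity gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradflow)
```

# The scientific problem

Resting-state functional connectivity (FC) between cortical regions can be
summarized by a small number of *gradients*: smooth spatial axes along which
connectivity profiles vary, obtained by nonlinear embedding of the FC
matrix. Two questions motivate this package. First, how strongly are these
gradients shaped by anatomical wiring, as measured by retrograde-tracing
connectomes, and by the spatial organization of neuromodulatory receptor
expression? Second, how do the gradients reorganize from moment to moment as
arousal fluctuates between drowsy and alert states?

`gradflow` implements the full analysis chain: diffusion-map gradient
estimation, behavioral (pupil) and fMRI-template arousal indices, dynamic
conditional correlation (DCC) connectivity, arousal-binned dynamic
gradients, a pairwise regression model with shuffle-based variance
partitioning, and spatial-autocorrelation-preserving surrogate inference —
plus a synthetic-cohort generator with planted ground truth so that every
stage can be validated end to end without any imaging data.

# Gradient estimation

For one scan, FC is the Pearson correlation matrix of the region time
series. Following standard practice in the gradient literature, each row is
thresholded to its top 10% connections (`threshold_rows()`, count
`ceiling(density * (N - 1))`, ties to the lower column index), converted to
a normalized-angle affinity `A = 1 - acos(cosine)/pi` between thresholded
row profiles (`normalized_angle()`; the thresholded matrix is asymmetric,
the cosine-of-rows affinity is symmetric by construction), and embedded
with diffusion maps (`diffusion_embed()`).

The embedding uses the anisotropic normalization `W = D^-a A D^-a` with
`a = 0.5` and the multi-scale scaling `lambda/(1 - lambda)` (diffusion time
0), the community defaults. Explained variance of component *k* is defined
as `lambda_k^2 / sum(lambda^2)` over the non-trivial spectrum; components
are ordered by explained variance, which differs from ordering by eigenvalue
only when the affinity is indefinite (negative eigenvalues are possible and
are handled). Gradient sets are compared after orthogonal Procrustes
alignment without scaling (`procrustes_align()`), which preserves the
explained-variance interpretation across arousal bins; sign and rotation
indeterminacy of the embedding makes some alignment step mandatory for any
cross-scan or cross-bin comparison.

Two open choices are documented here. Whether the top-10% threshold is
applied per row or over the whole matrix is ambiguous in the literature we
follow; row-wise is implemented (each region keeps its strongest profile).
And the explained-variance normalization is one consistent choice among
several in use; it is configurable in spirit — the eigenvalues are returned,
so any other normalization can be computed.

# Arousal indices

The behavioral index (`behavioral_index()`) takes the median of valid pupil
samples within each TR bin and divides by the per-scan maximum, so 1 means
"eye fully open" and the index is invariant to camera gain. Blinks shorter
than half a bin cannot move the median; bins with no valid sample are
linearly interpolated and flagged. The eye-open ratio is the fraction of
frames with at least half their samples valid.

The fMRI-based index projects an *arousal spatial template* onto successive
frames (`fmri_arousal_index()`): the template is the per-region correlation
between BOLD and the HRF-convolved behavioral index, Fisher-z averaged
across scans (`arousal_template()`). The HRF is the canonical double-gamma
(response peak 6 s, undershoot 16 s, ratio 1/6), sampled at TR; a
species-specific kernel can be substituted by convolving externally. Frames
are correlated against the template as-is (the BOLD input is assumed
variance-normalized upstream); no per-frame z-scoring is applied.

`bin_by_arousal()` ranks frames by the index and cuts them into equal-count
bins (equal degrees of freedom per bin), dropping remainder frames from the
two extremes of the ranking and breaking ties by frame order.

# Dynamic connectivity

Frame-resolved connectivity uses the two-stage DCC estimator (`dcc_fit()`):
GARCH(1,1) per region by Gaussian quasi-maximum likelihood, then a scalar
DCC(1,1) recursion on the standardized residuals with the unconditional
correlation as targeting intercept. Stage two maximizes the *composite*
pairwise bivariate likelihood rather than the joint N-dimensional one: for
region counts in the dozens the joint likelihood is biased towards a static
model (the innovation outer products that drive the recursion are rank-one
and extremely noisy in high dimension), while the composite estimator
remains consistent and is what pairwise DCC toolboxes effectively compute.
The per-frame correlation matrices are then produced by the joint recursion
at the estimated parameters, which guarantees a valid correlation matrix at
every frame. The optimizer is bounded quasi-Newton (L-BFGS-B) from three
deterministic starting points spanning slow and fast dynamics, with
boundary clamping at `a + b = 1 - 1e-4` under a warning; deterministic
starts replace randomized restarts so that fits are exactly reproducible
without an extra seed.

Per-bin mean DCC matrices are re-embedded and aligned to the static
reference, giving explained-variance curves and gradient values per arousal
bin. `gradient_flow()` tracks each network's centroid in the (gradient 1,
gradient 2) plane across bins and summarizes its drift by the least-squares
linear displacement per bin step — more robust to single-bin noise than the
endpoint difference. `flow_null()` builds the null by reassigning the
per-scan arousal traces across scans and recomputing everything, with
`p = (1 + #{null >= obs}) / (1 + n_perm)`. `fc_entropy()` is the Shannon
entropy (bits) of the upper-triangle FC histogram over 64 fixed bins
spanning [-1, 1]. `quadratic_trend()` fits `y = c2 x^2 + c1 x + c0` and
labels the shape inverted-U (or U) only when the 95% CI of `c2` excludes
zero.

# The pairwise model and variance partitioning

Over region pairs, `FC = b0 + b1 * SC + b2 * NS`, where SC is the Pearson
similarity of log-transformed tracing target profiles
(`tracing_similarity()`, `log(w + 1)` for zero handling, rows = sources
because gradients live on the source parcellation) and NS the Pearson
similarity of receptor expression profiles between regions
(`expression_similarity()`). The least-squares constraint on the
coefficient norm is implemented as a small ridge penalty on the slopes
(intercept unpenalized), scaled by the mean squared predictor magnitude
and negligible by default, so OLS is recovered on well-conditioned data
while exact collinearity is still handled gracefully.

Model quality is the leave-one-scan-out cross-validated explained variance
(`loo_cv()`): fit on the mean FC of the remaining scans, score
`1 - SSE/SST` on the held-out scan (the squared Pearson correlation is
reported alongside, as the two definitions differ under miscalibration).
A predictor's contribution is bracketed by the single-variable model
(`single_variable()`, upper bound — shared variance counts) and the
reduced model (`reduced_delta()`, lower bound): the predictor is randomly
shuffled — by default a joint row/column permutation of its similarity
matrix, which preserves the model's degrees of freedom and keeps the
shuffled predictor a valid similarity matrix — the model refitted, and
`deltaR2 = cvR2_full - mean(shuffled cvR2)`. Frame-wise fits
(`framewise_glm()`) share the design across frames, so the per-frame
coefficients are obtained in one linear solve; zero-variance frames are
flagged and given zero slopes.

# Surrogate inference

Cortical maps are spatially autocorrelated, so naive parametric tests of
map-to-map correlations are anti-conservative — one of the acceptance
properties demonstrates this directly. `make_surrogates()` builds
variogram-matched surrogates: permute the map, smooth the permutation by
distance-kernel averaging over k nearest neighbors for
k in {3, 5, 8, 13, 21, 34, 55, 89}, fit the smooth and nugget components to
the target variogram by weighted (relative-error) least squares, rescale,
and keep the k with the smallest realized maximal relative error. The
variogram (`variogram()`) uses equal-count distance-lag bins defined by the
distance matrix alone, so target and surrogate variograms share lags.
Distances come from the region coordinates (Euclidean by default); any
distance matrix, e.g. geodesic, can be supplied.

One calibration point deserves emphasis: at a few hundred regions the
variogram of a *single* realization of a smooth field fluctuates strongly
around its expectation — fresh draws from the exact generating law miss one
realized target variogram by ~40% at some lag, median across draws. The
ensemble-mean surrogate variogram is therefore the meaningful match
criterion (it stays within 15% of the target at every lag under the default
conditions), while individual surrogates scatter around it exactly as
same-law draws would.

## Receptor screening

For the per-receptor analysis (`receptor_contribution()`,
`receptor_screen()`), two quantities are computed from each receptor's
surrogate ensemble. *Significance per gradient* is the right-tailed
SA-corrected p-value of the receptor map's absolute spatial correlation with
the reference gradient — a statistic linear in the map, the class for which
variogram-matched ensembles are well calibrated (the calibration is itself
tested). *Contribution magnitude* per gradient is the reduced-model score:
each surrogate replaces the receptor in the expression matrix, the
neuromodulatory similarity is rebuilt, the per-bin model refitted, and the
reconstruction of binned dynamic connectivity along the gradient axis
scored; the unique contribution is the observed score minus the surrogate
mean. Two pitfalls dictated this division of labor, and both are general
cautions for surrogate-based model comparison. First, quadratic fit
statistics compared against a variogram-matched ensemble inherit a
*family bias*: all surrogates share the permute-and-smooth construction, so
an observed map is systematically (and cohort-dependently) inside or
outside the ensemble for any statistic that is nonlinear in the map —
including for truly null receptors. Second, the explained variance of
re-embedded model predictions is insensitive to corruption of one
predictor: the refitted model falls back on the remaining predictor, whose
gradient structure is intact. Groups follow the per-gradient FDR
(Benjamini-Hochberg across receptors): gradient 1 only, gradient 2 only,
both, or neither.

# The synthetic cohort generator

`make_cohort()` generates everything the pipeline consumes, with planted
ground truth. Defaults mirror the study conditions the pipeline targets:
116 cortical regions with 55 tracing targets, scans of 512 frames at
TR = 2 s, pupil video at 6 fps, ten arousal bins.

The generative model, in order:

1. **Latent fields and coordinates.** Region coordinates are uniform in the
   unit square; smooth latent fields are Gaussian random fields with
   exponential covariance (`make_spatial_maps()`, correlation length 0.25 —
   a quarter of the cortex-analog, giving a handful of large-scale lobes).
2. **Tracing matrix.** Each target's log connection profile is a smooth
   Gaussian-process field over the *latent field space* plus physical
   distance decay and log-normal scatter (`make_tracing()`). Profile
   correlations between regions then decay with their distance in field
   space, which is what makes the derived structural similarity carry the
   planted axes through the rank-based threshold and angle transform; a
   low-rank bilinear term, the more obvious construction, survives those
   nonlinear steps only as an angle in map space and caps recovery around
   |r| = 0.8.
3. **Receptors.** Loadings cycle through a balanced block of eight
   patterns: plus and minus each gradient and the four diagonal directions.
   Balance (loadings sum to zero) matters because the Pearson similarity
   across receptors centers each region's profile, and an unbalanced
   loading set rotates the effective axes; isotropy (the loading kernel
   proportional to the identity) matters because an anisotropic receptor
   kernel tilts the population gradients away from the loading frame. Null
   receptors are smooth, map-independent fields (correlation length 0.1) —
   spatial autocorrelation is a property of real expression maps, and the
   surrogate test presumes it. The *generative* neuromodulatory similarity
   uses the loaded receptors only; nulls are observation-side negatives.
4. **Arousal and covariance.** A latent AR(1) process (persistence 0.95 per
   2-s frame, so state episodes last on the order of a minute) squashed to
   [0, 1] drives the frame covariance: the correlation mixture
   `b0*I + b1*SC + w(a)*NS`, normalized to unit diagonal, with
   `w(a) = b2 * 4 * (a - 1/2)^2` — the neuromodulatory weight is U-shaped,
   largest at the drowsy and alert extremes. Defaults
   `b0 = 0.3, b1 = 0.55, b2 = 0.8` put the structural kernel in charge of
   the static gradients while the modulation reaches comparable strength at
   the extremes. Arousal is quantized to 21 levels so each scan needs at
   most 21 Cholesky factors; a nearest-correlation projection
   (`Matrix::nearPD`) guards validity, though the convex mixture is already
   a correlation matrix. A global-amplitude term — the HRF-convolved,
   mean-centred arousal scaling a fixed template map — makes the fMRI
   arousal index recoverable, and independent observation noise
   (sd 0.2) is added.
5. **Planted maps as population gradients.** The planted gradient maps are
   defined as the leading diffusion gradients of the *population*
   correlation matrix — the arousal-averaged mixture plus the amplitude
   and noise terms, with the arousal distribution calibrated once by a
   long seeded simulation — rotated within their span to the frame the
   receptor loadings were expressed in (a Procrustes-matched fixed point,
   four iterations). Planted maps are therefore exactly what the pipeline
   estimates in the infinite-data limit: finite-sample recovery measures
   estimation error, not model mismatch. A 5000-frame scan recovers them
   at |r| about 0.995.

What the generator does *not* emulate: hemodynamic spatial spread, head
motion, scanner drift, non-Gaussian BOLD noise, heavy-tailed volatility,
and any mismatch between the tracing/expression parcellation and the
functional one. Passing tests therefore demonstrate that the pipeline's
inferences are correct *under its own statistical assumptions*, not that
those assumptions hold in any particular dataset.

# Numerical choices and problem sizes

Determinism: every stochastic function takes a `seed` and restores the
caller's RNG state; `run_pipeline()` fans one global seed out to per-stage
seeds by a documented hash. Degenerate inputs fail loudly: constant time
series name the offending region, all-zero connectivity profiles raise an
isolated-node error, disconnected affinity graphs are rejected, constant
maps cannot be surrogate-shuffled. Permutation-style p-values use the +1
convention and never return zero.

The validation suite runs at deliberately reduced problem sizes chosen to
keep the full run in the tens of minutes while leaving comfortable margins
on every statistical claim: gradient recovery at 100 regions and 5000
frames; DCC parameter recovery at T = 4000 over 20 replicates; the
opposing-modulation property on 100 cohorts of 30 regions and 900 frames;
the receptor screen on 50 cohorts with 200 surrogates each; surrogate
calibration over 500 replicates. The same code paths scale to
parcellations of a few hundred regions; voxel-level (tens of thousands of
nodes) gradient estimation is out of scope.

# Known limitations

- The DCC tracking of slow exogenous correlation modulation is heavily
  attenuated (the composite estimator recovers the sign and ordering of
  arousal-binned effects, but bin-to-bin effect sizes are an order of
  magnitude below their population values); conclusions should rest on
  trends across bins, not on raw effect sizes.
- Variogram-matched surrogates are approximately, not exactly, exchangeable
  with the observed map; statistics nonlinear in the map inherit a family
  bias (see the receptor-screening section).
- The reduced-model `deltaR2` is a lower bound and the single-variable
  `cvR2` an upper bound on a predictor's unique contribution; neither is an
  unbiased point estimate, and heavily collinear predictors compress the
  interval toward zero.
- Procrustes alignment assumes the compared embeddings span comparable
  subspaces; with near-degenerate eigenvalue gaps, component identity is
  unstable even though the span is recovered.
```
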