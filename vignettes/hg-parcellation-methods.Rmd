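---
title: "Methods: connectivity-based parcellation of Heschl's gyrus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity-based parcellation of Heschl's gyrus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgparcel)
```

## The model and its assumptions

Heschl's gyrus (HG) hosts the human primary auditory cortex, and its
gyrification varies so much across individuals that group-atlas
subdivisions transfer poorly. The pipeline implemented here subdivides
HG *per subject* from structural connectivity: each seed unit (voxel or
vertex) carries a 42-element fingerprint of streamline counts to the
remaining intrahemispheric Desikan–Killiany regions, K-means clusters
the fingerprints, and an inertia elbow selects the number of
subregions. The assumptions this rests on are:

* connection *patterns* (not absolute streamline yield) distinguish
  auditory subfields — hence the default row-proportion normalization
  before clustering;
* subregions are few and their fingerprints form compact clusters in
  Euclidean space — hence K-means and the elbow criterion;
* a stable medial→lateral anatomical axis exists along which clusters
  can be named consistently across subjects (HG2 medial, HG1 central,
  HG3 lateral).

Downstream, the subregions are profiled (structural connectivity,
soft-thresholded functional connectivity, myelin proxy, thickness),
contrasted across subjects with paired t-tests under per-family
Benjamini–Hochberg FDR control, and a functional gradient is estimated
within HG from a cosine-similarity affinity of connectivity
fingerprints, PCA, and Procrustes alignment to a group reference.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| seed units | 300 | count | desk-scale stand-in for the ~10² – 10³ HG voxels of high-resolution diffusion imaging |
| band proportions HG1/HG2/HG3 | 0.46/0.24/0.30 | fraction | HG1 is the largest subregion (≈46% of HG); HG2 the smallest; the exact HG2/HG3 split is a convention, configurable |
| streamlines per unit | 10,000 | count | tractography seeding density the fingerprints emulate |
| targets | 42 | count | intrahemispheric Desikan–Killiany regions excluding the seed |
| timepoints | 1400 | TR | length of a high-quality resting-state run |
| dilation radius | 2.1 | mm | boundary-ambiguity dilation toward STG and insula; "direction" is realized as a label constraint because no direction vector is defined on unit tables |
| K range | 2–10 | — | the sweep over candidate cluster counts |
| K-means restarts | 10 | — | stabilizes the inertia curve the elbow depends on; k-means++ init, Lloyd iterations |
| Kneedle sensitivity S | 1 | — | no smoothing: nine-point profiles are short and (post-restart) monotone |
| soft-threshold β | 6 | — | scale-free index of ((r+1)/2)^β |
| FDR q | 0.05 | — | per-family BH control |
| gradients retained | 3 | — | the first component is the quantity of interest; two spares for alignment stability |

Generator noise levels were chosen once, before any acceptance check
was run, to emulate data on which the published analysis succeeds (the
real pipeline robustly finds three clusters, so a generator whose bands
were barely separable would emulate the wrong world):

* **Dirichlet concentration 400** for fingerprint variability: gives
  within-band dispersion of the same order as the between-band profile
  differences (a few percentage points of connection proportion),
  i.e. clearly clusterable but far from noise-free;
* **time-series noise SD 0.5** against unit-variance latents (SNR ≈ 2
  per vertex), typical of region-averaged resting-state signals;
* **myelin SD 0.05** (T1w/T2w units) and **thickness SD 0.1 mm** around
  band means 1.60/1.45/1.40 and 2.9/2.6/2.5 mm — plausible cortical
  values with band differences a few multiples of the unit noise;
* **boundary jitter SD 0.02** axis units on the two band cut points:
  inter-individual variability of subregion extent of a few units out
  of 300.

## What the generator emulates — and does not

Each subject's world is: three contiguous fingerprint bands along the
axis (HG3 most strongly connected to STG, HG2 to insula/SMG/SPG, HG1
intermediate); seed time series mixing two latent networks by the axis
coordinate g as (1−g)·A + g·B, which plants a smooth functional
gradient and makes the lateral band more strongly coupled to
association/paralimbic targets; and morphometry ordered HG1-highest,
with the HG2/HG3 thickness ordering flipping between hemispheres.

It does **not** simulate streamline trajectories, fiber ODFs,
hemodynamic responses, autocorrelated BOLD noise, spatial smoothness of
noise, registration error, or subject-specific meshes. Consequently a
green recovery test establishes that the *algorithms* recover planted
structure at realistic noise — not that real HG data contain three
subregions. One visible consequence: the first gradient explains ≈87%
of affinity variance here versus ≈48% reported on real data, because
two latent signals generate the synthetic connectivity space.

## Numerical choices

* **K-means degenerate inputs.** When a fingerprint matrix has fewer
  distinct rows than K (the noise-free limit), Lloyd's algorithm
  necessarily leaves clusters empty. Any split of a duplicate group
  across co-located centers attains the optimal inertia, so that
  solution is constructed directly; genuinely pathological inputs still
  error after the restart budget.
* **Kneedle.** Min–max normalize, difference curve d = (1−ŷ) − x̂,
  first interior local maximum of d above S·mean(Δx̂). An exactly
  linear profile errors ("no elbow") rather than silently defaulting.
  Near-linear convex profiles whose maximum d falls below the
  threshold also error — that is the intended reading of sensitivity,
  and the brute-force chord-distance oracle is therefore only asserted
  to agree on profiles with a genuine elbow.
* **Monotonicity repair.** An inertia inversion at some K is re-run
  with doubled restarts; a persisting inversion is kept and warned
  about, never silently edited.
* **Canonical labels.** k = 3: smallest axis centroid → HG2, largest →
  HG3, remainder → HG1; exact centroid ties broken by size (larger →
  HG1, mirroring HG1 being the largest subregion). Other k: ordinal
  names HG_a1…HG_ak by axis centroid.
* **Soft threshold before averaging.** ((r+1)/2)^β is applied to each
  seed–target correlation, then averaged within subregion; the
  transform is convex, so the order matters and is fixed accordingly.
* **Paired t-test degenerate case.** Identical inputs return t = 0,
  p = 1 (a well-defined null outcome); zero-variance differences with a
  nonzero mean error instead of returning ±∞.
* **Z-normalization** uses the population-SD convention (divide by
  √mean squared deviation); zero-variance rows are excluded with a
  warning.
* **SVD reduction** returns singular-value-weighted component time
  courses S·Vᵀ. With z-normalized rows the components are mean-zero,
  and keeping the singular-value weighting in the fingerprint step
  preserves the seed-to-outside inner-product geometry exactly — the
  full-rank SVD path then equals the direct voxel-space affinity to
  1e−6, which is tested as an oracle equivalence.
* **Gradient PCA** column-centers the affinity matrix; the eigen-sign
  is fixed at stratification time by requiring the HG3 mean to exceed
  the HG2 mean (the axis expands from HG2 to HG3).
* **Procrustes** is orthogonal (rotation + reflection) *without*
  scaling, so gradient magnitudes remain comparable across subregions.
* **Determinism.** Every stochastic function takes an explicit seed;
  cohort and stage seeds are spawned from one master seed and restored
  after use, so identical configurations are bitwise-reproducible.

## Design decisions where the method description was open

* **Features for clustering:** row-proportion fingerprints by default
  (raw counts reproduce the literal streamline-count reading and remain
  available via `normalization = "raw"`); raw counts would let
  per-unit streamline yield dominate the distance.
* **Group vs per-subject K:** one K for the whole cohort, selected by
  Kneedle on the mean of per-subject min–max-normalized inertia
  profiles; a per-subject mode (`k_selection = "subject"`, modal K) is
  provided.
* **Dilated units in clustering:** units absorbed by the dilation are
  retained for fingerprinting and clustering (the default documented
  reading); callers can subset beforehand for the seeding-only reading.
* **Multiple-comparison correction:** Benjamini–Hochberg FDR at
  q = 0.05 throughout. (The source analyses label results "p_FWE"
  while describing FDR correction; this package implements FDR and
  flags the discrepancy rather than guessing at an unreported FWE
  procedure.)
* **Shared mesh for the group reference:** stacking subject gradients
  requires equal vertex counts; the cohort generator guarantees this,
  and real-data use with differing meshes is explicitly out of scope.

## Known limitations

* No NIfTI I/O: all readers/writers use tab-separated tables (plus a
  JSON summary), because no NIfTI-capable R package is available in the
  supported environment; coordinates are in mm so voxel and vertex
  representations are handled identically.
* Only K-means is implemented; the clustering step is a single
  function boundary (`cluster_fingerprints()`) behind which other
  families could be slotted, but none are shipped.
* PCA gradients only — no diffusion-map or Laplacian-eigenmap kernels.
* The acceptance properties are recovery statements about the synthetic
  world; headline numbers from restricted-access cohorts (subregion
  size percentages, variance explained, specific t values) are not
  reproducible at desk scale and are not claimed.

## A minimal run

```{r example, eval = FALSE}
run <- run_pipeline(run_config(n_subjects = 20, rng_seed = 1))
write_report(run)
run$summary$chosen_k   # 3
run$summary$mean_ari   # ~0.97
```
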