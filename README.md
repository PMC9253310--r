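# hgparcel

Individual-level, connectivity-based parcellation of Heschl's gyrus
(HG) — the region of the human temporal lobe containing the primary
auditory cortex — plus downstream structural/functional profiling and
seed-based functional gradient mapping, implemented as a fully tested R
pipeline that runs on synthetic cohorts.

## The problem and who this is for

The folding pattern of HG varies strongly across people, so a single
group-level atlas of auditory subregions fits nobody well. A
data-driven alternative is to cluster each person's HG voxels by their
*structural connectivity fingerprints*: for every seed unit (voxel or
vertex) in HG, tractography yields a vector of streamline counts to the
42 other intrahemispheric regions of the Desikan–Killiany atlas, and
K-means on these 42-element fingerprints partitions HG into subregions.
This package is for methodologists who want a compact, deterministic,
fully testable implementation of that pipeline — clustering, model
selection, subregion statistics, and gradient mapping — without access
to restricted neuroimaging data.

## The method

For subject *s* with fingerprint matrix **F** ∈ ℝ^(n×42) (row-normalized
to proportions):

1. **Parcellation.** K-means (Lloyd, k-means++ init, best of 10
   restarts) for K = 2…10; the inertia
   I(K) = Σᵢ ‖fᵢ − c_{k(i)}‖² forms an elbow curve, and the **Kneedle**
   method (min–max normalize, difference curve d = (1−ŷ) − x̂, first
   qualifying local maximum) picks the optimal K. One K is selected for
   the whole cohort from the mean normalized inertia profile. Clusters
   are canonicalized along the medial→lateral anatomical axis: HG2 =
   medial-posterior-superior band, HG1 = central, HG3 =
   lateral-anterior-inferior band.
2. **Profiles.** Per subregion: mean structural connection proportions;
   functional connectivity as Pearson r between seed and target-ROI
   time series, soft-thresholded per pair as ((r+1)/2)^β with β = 6
   before averaging; mean myelin proxy (T1w/T2w ratio) and cortical
   thickness. Subregion pairs are compared across subjects with paired
   t-tests, Benjamini–Hochberg FDR-corrected within each measure
   family (q = 0.05).
3. **Gradients.** Seed and outside-HG time series are z-normalized; the
   outside matrix is SVD-reduced to singular-value-weighted component
   time courses S·Vᵀ (lossless at full rank); each seed vertex's
   correlation fingerprint with the components gives a cosine-similarity
   affinity matrix; PCA of the affinity yields "gradients", aligned
   across subjects by orthogonal Procrustes onto a group reference
   (PCA of the stacked subject gradients) and stratified by subregion.

A synthetic cohort generator plants all of this structure (three
contiguous fingerprint bands, a two-latent-signal mixing model that
creates a smooth medial→lateral functional gradient, subregion-ordered
morphometry) so every stage is checked by recovery tests. See
`vignettes/hg-parcellation-methods.Rmd` for assumptions and parameter
rationale.

## Worked example

```r
library(hgparcel)
cfg  <- phantom_config(rng_seed = 42)     # 300 units, 42 targets, defaults
ph   <- make_phantom(cfg)
fp   <- normalize_fingerprints(simulate_fingerprints(ph, cfg))
parc <- parcellate_subject(fp, ph$axis_coordinate, rng_seed = 42)
parc
#> hg_parcellation: k = 3; sizes: HG1=125 HG2=80 HG3=95
adjusted_rand_index(parc$labels, ph$true_labels)
#> [1] 0.9784465
```

The elbow picks K = 3 and the canonical labels recover the planted
bands almost perfectly (ARI 0.98). The full cohort pipeline:

```r
run <- run_pipeline(run_config(n_subjects = 20, rng_seed = 1))
write_report(run)
```

prints (abridged):

```
subjects: 20   chosen K: 3   mean ARI: 0.975

Structural connectivity (mean proportion, featured targets):
    superiorparietal superiortemporal supramarginal insula
HG1           0.0279           0.0658        0.0309 0.0753
HG2           0.0464           0.0219        0.0540 0.1131
HG3           0.0150           0.1327        0.0140 0.0488

Morphometry (cohort means):
    myelin thickness
HG1 1.5988    2.8968
HG2 1.4541    2.6022
HG3 1.4009    2.5012

Gradient stratification (mean g1 per subregion):
         HG1     HG2    HG3
[1,] -1.0609 -4.0895 4.7625
variance explained by g1: 87.4%  (ordering HG3>HG1>HG2 in 100% of subjects)
```

Reading this: HG3 is the most strongly STG-connected subregion and HG2
the most insula/SMG-connected (the planted structural contrast); HG1
carries the highest myelin proxy and thickness; and the first
functional gradient orders subregions HG3 > HG1 > HG2, the
medial→lateral axis. All orderings match the generative model, which is
what the acceptance suite verifies.

## CLI

`inst/cli/hgparcel.R` exposes `simulate`, `parcellate` and `run`
subcommands (see the file header for usage); all outputs are
tab-separated tables plus a JSON summary sidecar.
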