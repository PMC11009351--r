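---
title: "Habitat imaging of PET/CT tumors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat imaging of PET/CT tumors: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`habitatr` implements a habitat-imaging pipeline for non-small cell lung
cancer (NSCLC) risk stratification from co-registered CT and FDG-PET tumor
volumes. The pipeline has five stages:

1. **Harmonization** — lung windowing of CT, body-weight SUV for PET,
   isotropic resampling, local entropy maps.
2. **Habitat discovery** — two-level clustering: per-patient superpixel
   over-segmentation, then population-level clustering of pooled superpixel
   features into shared habitat subregions.
3. **Spatial quantification** — the multiregional spatial interaction (MSI)
   matrix and its 92 features per patient.
4. **Subtype discovery** — consensus clustering of MSI feature vectors into
   imaging subtypes with CDF-based selection of the cluster number.
5. **Clinical evaluation** — Kaplan–Meier/log-rank, Cox proportional
   hazards, C-index model comparison, and ctDNA crosstabs.

A synthetic phantom generator (`phantom_spec()`, `generate_phantom()`,
`generate_cohort()`) plants known habitat structure, subtype mixtures,
survival outcomes and ctDNA status, so every stage can be validated against
ground truth without clinical data.

# Harmonization

**Lung windowing.** CT Hounsfield units are mapped linearly onto [0, 1]
over the window `center ± width/2` and clipped outside. Defaults are the
standard lung window, center −400 HU and width 1500 HU; both are
configurable.

**SUV.** The body-weight standardized uptake value is
`SUV = activity / (injected_dose / body_weight)` with tissue density
assumed 1 g/mL. For channel scaling, SUV is clipped at `suv_cap = 20`
(uptake beyond SUV 20 is rare in NSCLC and would otherwise compress the
informative range) and divided by the cap.

**Resampling.** All volumes are resampled to a 1 mm isotropic grid —
trilinear for intensities, nearest-neighbour for masks and label maps. We
interpret "identical resolution" as 3-D isotropic rather than in-plane-only:
the downstream 26-neighbourhood co-occurrence counting assumes isotropic
voxels. The grid is anchored at the input origin and the physical extent is
preserved to within one voxel. Registration is deliberately *not*
implemented; inputs must already share a grid, and a hard check rejects
mismatched shapes.

**Local entropy.** For each voxel, the Shannon entropy (bits) of the
intensity histogram over a spherical neighbourhood. Defaults: radius 2
voxels (33-voxel ball) and 32 equal-width bins spanning the volume's
intensity range. Neither the kernel nor the bin count is dictated by the
method itself; radius 2 is the smallest ball that gives a stable
32-bin histogram estimate, and the resulting entropy ceiling
`log2(32) = 5` bits is used to scale the entropy channels to [0, 1]. The
filter is 3-D (not slice-wise), matching the isotropic grid. Entropy is
computed on a subvolume cropped to the tumor bounding box (padded by the
kernel radius), so the histogram range is the local one; only voxels inside
the tumor feed the downstream stages.

# Habitat discovery

**Fusion.** The four channels (windowed CT, CT entropy, scaled SUV, SUV
entropy), each in [0, 1] after fixed scaling, are summed voxelwise into a
composite in [0, 4]. The per-channel volumes — not just the composite —
are carried forward, since the superpixel features are computed per channel.

**Superpixels.** SLIC-style k-means over vectors
`(λx, λy, λz, c1, c2, c3, c4)` restricted to tumor voxels, with
`λ = compactness / (V/n)^(1/3)`. Defaults: target size 100 voxels
(`n = max(10, V/100)`), compactness 0.2. K-means clusters are split into
26-connected components; fragments under 10 voxels are merged into the
adjacent superpixel with the nearest feature centroid. The result is an
exact partition of the mask into contiguous superpixels.

**First-order features.** Ten statistics per channel per superpixel:
skewness, kurtosis (excess), mean, median, first quartile, second quartile,
interquartile range, standard deviation, variance, energy (sum of squared
intensities) — 40 features. The published statistic list includes both
"median" and "second quartile", which are the same number; we keep both
columns rather than substitute a different statistic, so the canonical
40-column layout is preserved. Skewness and kurtosis of constant
superpixels are set to 0 so feature tables stay finite.

**Population clustering.** Features are z-scored across the pooled cohort
table; a kNN graph (Euclidean) is re-weighted by shared-nearest-neighbour
Jaccard overlap computed over all pairs, pruned below 1/15, and Louvain
communities are extracted, relabelled 1..K by decreasing size.

Two defaults here deserve explanation:

* `knn = max(20, round(sqrt(n)))`. With a fixed k, the within-community
  edge density of a kNN graph falls as the pooled superpixel count grows,
  and modularity optimization then splits large homogeneous groups into
  pure but redundant pieces. Scaling k with √n keeps the graph density per
  community roughly stable; at cohort sizes of a few hundred superpixels
  this reduces to the conventional k = 20.
* `resolution = 0.4`. Resolutions at or above 1 consistently over-split
  well-separated phantom habitats (the extra communities are pure subsets
  of a single planted habitat). Since the habitat count is emergent and
  downstream MSI features are defined per habitat, we prefer the coarser
  regime; the value is configurable and K remains data-driven.

The habitat count K is whatever Louvain returns — it is not forced to 8.
The MSI feature extractor pads with zero-valued features for absent
subregions so vectors stay aligned across patients when K < 8.

# MSI quantification

The habitat map is augmented with a **border** label: every non-tumor voxel
26-adjacent to a tumor voxel. For each voxel carrying a tumor or border
label, each of its ≤ 26 labelled neighbours contributes an ordered count to
the (K+1)×(K+1) MSI matrix; border–border pairs are skipped (only
subregion–subregion and subregion–border contact is of interest). Counting
both directions makes the matrix symmetric by construction, and the entry
for an unordered pair equals the number of unordered adjacent voxel pairs.

The 92 features for K = 8 are: 4 second-order statistics (contrast,
homogeneity, correlation, energy of the normalized matrix, with the border
row/column included in the normalization); 8 absolute subregion volumes;
8 subregion–border interaction counts; 28 pairwise interaction counts
(i < j); 8 percentage volumes (summing to 100); and the 36 interactions
normalized by the total unordered interaction count, so normalized values
are per-pair fractions in [0, 1]. Degenerate marginals (single-label
tumors) set correlation to 0 with a warning. Same-label adjacencies are
counted in the matrix — they feed the second-order statistics — but are not
exported as interaction features.

Conventional PET metrics (SUVmax, SUVmean, MTV, TLG, tumor volume) use an
absolute MTV threshold of SUV ≥ 2.5 by default, with a 40%-of-SUVmax
relative option.

# Subtype discovery

Per-patient MSI vectors are scaled to [0, 1] per feature across the cohort
(otherwise count-scale features dominate the within-patient ranking), and
patient–patient distance is `1 − Spearman ρ` of the scaled profiles.
Consensus clustering subsamples 80% of patients 500 times per candidate
k ∈ 2..5, runs partition-around-medoids (PAM) on the subsampled distance
matrix, and records the fraction of co-sampled runs in which each pair
co-clusters. The number of clusters is chosen from the CDF of consensus
values: with `A(k)` the area under the CDF, the relative delta-area
`(A(k) − A(k−1))/A(k−1)` must exceed 0.10 for k to be accepted, and the
largest accepted k wins (ties and degenerate cases fall back to the
smallest candidate). Final labels come from PAM on `1 − consensus`;
the medoid patients' feature vectors are stored so a validation cohort can
be assigned by nearest-medoid Spearman distance (`assign_subtype()`,
ties to the lower cluster id). Risk names (low/intermediate/high) are
attached post hoc by ranking clusters on an outcome surrogate (by default
the percentage volume of the dense high-uptake subregion); clustering
itself is unsupervised.

# Survival evaluation

All model fitting goes through the survival package: product-limit curves
and the log-rank test (`km_logrank()`), Cox proportional hazards with Efron
tie handling and Wald intervals (`cox_fit()`; the high-risk subtype is the
reference level, so hazard ratios below 1 mean better outcome), Harrell's
C (`concordance_index()`, ties count 0.5), and nested model comparison by
C-index with a seeded 200-replicate bootstrap CI (`compare_models()`).
Missing covariates are handled by complete-case analysis with a logged
exclusion count; a covariate missing for more than 20% of patients is an
error. All tests are two-sided at α = 0.05.

# The phantom generator

The generator emulates, at desk scale, the data conditions the pipeline
targets:

* **Geometry** — an ellipsoidal tumor (default semi-axes 18 × 14 × 12 mm on
  a 64³ 1 mm grid) with habitats grown as contiguous blobs by seeded,
  batched region growth to target volume fractions.
* **Phenotypes** — 8 habitats spanning the observed CT/SUV/entropy
  combinations: habitats 1–2 low CT / low SUV, 3–4 high CT (dense tissue) /
  low SUV / low PET entropy, 5–6 low CT / high SUV / high entropy, 7–8
  high CT / high SUV / low CT entropy. Per-habitat noise SDs generate the
  entropy contrasts, since local entropy rises with local noise.
* **Subtype mixtures** — three mixtures named low/intermediate/high risk;
  the low-risk mixture is enriched for habitats 3–4, the high-risk mixture
  for habitats 7–8 with growth seeds for habitats 4, 7, 8 placed near the
  tumor border (within 2 voxels of the surface). Realized fractions are
  Dirichlet draws around the mixture (concentration 200).
* **Outcomes** — proportional-hazards Weibull event times (shape 1.2, scale
  60 months) with hazard ratios 0.38 (low vs high) and 0.52 (intermediate
  vs high); uniform censoring on (0, 80) months applied to a 30% random
  subset by default. ctDNA clearance is drawn per subtype with Persistent =
  0.67 for high risk, Never Detected = 0.62 for low risk and Cleared = 0.45
  for intermediate risk (the remaining mass split roughly 55:45 between the
  other two categories); baseline detection probabilities are 0.80 / 0.70 /
  0.40 for high / intermediate / low.

What the phantom does **not** emulate: scanner physics, partial-volume
effects, respiratory motion, registration error, non-ellipsoidal tumor
shapes, inter-scanner batch effects, or correlated (non-Gaussian) texture.
Passing recovery tests on phantoms therefore demonstrates that the
algorithms are implemented correctly and are statistically calibrated —
not that the pipeline generalizes to clinical scans.

# Numerical and scale choices

* Test and validation cohorts are sized for a desk machine: habitat
  recovery uses 20 patients on the default 64³ grid (~12,700 tumor voxels
  each); subtype recovery uses 90 patients (30 per subtype) on a 48³ grid
  with ~4,500-voxel tumors and 200 consensus resamples; survival
  calibration uses n = 300 cohorts with 100 replicates for CI coverage and
  500 for test level.
* All randomness flows through explicit integer seeds; per-case seeds are
  derived from a base seed with a fixed affine hash, so every cohort,
  resample and bootstrap is reproducible bit-for-bit.
* The consensus entry for a never-co-sampled pair is defined as 0 and
  flagged with a warning (it cannot occur at the default 500 resamples).
* Degenerate inputs have defined behaviour throughout: constant volumes
  yield zero entropy with a warning; constant superpixels yield zero
  skewness/kurtosis; single-label tumors yield zero correlation with a
  warning; a mask that fills the whole grid (no border possible) is an
  error.

# Known limitations

* The two-level clustering is not deterministic across platforms at the
  floating-point level (k-means and Louvain tie-breaks), although it is
  exactly reproducible for a fixed seed on one platform.
* Cross-cohort habitat alignment is provided only as a centroid-matching
  utility (`match_clusters()`); the pipeline clusters a pooled cohort once
  rather than clustering cohorts separately and matching.
* `assign_subtype()` transfers subtype labels by nearest medoid; this is an
  explicit mechanism chosen here, as label transfer between independently
  clustered cohorts is otherwise undefined.
* The MSI feature layout is canonical for K = 8; for other K the vector
  length follows `4 + 2(2K + K(K−1)/2)` and downstream column names shift
  accordingly.
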