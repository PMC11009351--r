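# habitatr

Habitat imaging for non-small cell lung cancer (NSCLC) risk stratification
from co-registered CT and FDG-PET. Between 30% and 55% of early-stage NSCLC
patients relapse after curative treatment; whole-tumor radiomics averages
away the regional heterogeneity that drives much of that risk. `habitatr`
instead partitions each tumor into phenotypically coherent subregions
("habitats"), quantifies how those subregions are arranged and interact in
space, and clusters patients into imaging subtypes that can be evaluated
against recurrence-free / overall survival and circulating tumor DNA
(ctDNA) status.

The pipeline:

1. **Harmonize** multi-site scans: lung-window CT (`ct_lung_window`),
   body-weight SUV (`compute_suv`), 1 mm isotropic resampling
   (`resample_isotropic`), local entropy maps (`local_entropy`).
2. **Discover habitats** by two-level clustering: fuse the four channels
   (CT, CT entropy, SUV, SUV entropy; `fuse_channels`), over-segment each
   tumor into contiguous superpixels by spatial k-means (`oversegment`),
   extract 40 first-order features per superpixel
   (`superpixel_features`), and cluster the pooled superpixels across the
   cohort with an SNN graph + Louvain (`population_cluster`).
3. **Quantify spatial architecture** with the multiregional spatial
   interaction (MSI) matrix: co-occurrence counts of habitat labels among
   26-connected neighbouring voxels, including a tumor-border label
   (`add_border_label`, `build_msi_matrix`). For K = 8 habitats this yields
   92 named features per patient (`extract_msi_features`): 4 second-order
   statistics (contrast, homogeneity, correlation, energy), 8 subregion
   volumes, 8 + 28 border/pairwise interactions, and their normalized
   counterparts.
4. **Derive imaging subtypes** by consensus clustering of the MSI vectors —
   repeated partition-around-medoids on the Spearman distance over patient
   subsamples, with the cluster number chosen from the consensus CDF
   delta-area (`consensus_cluster`, `select_k_by_cdf`, `assign_subtype`).
5. **Evaluate clinically**: Kaplan–Meier + log-rank (`km_logrank`), Cox
   models with the high-risk subtype as reference (`cox_fit`), Harrell's
   C-index model comparison (`compare_models`), ctDNA-by-subtype crosstabs
   (`ctdna_crosstab`), and conventional PET covariates
   (`conventional_pet_metrics`).

A synthetic phantom module (`phantom_spec`, `generate_phantom`,
`generate_cohort`, `simulate_survival`, `simulate_ctdna`) plants known
habitats, subtype mixtures, survival outcomes and ctDNA categories so the
entire pipeline is testable without clinical data. `run_pipeline()` runs
everything from a single YAML config and writes NIfTI/CSV/JSON artifacts
with a manifest; `inst/cli/habitat-pipeline.R` is a thin command-line
wrapper.

## Worked example

Generate a small synthetic cohort with four planted habitats, run habitat
discovery end to end, and extract MSI features:

```r
library(habitatr)

spec <- phantom_spec(
  grid_shape = c(48L, 48L, 48L), tumor_radii = c(14, 11, 10),
  habitat_means = cbind(ct = c(-600, 20, -450, 60), suv = c(1, 1.5, 6, 11)),
  habitat_sds = cbind(ct = c(40, 15, 70, 25), suv = c(0.2, 0.15, 0.9, 0.5)),
  subtype_mixtures = matrix(0.25, 1, 4, dimnames = list("only", NULL)))
cases <- lapply(1:6, function(i) generate_phantom(spec, 1, seed = i))
res <- run_habitat_cohort(cases, seed = 42)
res$K
#> [1] 4
ari <- sapply(seq_along(cases), function(i) {
  idx <- which(cases[[i]]$mask$data == 1)
  adjusted_rand(res$habitat_maps[[i]]$labels[idx],
                cases[[i]]$truth_labels[idx])
})
round(mean(ari), 2)
#> [1] 1
```

The recovered habitat count matches the four planted habitats and the
voxel-level adjusted Rand index against the planted labels is 1.0, i.e.
the discovered habitat maps reproduce the ground truth exactly on this
low-noise phantom.

MSI features and subtypes on a full synthetic cohort:

```r
spec8 <- phantom_spec(grid_shape = c(48L, 48L, 48L),
                      tumor_radii = c(14, 11, 10))   # 8 habitats, 3 subtypes
coh <- generate_cohort(spec8, n_per_subtype = 30, seed = 11,
                       keep_volumes = FALSE)
X <- msi_feature_table(lapply(coh$cases, `[[`, "truth_labels"),
                       lapply(coh$cases, `[[`, "mask"), K = 8)
cc <- consensus_cluster(X, n_resamples = 200, seed = 11)
cc
#> <consensus_result> n = 90 patients, k candidates 2, 3, 4, 5
#>   chosen k = 3  (delta-area: 2=0.503, 3=0.342, 4=0.076, 5=0.069)
#>   cluster sizes: 30, 29, 31
adjusted_rand(cc$labels, coh$clinical$subtype_truth)
#> [1] 0.9664753
```

Consensus clustering selects k = 3 (the delta-area criterion accepts k = 3
at 0.342 but rejects k = 4 at 0.076) and the recovered subtypes agree with
the planted mixtures at ARI 0.97.

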