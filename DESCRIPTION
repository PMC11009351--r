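Package: habitatr
Title: Tumor Habitat Imaging and Multiregional Spatial Interaction
    Analysis for PET/CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A habitat-imaging pipeline for co-registered CT and FDG-PET
    tumor volumes. Harmonizes multi-site scans (lung windowing, body-weight
    SUV, isotropic resampling, local entropy maps), fuses the four channels
    and over-segments each tumor into superpixels, clusters pooled
    superpixels into population-level habitat subregions, quantifies their
    spatial architecture with the 92-feature multiregional spatial
    interaction (MSI) matrix, derives imaging subtypes by consensus
    clustering with CDF-based selection of the cluster number, and
    evaluates subtypes against survival endpoints and circulating tumor
    DNA status. Includes a synthetic phantom generator so the whole
    pipeline is exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    cluster,
    survival,
    igraph,
    e1071,
    mclust,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
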