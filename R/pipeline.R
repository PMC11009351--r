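# End-to-end orchestration: phantom simulation or NIfTI input -> channel
# harmonization -> superpixel habitats -> MSI features -> consensus subtypes
# -> survival evaluation, with a manifest of every artifact written.

#' Run the habitat-discovery stage over a cohort
#'
#' Preprocesses every case, fuses the four channels, over-segments each tumor
#' into superpixels, pools the 40 first-order features across patients,
#' clusters them into population-level habitats and renders per-patient
#' habitat maps.
#'
#' @param cases list of cases; each needs `ct`, `suv` ([image_volume()]s) and
#'   `mask` ([tumor_mask()]).
#' @param target_spacing,window_center,window_width,suv_cap,entropy_radius,entropy_bins
#'   preprocessing parameters, see [preprocess_case()].
#' @param target_size,compactness,min_size superpixel parameters, see
#'   [oversegment()].
#' @param knn,snn_prune,resolution population clustering parameters, see
#'   [population_cluster()].
#' @param seed integer seed controlling k-means and Louvain.
#' @return List: `habitat_maps` (per patient), `masks` (resampled),
#'   `spmaps`, `features` (pooled superpixel table with `habitat` column),
#'   `K` (habitat count).
#' @export
run_habitat_cohort <- function(cases, target_spacing = 1,
                               window_center = -400, window_width = 1500,
                               suv_cap = 20, entropy_radius = 2,
                               entropy_bins = 32,
                               target_size = 100, compactness = 0.2,
                               min_size = 10,
                               knn = NULL, snn_prune = 1 / 15,
                               resolution = 0.4, seed = 1) {
  n <- length(cases)
  stacks <- vector("list", n)
  spmaps <- vector("list", n)
  masks <- vector("list", n)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- cases[[i]]
    pp <- preprocess_case(cs$ct, cs$suv, cs$mask,
                          target_spacing = target_spacing,
                          window_center = window_center,
                          window_width = window_width, suv_cap = suv_cap,
                          entropy_radius = entropy_radius,
                          entropy_bins = entropy_bins)
    st <- fuse_channels(pp$ct_norm, pp$ct_entropy, pp$suv_norm,
                        pp$suv_entropy, pp$mask, suv_cap = suv_cap,
                        entropy_bins = entropy_bins)
    sp <- oversegment(st, target_size = target_size,
                      compactness = compactness, min_size = min_size,
                      seed = child_seed(seed, i))
    stacks[[i]] <- st
    spmaps[[i]] <- sp
    masks[[i]] <- pp$mask
    feats[[i]] <- superpixel_features(st, sp,
                                      patient_id = sprintf("P%03d", i))
  }
  pooled <- do.call(rbind, feats)
  hab <- population_cluster(pooled, knn = knn, snn_prune = snn_prune,
                            resolution = resolution,
                            seed = child_seed(seed, 0L))
  pooled$habitat <- as.integer(hab)
  K <- attr(hab, "K")
  hmaps <- vector("list", n)
  for (i in seq_len(n)) {
    ids <- pooled$habitat[pooled$patient_id == sprintf("P%03d", i)]
    hmaps[[i]] <- render_habitat_map(spmaps[[i]], ids)
  }
  list(habitat_maps = hmaps, masks = masks, spmaps = spmaps,
       features = pooled, K = K)
}

#' Load (or validate) a pipeline configuration
#'
#' The configuration is a single YAML (or list) document holding stage
#' parameters and either a `phantom` section (synthetic cohort) or an
#' `inputs` section with per-patient NIfTI paths and a clinical CSV.
#'
#' @param config path to a YAML file, or a list.
#' @return Validated config list (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("pipeline_config: file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1L, outdir = "habitat_out",
    target_spacing = 1, window_center = -400, window_width = 1500,
    suv_cap = 20, entropy_radius = 2, entropy_bins = 32,
    target_size = 100, compactness = 0.2, min_size = 10,
    knn = NULL, snn_prune = 1 / 15, resolution = 0.4,
    k_range = 2:5, n_resamples = 500, subsample_fraction = 0.8,
    endpoint = "rfs")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (config$seed != round(config$seed))
    stop("pipeline_config: seed must be an integer")
  has_phantom <- !is.null(config$phantom)
  has_inputs <- !is.null(config$inputs)
  if (!has_phantom && !has_inputs)
    stop("pipeline_config: need a 'phantom' or 'inputs' section")
  if (has_inputs) {
    inp <- config$inputs
    if (is.null(inp$clinical) || !file.exists(inp$clinical))
      stop("pipeline_config: clinical CSV missing or not found")
    for (p in unlist(inp[c("ct", "suv", "mask")]))
      if (!file.exists(p))
        stop("pipeline_config: input volume not found: ", p)
  }
  structure(config, class = c("pipeline_config", "list"))
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate/load -> preprocess + habitats -> msi -> subtype ->
#' survive, writes artifacts (NIfTI habitat maps, CSV feature tables, JSON
#' results) under `config$outdir`, and returns a manifest. Re-running with
#' the same configuration and seeds reproduces all numeric outputs.
#'
#' @param config a [pipeline_config()] (or path / list coercible to one).
#' @return The manifest list (also written as `manifest.json`): per-stage
#'   outputs, parameters, seeds and md5 hashes.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  seed <- as.integer(cfg$seed)

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages[[name]] <<- res
    res
  }

  # -- stage 1: cohort ------------------------------------------------------
  cohort <- run_stage("simulate", function() {
    if (!is.null(cfg$phantom)) {
      ph <- cfg$phantom
      spec <- do.call(phantom_spec, ph$spec %||% list())
      generate_cohort(spec, n_per_subtype = ph$n_per_subtype %||% 10,
                      seed = seed)
    } else {
      inp <- cfg$inputs
      clinical <- load_clinical(inp$clinical)
      cases <- lapply(seq_along(inp$ct), function(i) list(
        ct = load_volume(inp$ct[[i]], "CT"),
        suv = load_volume(inp$suv[[i]], "SUV"),
        mask = {
          mv <- load_volume(inp$mask[[i]], "CT")
          tumor_mask(mv$data != 0, mv$spacing, mv$origin)
        }))
      list(cases = cases, clinical = clinical)
    }
    })
  clinical <- cohort$clinical
  utils::write.csv(clinical, file.path(cfg$outdir, "clinical.csv"),
                   row.names = FALSE)

  # -- stage 2: habitats ----------------------------------------------------
  hab <- run_stage("habitats", function()
    run_habitat_cohort(cohort$cases,
                       target_spacing = cfg$target_spacing,
                       window_center = cfg$window_center,
                       window_width = cfg$window_width,
                       suv_cap = cfg$suv_cap,
                       entropy_radius = cfg$entropy_radius,
                       entropy_bins = cfg$entropy_bins,
                       target_size = cfg$target_size,
                       compactness = cfg$compactness,
                       min_size = cfg$min_size,
                       knn = cfg$knn, snn_prune = cfg$snn_prune,
                       resolution = cfg$resolution, seed = seed))
  utils::write.csv(hab$features,
                   file.path(cfg$outdir, "superpixel_features.csv"),
                   row.names = FALSE)
  for (i in seq_along(hab$habitat_maps))
    write_volume(image_volume(hab$habitat_maps[[i]]$labels,
                              hab$masks[[i]]$spacing,
                              hab$masks[[i]]$origin, "LABEL"),
                 file.path(cfg$outdir, sprintf("habitat_P%03d.nii.gz", i)))

  # -- stage 3: MSI features ------------------------------------------------
  msi <- run_stage("msi", function()
    msi_feature_table(hab$habitat_maps, hab$masks, K = max(8, hab$K),
                      patient_ids = clinical$patient_id))
  utils::write.csv(as.data.frame(msi),
                   file.path(cfg$outdir, "msi_features.csv"))

  # -- stage 4: subtypes ----------------------------------------------------
  sub <- run_stage("subtype", function()
    consensus_cluster(msi, k_range = cfg$k_range,
                      n_resamples = cfg$n_resamples,
                      subsample_fraction = cfg$subsample_fraction,
                      seed = seed))
  clinical$subtype <- if (sub$chosen_k == 3)
    name_risk_levels(sub, msi) else as.character(sub$labels)
  utils::write.csv(clinical, file.path(cfg$outdir, "clinical_subtyped.csv"),
                   row.names = FALSE)

  # -- stage 5: survival ----------------------------------------------------
  surv <- run_stage("survive", function() {
    tcol <- paste0(cfg$endpoint, "_time")
    ecol <- paste0(cfg$endpoint, "_event")
    kml <- km_logrank(clinical, "subtype", time = tcol, event = ecol)
    cox <- tryCatch(cox_fit(clinical, "subtype", time = tcol, event = ecol),
                    error = function(e) NULL)
    ct <- tryCatch(ctdna_crosstab(clinical), error = function(e) NULL)
    list(logrank_chisq = kml$chisq, logrank_p = kml$p,
         cox_table = if (!is.null(cox)) cox$table else NULL,
         ctdna = ct)
  })
  jsonlite::write_json(
    list(logrank_chisq = surv$logrank_chisq, logrank_p = surv$logrank_p,
         cox = surv$cox_table, ctdna = surv$ctdna,
         chosen_k = sub$chosen_k),
    file.path(cfg$outdir, "survival_results.json"),
    auto_unbox = TRUE, digits = NA)

  # -- manifest -------------------------------------------------------------
  files <- list.files(cfg$outdir, full.names = TRUE)
  files <- files[!grepl("manifest[.]json$", files)]
  manifest <- list(
    stages = c("simulate", "habitats", "msi", "subtype", "survive"),
    parameters = cfg[setdiff(names(cfg), c("phantom", "inputs"))],
    seed = seed,
    n_patients = nrow(clinical),
    K_habitats = hab$K,
    chosen_k = sub$chosen_k,
    outputs = stats::setNames(as.list(unname(tools::md5sum(files))),
                              basename(files)))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
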