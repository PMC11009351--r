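# Synthetic phantom generator: paired CT/SUV volumes with planted contiguous
# habitat subregions, cohort-level subtype mixtures, subtype-linked survival
# and ctDNA status. Every downstream stage is testable against the planted
# truth. Defaults emulate the study conditions: 8 habitats whose (CT, SUV)
# phenotypes span dense/low-uptake through dense/high-uptake tissue, and
# 3 subtype mixtures (low/intermediate/high risk) where the high-risk mixture
# is enriched for the dense high-uptake habitats near the tumor border.

#' Phantom specification
#'
#' @param grid_shape integer length-3 voxel grid (default 64^3).
#' @param spacing isotropic voxel spacing in mm (default 1).
#' @param tumor_radii ellipsoid semi-axes in mm (default 18, 14, 12).
#' @param habitat_means `n_habitats x 2` matrix of per-habitat (CT HU, SUV)
#'   means. Default 8 habitats: 1-2 low CT / low SUV, 3-4 high CT / low SUV,
#'   5-6 low CT / high SUV, 7-8 high CT / high SUV.
#' @param habitat_sds `n_habitats x 2` matrix of per-habitat (CT HU, SUV)
#'   noise SDs; local texture entropy rises with the SD, so these encode the
#'   habitats' entropy phenotypes (default: low PET entropy for habitats 3-4,
#'   low CT entropy for 7-8). If `NULL`, `noise_sd` is recycled for all
#'   habitats.
#' @param noise_sd length-2 fallback (CT HU, SUV) noise SD used when
#'   `habitat_sds` is `NULL`, and for the background; default c(30, 0.3).
#' @param subtype_mixtures `n_subtypes x n_habitats` matrix of habitat volume
#'   fractions, rows summing to 1. Default 3 rows named low / intermediate /
#'   high.
#' @param mixture_conc Dirichlet concentration: realized per-patient fractions
#'   are drawn as Dirichlet(mixture * conc). `Inf` means exact fractions.
#' @param border_habitats list (one entry per subtype) of habitat ids whose
#'   growth seeds are placed near the tumor border. Default puts habitats
#'   4, 7, 8 at the border for the high-risk subtype.
#' @param background length-2 (CT HU, SUV) outside the tumor, default
#'   c(-800, 0.2).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing = 1,
                         tumor_radii = c(18, 14, 12),
                         habitat_means = NULL,
                         habitat_sds = NULL,
                         noise_sd = c(30, 0.3),
                         subtype_mixtures = NULL,
                         mixture_conc = 200,
                         border_habitats = NULL,
                         background = c(-800, 0.2)) {
  default_means <- is.null(habitat_means)
  if (is.null(habitat_means)) {
    habitat_means <- cbind(
      ct  = c(-600, -300,   20,   60, -450, -150,   40,   80),
      suv = c( 1.0,  2.0,  1.5,  1.0,  5.0,  7.0, 10.0, 12.0))
  }
  habitat_means <- as.matrix(habitat_means)
  n_h <- nrow(habitat_means)
  if (n_h < 2) stop("phantom_spec: need at least 2 habitats")
  if (any(noise_sd < 0)) stop("phantom_spec: noise_sd must be >= 0")
  if (is.null(habitat_sds)) {
    if (default_means) {
      # entropy phenotypes: PET entropy low for 3-4, CT entropy low for 7-8
      habitat_sds <- cbind(
        ct_sd  = c(40, 60, 25, 35, 60, 80, 15, 20),
        suv_sd = c(0.4, 0.6, 0.15, 0.2, 0.8, 1.0, 0.8, 1.0))
    } else {
      habitat_sds <- matrix(noise_sd, n_h, 2, byrow = TRUE)
    }
  }
  habitat_sds <- as.matrix(habitat_sds)
  if (!identical(dim(habitat_sds), dim(habitat_means)))
    stop("phantom_spec: habitat_sds must match habitat_means in shape")
  if (any(habitat_sds < 0)) stop("phantom_spec: habitat_sds must be >= 0")
  if (is.null(subtype_mixtures)) {
    if (n_h != 8)
      stop("phantom_spec: default subtype_mixtures require 8 habitats")
    subtype_mixtures <- rbind(
      low          = c(.05, .05, .35, .30, .08, .07, .05, .05),
      intermediate = c(.10, .15, .10, .10, .20, .15, .10, .10),
      high         = c(.05, .05, .08, .07, .05, .10, .35, .25))
  }
  subtype_mixtures <- as.matrix(subtype_mixtures)
  if (ncol(subtype_mixtures) != n_h)
    stop("phantom_spec: subtype_mixtures must have n_habitats columns")
  if (any(abs(rowSums(subtype_mixtures) - 1) > 1e-9))
    stop("phantom_spec: each subtype mixture must sum to 1")
  if (is.null(rownames(subtype_mixtures)))
    rownames(subtype_mixtures) <- paste0("subtype", seq_len(nrow(subtype_mixtures)))
  if (is.null(border_habitats)) {
    border_habitats <- rep(list(integer(0)), nrow(subtype_mixtures))
    hi <- which(rownames(subtype_mixtures) == "high")
    if (length(hi) && n_h >= 8) border_habitats[[hi]] <- c(4L, 7L, 8L)
  }
  structure(list(grid_shape = as.integer(grid_shape), spacing = spacing,
                 tumor_radii = tumor_radii, habitat_means = habitat_means,
                 habitat_sds = habitat_sds,
                 noise_sd = noise_sd, subtype_mixtures = subtype_mixtures,
                 mixture_conc = mixture_conc,
                 border_habitats = border_habitats,
                 background = background),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> grid %s, %d habitats, %d subtypes (%s)\n",
              paste(x$grid_shape, collapse = "x"),
              nrow(x$habitat_means), nrow(x$subtype_mixtures),
              paste(rownames(x$subtype_mixtures), collapse = ", ")))
  invisible(x)
}

# ellipsoidal mask centred in the grid
ellipsoid_mask <- function(grid_shape, radii_vox) {
  ctr <- (grid_shape + 1) / 2
  x <- ((seq_len(grid_shape[1]) - ctr[1]) / radii_vox[1])^2
  y <- ((seq_len(grid_shape[2]) - ctr[2]) / radii_vox[2])^2
  z <- ((seq_len(grid_shape[3]) - ctr[3]) / radii_vox[3])^2
  arr <- outer(outer(x, y, `+`), z, `+`)
  array(as.integer(arr <= 1), dim = grid_shape)
}

# multi-seed batched region growth to per-habitat target voxel counts;
# returns integer label array (0 outside mask), contiguous per habitat
grow_regions <- function(mask, targets, seed_idx) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  n_h <- length(targets)
  lab[seed_idx] <- seq_len(n_h)
  quota <- targets - 1L
  frontier <- as.list(seed_idx)
  offs <- offsets26()
  nbrs_of <- function(idx) {
    if (!length(idx)) return(integer(0))
    xyz <- lin_to_coord(idx, d)
    out <- integer(0)
    for (o in seq_len(nrow(offs))) {
      nb <- cbind(xyz[, 1] + offs[o, 1], xyz[, 2] + offs[o, 2],
                  xyz[, 3] + offs[o, 3])
      ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L &
            nb[, 2] <= d[2] & nb[, 3] >= 1L & nb[, 3] <= d[3]
      out <- c(out, coord_to_lin(nb[ok, , drop = FALSE], d))
    }
    unique(out)
  }
  refreshed <- logical(n_h)
  repeat {
    remaining <- sum(mask == 1L & lab == 0L)
    if (remaining == 0L) break
    progress <- FALSE
    for (h in sample(seq_len(n_h))) {
      if (quota[h] <= 0L) next
      cand <- nbrs_of(frontier[[h]])
      cand <- cand[mask[cand] == 1L & lab[cand] == 0L]
      if (!length(cand)) {
        if (!refreshed[h]) {          # frontier stale: rescan whole region
          frontier[[h]] <- which(lab == h)
          refreshed[h] <- TRUE
          cand <- nbrs_of(frontier[[h]])
          cand <- cand[mask[cand] == 1L & lab[cand] == 0L]
        }
        if (!length(cand)) next
      }
      refreshed[h] <- FALSE
      take <- cand[seq_len(min(length(cand), quota[h]))]
      lab[take] <- h
      quota[h] <- quota[h] - length(take)
      frontier[[h]] <- take
      progress <- TRUE
    }
    if (!progress) {
      # quotas exhausted or regions boxed in: flood remaining voxels from the
      # nearest assigned region, ignoring quotas
      repeat {
        un <- which(mask == 1L & lab == 0L)
        if (!length(un)) break
        changed <- FALSE
        for (o in seq_len(nrow(offs))) {
          p <- offset_pairs(d, offs[o, ])
          sel <- lab[p$center] > 0L & mask[p$nb] == 1L & lab[p$nb] == 0L
          if (any(sel)) {
            lab[p$nb[sel]] <- lab[p$center[sel]]
            changed <- TRUE
          }
        }
        if (!changed) break
      }
      break
    }
  }
  lab
}

#' Generate one synthetic CT/PET phantom case
#'
#' Plants an ellipsoidal tumor whose voxels are partitioned into contiguous
#' habitat blobs with volume fractions drawn around the subtype mixture, then
#' fills CT (HU) and PET (SUV) channels with habitat means plus Gaussian
#' noise. Deterministic given `seed`.
#'
#' @param spec a [phantom_spec()].
#' @param subtype subtype row index or row name of `spec$subtype_mixtures`.
#' @param seed integer RNG seed.
#' @return A list of class `phantom_case` with elements `ct`, `suv`
#'   ([image_volume()]s), `mask` ([tumor_mask()]), `truth_labels` (integer
#'   array, 0 outside tumor), `subtype` (row name) and `fractions` (realized
#'   habitat volume fractions).
#' @export
generate_phantom <- function(spec, subtype = 1, seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.character(subtype))
    subtype <- match(subtype, rownames(spec$subtype_mixtures))
  if (is.na(subtype) || subtype < 1 || subtype > nrow(spec$subtype_mixtures))
    stop("generate_phantom: unknown subtype")
  set.seed(seed)
  d <- spec$grid_shape
  mask <- ellipsoid_mask(d, spec$tumor_radii / spec$spacing)
  tumor_idx <- which(mask == 1L)
  V <- length(tumor_idx)
  n_h <- nrow(spec$habitat_means)
  if (V < n_h)
    stop("generate_phantom: tumor of ", V,
         " voxel(s) cannot host ", n_h, " habitats")
  mix <- spec$subtype_mixtures[subtype, ]
  if (is.finite(spec$mixture_conc)) {
    g <- stats::rgamma(n_h, shape = mix * spec$mixture_conc)
    frac <- g / sum(g)
  } else frac <- mix
  # largest-remainder rounding to exact voxel counts, >= 1 each
  raw <- frac * V
  cnt <- pmax(1L, floor(raw))
  while (sum(cnt) > V) cnt[which.max(cnt)] <- cnt[which.max(cnt)] - 1L
  rem <- V - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - floor(raw), decreasing = TRUE)
    add <- rep(seq_along(ord), length.out = rem)
    for (i in seq_len(rem)) cnt[ord[add[i]]] <- cnt[ord[add[i]]] + 1L
  }
  # growth seeds: border-biased habitats start within 2 voxels of the surface
  eroded <- mask
  for (i in 1:2) {
    shrunk <- 1L - dilate26(1L - eroded)
    if (sum(shrunk) > n_h) eroded <- shrunk
  }
  near_border <- tumor_idx[eroded[tumor_idx] == 0L]
  interior <- tumor_idx[eroded[tumor_idx] == 1L]
  if (!length(interior)) interior <- tumor_idx
  bh <- spec$border_habitats[[subtype]]
  seed_idx <- integer(n_h)
  pool_b <- near_border
  pool_i <- interior
  for (h in seq_len(n_h)) {
    pool <- if (h %in% bh && length(pool_b)) pool_b else pool_i
    pick <- pool[sample.int(length(pool), 1L)]
    seed_idx[h] <- pick
    pool_b <- setdiff(pool_b, pick)
    pool_i <- setdiff(pool_i, pick)
  }
  labels <- grow_regions(mask, cnt, seed_idx)
  # fill channels
  ct <- array(spec$background[1], dim = d)
  suv <- array(spec$background[2], dim = d)
  if (spec$noise_sd[1] > 0)
    ct <- ct + array(stats::rnorm(prod(d), 0, spec$noise_sd[1] / 3), dim = d)
  for (h in seq_len(n_h)) {
    idx <- which(labels == h)
    ct[idx] <- spec$habitat_means[h, 1] +
      stats::rnorm(length(idx), 0, spec$habitat_sds[h, 1])
    suv[idx] <- pmax(0, spec$habitat_means[h, 2] +
                       stats::rnorm(length(idx), 0, spec$habitat_sds[h, 2]))
  }
  realized <- tabulate(labels[tumor_idx], nbins = n_h) / V
  structure(list(
    ct = image_volume(ct, rep(spec$spacing, 3), modality = "CT"),
    suv = image_volume(suv, rep(spec$spacing, 3), modality = "SUV"),
    mask = tumor_mask(mask, rep(spec$spacing, 3)),
    truth_labels = labels,
    subtype = rownames(spec$subtype_mixtures)[subtype],
    fractions = realized),
    class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> subtype %s, tumor %d voxels, %d habitats\n",
              x$subtype, sum(x$mask$data), max(x$truth_labels)))
  invisible(x)
}

#' Simulate subtype-linked survival outcomes
#'
#' Event times follow a proportional-hazards Weibull model with the high-risk
#' subtype as reference; hazard ratios below 1 mean better outcome. Each
#' patient independently receives a uniform censoring time with probability
#' `censor_rate` (so `censor_rate = 0` observes every event).
#'
#' @param subtypes character vector with values in
#'   `c("low", "intermediate", "high")` (or a factor).
#' @param hr_low_vs_high,hr_int_vs_high hazard ratios vs the high-risk
#'   reference; defaults 0.38 and 0.52.
#' @param baseline_shape,baseline_scale Weibull baseline (shape 1.2, scale 60
#'   months).
#' @param censor_rate fraction of patients eligible for censoring, in \[0, 1).
#' @param censor_max upper bound of the uniform censoring window (months).
#' @param extra_lp optional per-patient additive log-hazard term (e.g. an
#'   independent ctDNA effect); recycled, default 0.
#' @param seed integer RNG seed.
#' @return A `data.frame` with columns `time` (months) and `event` (0/1).
#' @export
simulate_survival <- function(subtypes, hr_low_vs_high = 0.38,
                              hr_int_vs_high = 0.52,
                              baseline_shape = 1.2, baseline_scale = 60,
                              censor_rate = 0.3, censor_max = 80,
                              extra_lp = 0, seed = 1) {
  subtypes <- as.character(subtypes)
  bad <- setdiff(unique(subtypes), c("low", "intermediate", "high"))
  if (length(bad)) stop("simulate_survival: unknown subtype(s): ",
                        paste(bad, collapse = ", "))
  if (hr_low_vs_high <= 0 || hr_int_vs_high <= 0)
    stop("simulate_survival: hazard ratios must be > 0")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("simulate_survival: censor_rate must be in [0, 1)")
  if (baseline_shape <= 0 || baseline_scale <= 0)
    stop("simulate_survival: Weibull parameters must be > 0")
  set.seed(seed)
  n <- length(subtypes)
  lp <- log(c(low = hr_low_vs_high, intermediate = hr_int_vs_high,
              high = 1))[subtypes] + rep_len(extra_lp, n)
  u <- stats::runif(n)
  t_event <- baseline_scale * (-log(u) / exp(lp))^(1 / baseline_shape)
  cens <- stats::runif(n) < censor_rate
  c_time <- ifelse(cens, stats::runif(n, 0, censor_max), Inf)
  data.frame(time = pmin(t_event, c_time),
             event = as.integer(t_event <= c_time))
}

default_ctdna_probs <- function() {
  list(
    baseline = c(low = 0.40, intermediate = 0.70, high = 0.80),
    clearance = rbind(
      low          = c(Persistent = 0.13, Cleared = 0.25,
                       `Never Detected` = 0.62),
      intermediate = c(Persistent = 0.30, Cleared = 0.45,
                       `Never Detected` = 0.25),
      high         = c(Persistent = 0.67, Cleared = 0.18,
                       `Never Detected` = 0.15)))
}

#' Simulate subtype-linked ctDNA status
#'
#' Draws a baseline detection indicator and a clearance category (Persistent /
#' Cleared / Never Detected) per patient from per-subtype distributions. The
#' default clearance distributions put 67% Persistent in the high-risk group,
#' 62% Never Detected in the low-risk group and 45% Cleared in the
#' intermediate group.
#'
#' @param subtypes character vector in `c("low", "intermediate", "high")`.
#' @param baseline_probs named per-subtype probability of baseline detection.
#' @param clearance_probs per-subtype matrix (rows = subtypes, columns =
#'   Persistent / Cleared / Never Detected), rows summing to 1.
#' @param seed integer RNG seed.
#' @return A `data.frame` with columns `ctdna_baseline`
#'   (`"detected"`/`"not_detected"`) and `ctdna_clearance`.
#' @export
simulate_ctdna <- function(subtypes, baseline_probs = NULL,
                           clearance_probs = NULL, seed = 1) {
  subtypes <- as.character(subtypes)
  defs <- default_ctdna_probs()
  if (is.null(baseline_probs)) baseline_probs <- defs$baseline
  if (is.null(clearance_probs)) clearance_probs <- defs$clearance
  clearance_probs <- as.matrix(clearance_probs)
  if (any(abs(rowSums(clearance_probs) - 1) > 1e-9))
    stop("simulate_ctdna: each clearance distribution must sum to 1")
  if (any(clearance_probs < 0))
    stop("simulate_ctdna: negative probability")
  bad <- setdiff(unique(subtypes), rownames(clearance_probs))
  if (length(bad)) stop("simulate_ctdna: unknown subtype(s): ",
                        paste(bad, collapse = ", "))
  set.seed(seed)
  n <- length(subtypes)
  cats <- colnames(clearance_probs)
  clearance <- character(n)
  for (s in unique(subtypes)) {
    idx <- which(subtypes == s)
    clearance[idx] <- sample(cats, length(idx), replace = TRUE,
                             prob = clearance_probs[s, ])
  }
  baseline <- ifelse(stats::runif(n) < baseline_probs[subtypes],
                     "detected", "not_detected")
  data.frame(ctdna_baseline = baseline, ctdna_clearance = clearance,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with clinical outcomes
#'
#' Draws `n` patients across subtypes, generates each phantom case and
#' assembles a clinical table with subtype-linked survival and ctDNA status.
#'
#' @param spec a [phantom_spec()].
#' @param n_per_subtype integer patients per subtype (recycled across
#'   subtypes), or a named vector.
#' @param seed integer RNG seed; per-case seeds are derived from it.
#' @param keep_volumes if `FALSE`, drop the CT/SUV volumes and keep only the
#'   mask and truth labels (fast path when only habitat geometry is needed).
#' @param ... passed to [simulate_survival()].
#' @return List with `cases` (list of `phantom_case`) and `clinical`
#'   (data.frame with patient_id, subtype_truth, survival and ctDNA columns).
#' @export
generate_cohort <- function(spec, n_per_subtype = 10, seed = 1,
                            keep_volumes = TRUE, ...) {
  stopifnot(inherits(spec, "phantom_spec"))
  st_names <- rownames(spec$subtype_mixtures)
  n_st <- length(st_names)
  nps <- rep_len(n_per_subtype, n_st)
  subtypes <- rep(st_names, times = nps)
  n <- length(subtypes)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- generate_phantom(spec, subtypes[i], seed = child_seed(seed, i))
    if (!keep_volumes) cs$ct <- cs$suv <- NULL
    cases[[i]] <- cs
  }
  surv <- simulate_survival(subtypes, seed = child_seed(seed, n + 1), ...)
  ctdna <- simulate_ctdna(subtypes, seed = child_seed(seed, n + 2))
  clinical <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = round(stats::rnorm(n, 67, 9)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    stage = sample(c("I", "II", "III"), n, replace = TRUE,
                   prob = c(.45, .25, .30)),
    histology = sample(c("adenocarcinoma", "squamous", "other"), n,
                       replace = TRUE, prob = c(.75, .20, .05)),
    treatment = sample(c("surgery", "chemotherapy"), n, replace = TRUE,
                       prob = c(.7, .3)),
    subtype_truth = subtypes,
    rfs_time = surv$time, rfs_event = surv$event,
    os_time = surv$time * stats::runif(n, 1, 1.3),
    os_event = surv$event,
    ctdna_baseline = ctdna$ctdna_baseline,
    ctdna_clearance = ctdna$ctdna_clearance,
    stringsAsFactors = FALSE)
  list(cases = cases, clinical = clinical)
}
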