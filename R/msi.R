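# Multiregional spatial interaction (MSI) matrix and its 92 features: the
# co-occurrence statistics of habitat labels among 26-connected neighboring
# voxels, including a tumor-border label, summarized into second-order
# texture statistics, subregion volumes and pairwise interaction counts.

#' Add the tumor-border label around a habitat map
#'
#' The border is the set of non-tumor voxels 26-adjacent to at least one
#' tumor voxel. Returns a labeled volume where tumor voxels keep their
#' habitat ids (1..K), border voxels carry label 0, and everything else is
#' `NA`.
#'
#' @param hmap a `habitat_map` (see [render_habitat_map()]) or an integer
#'   label array with 0 outside the tumor.
#' @param mask [tumor_mask()] or binary array consistent with `hmap`.
#' @return Integer array: habitat ids on tumor, 0 on border, `NA` elsewhere.
#' @export
add_border_label <- function(hmap, mask) {
  labels <- if (inherits(hmap, "habitat_map")) hmap$labels else hmap
  m <- if (is_image_volume(mask)) mask$data else mask
  d <- dim(labels)
  if (!identical(d, dim(m))) stop("add_border_label: shape mismatch")
  if (any(labels[m == 1L] == 0L))
    stop("add_border_label: unlabeled voxel inside mask")
  if (any(labels[m == 0L] != 0L))
    stop("add_border_label: habitat label outside mask")
  border <- dilate26(m) & !m
  if (!any(border))
    stop("add_border_label: mask fills the entire grid; no border possible")
  out <- array(NA_integer_, dim = d)
  out[m == 1L] <- labels[m == 1L]
  out[border] <- 0L
  out
}

#' Build the MSI co-occurrence matrix
#'
#' For every voxel carrying a tumor or border label, each of its <= 26
#' neighbors with a tumor or border label contributes one ordered count to
#' `counts[label(v), label(u)]`; border-border pairs are skipped. Counting
#' both directions makes the matrix symmetric by construction: the entry for
#' an unordered label pair {i, j}, i != j, equals the number of unordered
#' adjacent voxel pairs with those labels.
#'
#' @param labeled integer array from [add_border_label()] (0 = border,
#'   1..K = subregions, `NA` = outside).
#' @param K number of subregions; default `max(labeled, na.rm = TRUE)`.
#' @return Integer `(K+1) x (K+1)` matrix of class `msi_matrix`, dimnames
#'   `border, SR1..SRK`.
#' @export
build_msi_matrix <- function(labeled, K = NULL) {
  d <- dim(labeled)
  if (is.null(K)) K <- max(labeled, na.rm = TRUE)
  if (K < 1) stop("build_msi_matrix: no tumor labels present")
  counts <- matrix(0, K + 1, K + 1)
  offs <- offsets26()
  for (o in seq_len(nrow(offs))) {
    p <- offset_pairs(d, offs[o, ])
    lv <- labeled[p$center]
    lu <- labeled[p$nb]
    ok <- !is.na(lv) & !is.na(lu) & !(lv == 0L & lu == 0L)
    if (!any(ok)) next
    # accumulate ordered pairs via a flat cross-tabulation
    flat <- (lv[ok]) * (K + 1) + lu[ok] + 1   # labels 0..K -> 1-based cell
    tab <- tabulate(flat, nbins = (K + 1)^2)
    counts <- counts + matrix(tab, K + 1, K + 1, byrow = TRUE)
  }
  dimnames(counts) <- list(c("border", paste0("SR", seq_len(K))),
                           c("border", paste0("SR", seq_len(K))))
  structure(counts, class = c("msi_matrix", "matrix", "array"), K = K)
}

#' Second-order statistics of the normalized MSI matrix
#'
#' With `P = counts / sum(counts)` and `i, j` the row/column indices:
#' contrast `= sum P(i,j) (i-j)^2`, homogeneity `= sum P(i,j) / (1+|i-j|)`,
#' energy `= sum P(i,j)^2`, and correlation
#' `= sum (i-mu_i)(j-mu_j) P(i,j) / (sigma_i sigma_j)` with marginal mean and
#' SD; correlation is 0 (with a warning) when a marginal SD vanishes.
#'
#' @param counts an [build_msi_matrix()] result (or any nonnegative matrix
#'   with positive total).
#' @return Named numeric vector `contrast, homogeneity, correlation, energy`.
#' @export
msi_second_order <- function(counts) {
  counts <- unclass(counts)
  tot <- sum(counts)
  if (tot <= 0) stop("msi_second_order: empty matrix")
  P <- counts / tot
  n <- nrow(P)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  contrast <- sum(P * (i - j)^2)
  homogeneity <- sum(P / (1 + abs(i - j)))
  energy <- sum(P^2)
  pi_ <- rowSums(P)
  pj_ <- colSums(P)
  mu_i <- sum(seq_len(n) * pi_)
  mu_j <- sum(seq_len(n) * pj_)
  sd_i <- sqrt(sum((seq_len(n) - mu_i)^2 * pi_))
  sd_j <- sqrt(sum((seq_len(n) - mu_j)^2 * pj_))
  if (sd_i * sd_j == 0) {
    warning("msi_second_order: degenerate marginal; correlation set to 0")
    correlation <- 0
  } else {
    correlation <- sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j)
  }
  c(contrast = contrast, homogeneity = homogeneity,
    correlation = correlation, energy = energy)
}

#' Extract the MSI feature vector
#'
#' For the canonical `K = 8` this yields exactly 92 named features
#' `MSI1..MSI92`: MSI1-4 second-order statistics of the normalized MSI
#' matrix; MSI5-12 absolute subregion volumes (voxel counts of SR1..SR8,
#' 0 if absent); MSI13-20 absolute subregion-border interactions; MSI21-48
#' absolute pairwise interactions SRi-SRj for i < j; MSI49-56 percentage
#' volumes (summing to 100); MSI57-92 the interactions normalized by the
#' total unordered interaction count (values in \[0, 1\]). For general K the
#' length is `4 + 2*(2K + K(K-1)/2)`.
#'
#' @param counts an [build_msi_matrix()] result.
#' @param hmap `habitat_map` or integer label array (for subregion volumes).
#' @param K number of subregions (default 8, the canonical habitat count).
#' @return Named numeric vector (length 92 for K = 8) with attribute
#'   `description`.
#' @export
extract_msi_features <- function(counts, hmap, K = 8) {
  labels <- if (inherits(hmap, "habitat_map")) hmap$labels else hmap
  counts <- unclass(counts)
  if (nrow(counts) != K + 1)
    stop("extract_msi_features: matrix is ", nrow(counts), "x", ncol(counts),
         " but K = ", K, " requires ", K + 1, "x", K + 1)
  if (max(labels, na.rm = TRUE) > K)
    stop("extract_msi_features: habitat map contains labels above K")
  so <- msi_second_order(counts)
  vols <- tabulate(labels[labels > 0L & !is.na(labels)], nbins = K)
  border_int <- counts[1 + seq_len(K), 1]
  pairs <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  pair_int <- counts[cbind(pairs[, 1] + 1, pairs[, 2] + 1)]
  pct_vol <- 100 * vols / sum(vols)
  # total unordered interaction count: each off-diagonal/border pair once
  ut <- upper.tri(counts)
  total_int <- sum(counts[ut])
  norm_border <- if (total_int > 0) border_int / total_int else
    rep(0, K)
  norm_pair <- if (total_int > 0) pair_int / total_int else
    rep(0, nrow(pairs))
  vals <- c(so, vols, border_int, pair_int, pct_vol, norm_border, norm_pair)
  names(vals) <- paste0("MSI", seq_along(vals))
  pair_lab <- paste0("SR", pairs[, 1], "-SR", pairs[, 2])
  attr(vals, "description") <- c(
    paste0("2nd-order ", names(so)),
    paste0("volume SR", seq_len(K)),
    paste0("interaction SR", seq_len(K), "-border"),
    paste0("interaction ", pair_lab),
    paste0("pct volume SR", seq_len(K)),
    paste0("norm interaction SR", seq_len(K), "-border"),
    paste0("norm interaction ", pair_lab))
  vals
}

#' MSI features for a cohort of habitat maps
#'
#' @param hmaps list of `habitat_map`s (or label arrays).
#' @param masks list of matching [tumor_mask()]s.
#' @param K habitat count shared across the cohort (default 8).
#' @param patient_ids optional ids for rownames.
#' @return Numeric matrix, one row per patient, columns `MSI1..`.
#' @export
msi_feature_table <- function(hmaps, masks, K = 8, patient_ids = NULL) {
  stopifnot(length(hmaps) == length(masks))
  rows <- lapply(seq_along(hmaps), function(i) {
    lb <- add_border_label(hmaps[[i]], masks[[i]])
    M <- build_msi_matrix(lb, K = K)
    extract_msi_features(M, hmaps[[i]], K = K)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- patient_ids %||% paste0("P", seq_along(hmaps))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Conventional PET metrics
#'
#' SUVmax/SUVmean over the tumor mask, metabolic tumor volume (MTV: volume of
#' mask voxels with SUV >= threshold, in mL), total lesion glycolysis
#' (TLG = MTV x mean SUV within the MTV region) and tumor volume.
#'
#' @param suv SUV [image_volume()].
#' @param mask [tumor_mask()] on the same grid.
#' @param mtv_threshold absolute SUV threshold (default 2.5), or if
#'   `relative = TRUE` a fraction of SUVmax (e.g. 0.4).
#' @param relative interpret `mtv_threshold` as a fraction of SUVmax.
#' @return Named list: `suv_max`, `suv_mean`, `mtv` (mL), `tlg` (mL*SUV),
#'   `tumor_volume` (mL).
#' @export
conventional_pet_metrics <- function(suv, mask, mtv_threshold = 2.5,
                                     relative = FALSE) {
  check_same_grid(suv, mask, "SUV and mask")
  idx <- which(mask$data == 1L)
  if (!length(idx)) stop("conventional_pet_metrics: empty mask")
  vals <- suv$data[idx]
  vox_ml <- prod(suv$spacing) / 1000
  thr <- if (relative) mtv_threshold * max(vals) else mtv_threshold
  hot <- vals[vals >= thr]
  mtv <- length(hot) * vox_ml
  list(suv_max = max(vals), suv_mean = mean(vals),
       mtv = mtv,
       tlg = if (length(hot)) mtv * mean(hot) else 0,
       tumor_volume = length(idx) * vox_ml)
}
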