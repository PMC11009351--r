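# Habitat discovery: fuse the four harmonized channels, over-segment each
# tumor into superpixels by k-means on intensity + spatial coordinates,
# extract 40 first-order features per superpixel, and cluster the pooled
# superpixels into population-level habitats via an SNN graph + Louvain.

CHANNEL_NAMES <- c("ct", "ct_entropy", "suv", "suv_entropy")
STAT_NAMES <- c("skewness", "kurtosis", "mean", "median", "q1", "q2",
                "iqr", "sd", "variance", "energy")

#' Fuse the four habitat channels
#'
#' Scales each channel to \[0, 1\] with fixed cohort windows (CT window output
#' is already \[0, 1\]; SUV is divided by `suv_cap` and clipped; entropy maps
#' are divided by `log2(entropy_bins)`) and sums them voxelwise into a
#' texture-rich composite.
#'
#' @param ct_norm,ct_ent,suv_norm,suv_ent [image_volume()]s on one grid.
#'   `suv_norm` may be raw SUV (it is clipped/scaled here if any value
#'   exceeds 1).
#' @param mask [tumor_mask()] on the same grid.
#' @param suv_cap SUV ceiling used for scaling when `suv_norm` is raw SUV.
#' @param entropy_bins histogram bin count used for the entropy maps.
#' @return A list of class `fused_stack`: `channels` (named list of 4 scaled
#'   volumes), `composite` (sum, range \[0, 4\]), `mask`.
#' @export
fuse_channels <- function(ct_norm, ct_ent, suv_norm, suv_ent, mask,
                          suv_cap = 20, entropy_bins = 32) {
  vols <- list(ct = ct_norm, ct_entropy = ct_ent, suv = suv_norm,
               suv_entropy = suv_ent)
  for (v in vols) check_same_grid(v, mask, "channel and mask")
  emax <- log2(entropy_bins)
  scaled <- list(
    ct = clip(ct_norm$data, 0, 1),
    ct_entropy = clip(ct_ent$data / emax, 0, 1),
    suv = if (max(suv_norm$data) > 1)
      clip(suv_norm$data, 0, suv_cap) / suv_cap else clip(suv_norm$data, 0, 1),
    suv_entropy = clip(suv_ent$data / emax, 0, 1))
  composite <- Reduce(`+`, scaled)
  structure(list(
    channels = lapply(scaled, function(a)
      image_volume(a, mask$spacing, mask$origin, "NORMALIZED")),
    composite = image_volume(composite, mask$spacing, mask$origin,
                             "NORMALIZED"),
    mask = mask), class = "fused_stack")
}

#' Over-segment a tumor into superpixels
#'
#' SLIC-style k-means on vectors `(lambda*x, lambda*y, lambda*z, c1..c4)`
#' restricted to tumor voxels, with `lambda = compactness / S` where `S` is
#' the equivalent superpixel diameter `(V / n)^(1/3)` in voxels. K-means
#' clusters are split into 26-connected components; components smaller than
#' `min_size` are merged into the adjacent superpixel with the nearest
#' feature centroid. Deterministic given `seed`.
#'
#' @param stack a [fuse_channels()] result.
#' @param n_superpixels target count; default `max(10, round(V / target_size))`.
#' @param target_size target voxels per superpixel (default 100).
#' @param compactness spatial weight (default 0.2).
#' @param min_size minimum superpixel size in voxels (default 10).
#' @param seed integer RNG seed for k-means initialization.
#' @return A list of class `superpixel_map`: `labels` (integer array, 0
#'   outside the tumor, 1..S inside), `n` (label count).
#' @export
oversegment <- function(stack, n_superpixels = NULL, target_size = 100,
                        compactness = 0.2, min_size = 10, seed = 1) {
  stopifnot(inherits(stack, "fused_stack"))
  d <- dim(stack$mask$data)
  tumor_idx <- which(stack$mask$data == 1L)
  V <- length(tumor_idx)
  if (is.null(n_superpixels))
    n_superpixels <- max(10L, as.integer(round(V / target_size)))
  n_superpixels <- min(n_superpixels, V)
  if (n_superpixels < 1) stop("oversegment: n_superpixels must be >= 1")
  xyz <- lin_to_coord(tumor_idx, d)
  feats <- cbind(
    stack$channels$ct$data[tumor_idx],
    stack$channels$ct_entropy$data[tumor_idx],
    stack$channels$suv$data[tumor_idx],
    stack$channels$suv_entropy$data[tumor_idx])
  S_diam <- (V / n_superpixels)^(1 / 3)
  lambda <- compactness / S_diam
  X <- cbind(xyz * lambda, feats)
  if (n_superpixels == 1L) {
    km_lab <- rep(1L, V)
  } else {
    set.seed(seed)
    km <- stats::kmeans(X, centers = n_superpixels, iter.max = 50,
                        nstart = 1)
    km_lab <- km$cluster
  }
  # split k-means clusters into spatially connected components
  lab_arr <- array(0L, dim = d)
  lab_arr[tumor_idx] <- km_lab
  comp <- label_components(lab_arr)
  sp <- comp[tumor_idx]
  # merge undersized components into the adjacent superpixel whose feature
  # centroid is nearest
  repeat {
    sizes <- table(sp)
    small <- as.integer(names(sizes)[sizes < min_size])
    if (!length(small) || length(sizes) == 1L) break
    lab_arr[tumor_idx] <- sp
    merged_any <- FALSE
    centroids <- rowsum(X, sp) / as.vector(table(sp))
    for (s in small) {
      vox <- tumor_idx[sp == s]
      nb_labels <- adjacent_labels(lab_arr, vox, d)
      nb_labels <- setdiff(nb_labels, c(0L, s))
      if (!length(nb_labels)) next
      cs <- centroids[as.character(s), , drop = FALSE]
      dists <- apply(centroids[as.character(nb_labels), , drop = FALSE], 1,
                     function(r) sum((r - cs)^2))
      tgt <- nb_labels[which.min(dists)]
      sp[sp == s] <- tgt
      lab_arr[vox] <- tgt
      merged_any <- TRUE
    }
    if (!merged_any) break
  }
  # dense relabel 1..S
  sp <- as.integer(factor(sp))
  out <- array(0L, dim = d)
  out[tumor_idx] <- sp
  if (max(sp) < n_superpixels && n_superpixels > 1)
    warning("oversegment: ", max(sp), " superpixels after splitting/merging ",
            "(target ", n_superpixels, ")")
  structure(list(labels = out, n = max(sp)), class = "superpixel_map")
}

# set of labels 26-adjacent to the given voxels
adjacent_labels <- function(lab_arr, vox, d) {
  xyz <- lin_to_coord(vox, d)
  offs <- offsets26()
  out <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nb <- cbind(xyz[, 1] + offs[o, 1], xyz[, 2] + offs[o, 2],
                xyz[, 3] + offs[o, 3])
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L &
          nb[, 2] <= d[2] & nb[, 3] >= 1L & nb[, 3] <= d[3]
    out <- union(out, unique(lab_arr[coord_to_lin(nb[ok, , drop = FALSE], d)]))
  }
  out
}

# the 10 first-order statistics of one intensity vector; skewness/kurtosis of
# constant data are 0 by convention (kurtosis is excess kurtosis); energy is
# the sum of squared intensities
first_order_stats <- function(x) {
  s <- stats::sd(x)
  qs <- stats::quantile(x, c(.25, .5, .75), names = FALSE, type = 7)
  sk <- if (s == 0 || length(x) < 2) 0 else e1071::skewness(x, type = 2)
  ku <- if (s == 0 || length(x) < 4) 0 else e1071::kurtosis(x, type = 2)
  if (!is.finite(sk)) sk <- 0
  if (!is.finite(ku)) ku <- 0
  c(skewness = sk, kurtosis = ku, mean = mean(x), median = qs[2],
    q1 = qs[1], q2 = qs[2], iqr = qs[3] - qs[1],
    sd = if (is.na(s)) 0 else s, variance = if (is.na(s)) 0 else s^2,
    energy = sum(x^2))
}

#' First-order features per superpixel
#'
#' For every superpixel and each of the 4 channels, computes 10 first-order
#' statistics (skewness, kurtosis, mean, median, first quartile, second
#' quartile, interquartile range, standard deviation, variance, energy) of
#' the voxel intensities — 40 features per superpixel. `median` and `q2` are
#' mathematically identical and are both kept as separate columns.
#'
#' @param stack a [fuse_channels()] result (scaled channels).
#' @param spmap an [oversegment()] result.
#' @param patient_id optional id recorded in the output.
#' @return A `data.frame` with `patient_id`, `superpixel_id`, `size` and 40
#'   feature columns named `<stat>_<channel>`.
#' @export
superpixel_features <- function(stack, spmap, patient_id = "P1") {
  stopifnot(inherits(stack, "fused_stack"),
            inherits(spmap, "superpixel_map"))
  tumor_idx <- which(spmap$labels != 0L)
  sp <- spmap$labels[tumor_idx]
  S <- max(sp)
  out <- matrix(NA_real_, nrow = S, ncol = 40)
  cn <- as.vector(outer(STAT_NAMES, CHANNEL_NAMES, paste, sep = "_"))
  colnames(out) <- cn
  for (ci in seq_along(CHANNEL_NAMES)) {
    vals <- stack$channels[[CHANNEL_NAMES[ci]]]$data[tumor_idx]
    per <- vapply(seq_len(S),
                  function(s) first_order_stats(vals[sp == s]),
                  numeric(10))
    out[, (ci - 1) * 10 + seq_len(10)] <- t(per)
  }
  if (any(!is.finite(out)))
    stop("superpixel_features: non-finite feature value")
  data.frame(patient_id = patient_id, superpixel_id = seq_len(S),
             size = as.vector(table(factor(sp, levels = seq_len(S)))),
             out, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Population-level clustering of pooled superpixels
#'
#' Z-scores the 40 features across the pooled table, builds a k-nearest-
#' neighbor graph (Euclidean), re-weights edges by shared-nearest-neighbor
#' Jaccard overlap with pruning, and extracts Louvain communities.
#' Communities are relabeled 1..K by decreasing size. Deterministic given
#' `seed`.
#'
#' @param features pooled [superpixel_features()] table (any extra non-feature
#'   columns are ignored).
#' @param knn neighbors per point; default `NULL` uses
#'   `max(20, round(sqrt(n)))`, which keeps the graph density per community
#'   roughly scale-free as the pooled superpixel count grows.
#' @param snn_prune minimum SNN Jaccard weight kept (default 1/15).
#' @param resolution Louvain resolution (default 0.4; values below 1 favor
#'   coarser communities, countering the tendency of modularity on kNN
#'   graphs to split large homogeneous groups).
#' @param seed integer RNG seed.
#' @return Integer habitat id per row of `features`, with attribute `K`.
#' @export
population_cluster <- function(features, knn = NULL, snn_prune = 1 / 15,
                               resolution = 0.4, seed = 1) {
  fcols <- intersect(as.vector(outer(STAT_NAMES, CHANNEL_NAMES, paste,
                                     sep = "_")), names(features))
  if (length(fcols) == 0)       # plain matrix input: use all columns
    X <- as.matrix(features)
  else
    X <- as.matrix(features[, fcols])
  n <- nrow(X)
  if (is.null(knn)) knn <- max(20L, as.integer(round(sqrt(n))))
  if (n < knn + 1)
    stop("population_cluster: need at least knn + 1 = ", knn + 1,
         " superpixels, got ", n)
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[sg == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  D <- as.matrix(stats::dist(Z))
  # kNN sets include the point itself (rank 0), as is conventional for SNN
  nn <- t(apply(D, 1, function(r) order(r)[seq_len(knn + 1)]))
  memb <- matrix(0L, n, n)
  memb[cbind(rep(seq_len(n), knn + 1), as.vector(nn))] <- 1L
  # shared-neighbor counts over all pairs, Jaccard re-weighting, pruning
  shared <- memb %*% t(memb)
  jac <- shared / (2 * (knn + 1) - shared)
  jac[jac < snn_prune] <- 0
  diag(jac) <- 0
  keep <- which(upper.tri(jac) & jac > 0, arr.ind = TRUE)
  w <- jac[keep]
  g <- igraph::graph_from_edgelist(keep, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, weights = w, resolution = resolution)
  lab <- igraph::membership(comm)
  sizes <- table(lab)
  remap <- stats::setNames(seq_along(sizes),
                           names(sort(sizes, decreasing = TRUE)))
  out <- as.integer(remap[as.character(lab)])
  attr(out, "K") <- length(sizes)
  out
}

#' Render a voxelwise habitat map from superpixel habitat ids
#'
#' @param spmap an [oversegment()] result.
#' @param habitat_ids integer habitat id per superpixel (length `spmap$n`).
#' @return A list of class `habitat_map`: `labels` (integer array, 0 outside
#'   tumor), `K` (number of habitat ids).
#' @export
render_habitat_map <- function(spmap, habitat_ids) {
  stopifnot(inherits(spmap, "superpixel_map"))
  habitat_ids <- as.integer(habitat_ids)
  if (length(habitat_ids) != spmap$n)
    stop("render_habitat_map: need one habitat id per superpixel (",
         spmap$n, "), got ", length(habitat_ids))
  if (any(is.na(habitat_ids)))
    stop("render_habitat_map: missing habitat id for superpixel(s) ",
         paste(which(is.na(habitat_ids)), collapse = ", "))
  lut <- c(0L, habitat_ids)          # index 1 = background label 0
  out <- array(lut[spmap$labels + 1L], dim = dim(spmap$labels))
  structure(list(labels = out, K = max(habitat_ids)), class = "habitat_map")
}

#' Match cluster labels between two partitions of the same items
#'
#' Exhaustive assignment (for K <= 8) maximizing overlap, used to align
#' habitat labels across runs or cohorts for consistency checks.
#'
#' @param a,b integer label vectors of equal length.
#' @return Named integer vector mapping labels of `a` onto labels of `b`.
#' @export
match_clusters <- function(a, b) {
  la <- sort(unique(a)); lb <- sort(unique(b))
  if (length(la) > 8) stop("match_clusters: more than 8 clusters")
  tab <- table(factor(a, la), factor(b, lb))
  k <- max(length(la), length(lb))
  # pad to square
  M <- matrix(0, k, k)
  M[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  perms <- permutations_of(k)
  best <- perms[[which.max(vapply(perms, function(p)
    sum(M[cbind(seq_len(k), p)]), numeric(1)))]]
  stats::setNames(c(lb, seq_len(k - length(lb)) + max(lb))[best][seq_along(la)],
                  la)
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in permutations_of(k - 1)) {
      q <- integer(k); q[1] <- i
      rest <- setdiff(seq_len(k), i)
      q[-1] <- rest[p]
      out[[length(out) + 1L]] <- q
    }
  }
  out
}
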