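# Imaging-subtype discovery: consensus clustering of per-patient MSI feature
# vectors with partition-around-medoids on the Spearman distance, CDF /
# delta-area selection of the cluster number, and medoid-based assignment of
# new patients.

#' Spearman distance between patients
#'
#' `d(a, b) = 1 - Spearman rank correlation` of the two patients' feature
#' vectors; 0 on the diagonal, symmetric, range \[0, 2\].
#'
#' @param features numeric matrix, patients x features (>= 3 features).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
spearman_distance <- function(features) {
  X <- as.matrix(features)
  if (ncol(X) < 3) stop("spearman_distance: need >= 3 features per patient")
  if (nrow(X) < 2) stop("spearman_distance: need >= 2 patients")
  const <- apply(X, 1, function(r) stats::sd(r) == 0)
  if (any(const))
    stop("spearman_distance: constant feature vector for patient(s) ",
         paste(rownames(X)[const] %||% which(const), collapse = ", "),
         " (ranks undefined)")
  D <- 1 - stats::cor(t(X), method = "spearman")
  diag(D) <- 0
  D
}

# scale each feature column to [0, 1] over the cohort (constant columns -> 0)
scale01 <- function(X, ranges = NULL) {
  X <- as.matrix(X)
  if (is.null(ranges)) {
    lo <- apply(X, 2, min)
    hi <- apply(X, 2, max)
  } else {
    lo <- ranges$lo; hi <- ranges$hi
  }
  span <- hi - lo
  span[span == 0] <- 1
  Z <- sweep(sweep(X, 2, lo), 2, span, "/")
  attr(Z, "ranges") <- list(lo = lo, hi = hi)
  Z
}

#' Consensus clustering of MSI feature vectors
#'
#' Repeats partition-around-medoids (PAM) clustering on patient subsamples
#' for each candidate k, records how often each patient pair co-clusters
#' among the resamples in which both were drawn, selects k from the CDF of
#' consensus values ([select_k_by_cdf()]), and derives final labels by PAM on
#' `1 - consensus` at the chosen k. Features are scaled to \[0, 1\] across
#' the cohort before the Spearman distance is computed. Deterministic given
#' `seed`.
#'
#' @param features numeric matrix, patients x features (e.g. `MSI1..MSI92`).
#' @param k_range candidate cluster numbers (default 2:5).
#' @param n_resamples subsamples per k (default 500).
#' @param subsample_fraction fraction of patients per subsample (default 0.8).
#' @param elbow_threshold relative delta-area threshold for k selection.
#' @param seed integer RNG seed.
#' @return Object of class `consensus_result`: `consensus` (list of n x n
#'   matrices per k), `cdf` (list), `area`, `delta_area`, `chosen_k`,
#'   `labels`, `medoids` (feature rows of the final medoid patients),
#'   `medoid_ids`, `scaling`, plus the call parameters.
#' @export
consensus_cluster <- function(features, k_range = 2:5, n_resamples = 500,
                              subsample_fraction = 0.8,
                              elbow_threshold = 0.10, seed = 1) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 2 * max(k_range))
    stop("consensus_cluster: need at least 2 * max(k_range) = ",
         2 * max(k_range), " patients, got ", n)
  if (min(k_range) < 2 || max(k_range) > n - 1)
    stop("consensus_cluster: k_range outside [2, n-1]")
  Z <- scale01(X)
  ranges <- attr(Z, "ranges")
  D <- spearman_distance(Z)
  m <- ceiling(subsample_fraction * n)
  consensus <- list()
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    co <- matrix(0, n, n)
    both <- matrix(0, n, n)
    set.seed(child_seed(seed, ki))
    for (r in seq_len(n_resamples)) {
      idx <- sort(sample.int(n, m))
      both[idx, idx] <- both[idx, idx] + 1
      cl <- cluster::pam(stats::as.dist(D[idx, idx]), k = k,
                         diss = TRUE, cluster.only = TRUE)
      for (g in unique(cl)) {
        gi <- idx[cl == g]
        co[gi, gi] <- co[gi, gi] + 1
      }
    }
    if (any(both == 0))
      warning("consensus_cluster: some patient pairs were never co-sampled ",
              "at k = ", k, " (increase n_resamples); their consensus is 0")
    M <- ifelse(both > 0, co / both, 0)
    diag(M) <- 1
    consensus[[as.character(k)]] <- M
  }
  sel <- select_k_by_cdf(consensus, elbow_threshold = elbow_threshold)
  chosen_k <- sel$chosen_k
  Mfin <- consensus[[as.character(chosen_k)]]
  fit <- cluster::pam(stats::as.dist(1 - Mfin), k = chosen_k, diss = TRUE)
  labels <- as.integer(fit$clustering)
  medoid_ids <- fit$id.med
  structure(list(consensus = consensus, cdf = sel$cdf, area = sel$area,
                 delta_area = sel$delta_area, chosen_k = chosen_k,
                 labels = labels, medoids = X[medoid_ids, , drop = FALSE],
                 medoid_ids = medoid_ids, scaling = ranges,
                 k_range = k_range, n_resamples = n_resamples,
                 subsample_fraction = subsample_fraction, seed = seed),
            class = "consensus_result")
}

#' Select the cluster number from consensus CDF curves
#'
#' Computes the empirical CDF of the upper-triangle consensus values per k
#' and the area under each CDF; the delta-area is `A(2)` for the smallest k
#' and the relative increment `(A(k) - A(k-1)) / A(k-1)` otherwise. The
#' chosen k is the largest candidate whose delta-area exceeds
#' `elbow_threshold` (ties and degenerate inputs fall back to the smallest
#' candidate, with a warning when all matrices are identical).
#'
#' @param consensus named list of consensus matrices, names = k.
#' @param elbow_threshold relative delta-area threshold (default 0.10).
#' @return List: `chosen_k`, `area`, `delta_area`, `cdf` (per-k list of
#'   `x`/`y` step-curve coordinates).
#' @export
select_k_by_cdf <- function(consensus, elbow_threshold = 0.10) {
  ks <- as.integer(names(consensus))
  if (length(ks) < 2) stop("select_k_by_cdf: need >= 2 candidate k")
  grid <- seq(0, 1, length.out = 101)
  cdf <- list(); area <- numeric(length(ks))
  for (i in seq_along(ks)) {
    v <- consensus[[i]][upper.tri(consensus[[i]])]
    y <- stats::ecdf(v)(grid)
    cdf[[as.character(ks[i])]] <- list(x = grid, y = y)
    area[i] <- sum(diff(grid) * (y[-1] + y[-length(y)]) / 2)  # trapezoid
  }
  delta <- numeric(length(ks))
  delta[1] <- area[1]
  if (length(ks) > 1)
    for (i in 2:length(ks))
      delta[i] <- (area[i] - area[i - 1]) / area[i - 1]
  names(delta) <- names(area) <- ks
  if (all(abs(delta[-1]) < 1e-12)) {
    warning("select_k_by_cdf: consensus identical across k; ",
            "returning smallest k")
    chosen <- ks[1]
  } else {
    ok <- delta > elbow_threshold
    chosen <- if (any(ok)) max(ks[ok]) else ks[1]
  }
  list(chosen_k = chosen, area = area, delta_area = delta, cdf = cdf)
}

#' Assign new patients to fitted subtypes
#'
#' Each new patient is assigned to the training medoid with the smallest
#' Spearman distance (after applying the training \[0, 1\] feature scaling);
#' ties break toward the lower cluster id.
#'
#' @param object a [consensus_cluster()] result.
#' @param new_features matrix of new patients x features; column names (if
#'   present) must match the training features.
#' @return Integer subtype labels.
#' @export
assign_subtype <- function(object, new_features) {
  stopifnot(inherits(object, "consensus_result"))
  X <- as.matrix(new_features)
  med <- object$medoids
  if (!is.null(colnames(X)) && !is.null(colnames(med)) &&
      !identical(colnames(X), colnames(med)))
    stop("assign_subtype: feature names do not match training features")
  Zm <- scale01(med, ranges = object$scaling)
  Zx <- scale01(X, ranges = object$scaling)
  k <- nrow(med)
  lab <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    d <- vapply(seq_len(k), function(j)
      1 - stats::cor(Zx[i, ], Zm[j, ], method = "spearman"), numeric(1))
    lab[i] <- which.min(d)          # which.min takes the first (lowest id)
  }
  lab
}

#' @export
predict.consensus_result <- function(object, newdata, ...) {
  assign_subtype(object, newdata)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> n = %d patients, k candidates %s\n",
              length(x$labels), paste(x$k_range, collapse = ", ")))
  cat(sprintf("  chosen k = %d  (delta-area: %s)\n", x$chosen_k,
              paste(sprintf("%s=%.3f", names(x$delta_area), x$delta_area),
                    collapse = ", ")))
  cat("  cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Plot consensus CDF curves
#'
#' @param x a [consensus_cluster()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.consensus_result <- function(x, ...) {
  ks <- names(x$cdf)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "consensus value", ylab = "CDF",
                 main = "Consensus CDF by k", ...)
  for (i in seq_along(ks))
    graphics::lines(x$cdf[[i]]$x, x$cdf[[i]]$y, col = i, lwd = 2)
  graphics::legend("bottomright", legend = paste("k =", ks),
                   col = seq_along(ks), lwd = 2, bty = "n")
  invisible(x)
}

#' Name subtype risk levels from an outcome surrogate
#'
#' Ranks fitted clusters by a per-cluster summary (by default the mean
#' percentage volume of the dense high-uptake subregion, `MSI55`, rising
#' with risk) and returns `low` / `intermediate` / `high` names. Stored as
#' metadata only; clustering itself is unsupervised.
#'
#' @param result a [consensus_cluster()] result with `chosen_k = 3`.
#' @param features the feature matrix used for fitting.
#' @param surrogate column name to rank by (default `"MSI55"`, the
#'   percentage volume of SR7).
#' @return Character vector of risk names per patient.
#' @export
name_risk_levels <- function(result, features, surrogate = "MSI55") {
  stopifnot(inherits(result, "consensus_result"))
  if (result$chosen_k != 3)
    stop("name_risk_levels: risk naming defined for k = 3, got k = ",
         result$chosen_k)
  X <- as.matrix(features)
  sv <- if (surrogate %in% colnames(X)) X[, surrogate] else
    stop("name_risk_levels: surrogate column not found")
  means <- tapply(sv, result$labels, mean)
  ord <- order(means)                 # ascending surrogate = descending risk?
  nm <- character(3)
  nm[as.integer(names(means))[ord]] <- c("low", "intermediate", "high")
  nm[result$labels]
}
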