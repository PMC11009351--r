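test_that("Spearman distance honors rank invariance and reversal", {
  set.seed(1)
  x <- runif(20)
  X <- rbind(a = x,
             b = exp(3 * x) + 5,          # strictly monotone transform
             c = -x,                       # exact rank reversal
             d = runif(20))
  D <- spearman_distance(X)
  expect_equal(D["a", "a"], 0)
  expect_equal(D["a", "b"], 0, tolerance = 1e-12)
  expect_equal(D["a", "c"], 2, tolerance = 1e-12)
  expect_identical(D, t(D))
  expect_true(all(D >= 0 & D <= 2))
  Xc <- rbind(a = x, flat = rep(1, 20))
  expect_error(spearman_distance(Xc), "flat")
  expect_error(spearman_distance(X[, 1:2]), ">= 3 features")
})

test_that("consensus matrix separates planted groups into clean blocks", {
  pb <- planted_blobs(n_per = 20, n_groups = 3, n_feat = 12, shift = 5,
                      seed = 4)
  rownames(pb$X) <- paste0("P", seq_len(nrow(pb$X)))
  cc <- consensus_cluster(pb$X, k_range = 2:4, n_resamples = 200, seed = 9)
  M3 <- cc$consensus[["3"]]
  within <- M3[outer(pb$truth, pb$truth, `==`) & upper.tri(M3)]
  between <- M3[outer(pb$truth, pb$truth, `!=`) & upper.tri(M3)]
  expect_gte(mean(within >= 0.95), 0.95)
  expect_true(all(between <= 0.05))
  expect_equal(cc$chosen_k, 3)
  expect_equal(adjusted_rand(cc$labels, pb$truth), 1)
  # structural invariants
  for (M in cc$consensus) {
    expect_identical(M, t(M))
    expect_true(all(diag(M) == 1))
    expect_true(all(M >= 0 & M <= 1))
  }
})

test_that("duplicated patients always co-cluster and seeds reproduce", {
  pb <- planted_blobs(n_per = 12, n_groups = 2, n_feat = 10, shift = 6,
                      seed = 2)
  X2 <- rbind(pb$X, pb$X[1:2, ])            # rows 25/26 duplicate rows 1/2
  cc <- consensus_cluster(X2, k_range = 2:3, n_resamples = 100, seed = 5)
  n <- nrow(pb$X)
  expect_equal(cc$consensus[[1]][1, n + 1], 1)
  expect_equal(cc$consensus[[1]][2, n + 2], 1)
  cc2 <- consensus_cluster(X2, k_range = 2:3, n_resamples = 100, seed = 5)
  expect_identical(cc$consensus, cc2$consensus)
  expect_identical(cc$labels, cc2$labels)
  expect_error(consensus_cluster(pb$X[1:5, ], k_range = 2:5), "at least")
})

test_that("CDF-based k selection finds the planted block count", {
  n <- 30
  block <- function(k, noise) {
    g <- rep(seq_len(k), length.out = n)
    M <- (outer(g, g, `==`)) * 1
    set.seed(42 + k)
    up <- upper.tri(M)
    M[up] <- pmin(1, pmax(0, M[up] + rnorm(sum(up), 0, noise)))
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    diag(M) <- 1
    M
  }
  cons <- list(`2` = block(2, 0.25), `3` = block(3, 0.02),
               `4` = block(4, 0.30), `5` = block(5, 0.32))
  sel <- select_k_by_cdf(cons)
  expect_equal(sel$chosen_k, 3)
  # all-ones consensus: CDF is a unit step at 1, area ~ 0
  ones <- matrix(1, 10, 10)
  sel2 <- suppressWarnings(select_k_by_cdf(list(`2` = ones, `3` = ones)))
  cdf2 <- sel2$cdf[["2"]]
  expect_true(all(cdf2$y[cdf2$x < 1] == 0))
  expect_equal(cdf2$y[length(cdf2$y)], 1)
  # trapezoid area equals the closed form for a two-point CDF:
  # values {0 (p), 1 (1-p)} -> area = p (up to grid resolution)
  M <- matrix(0, 4, 4); M[1, 2] <- M[2, 1] <- 1; diag(M) <- 1
  # upper triangle: one 1 and five 0s -> CDF jumps to 5/6 at 0
  sel3 <- suppressWarnings(select_k_by_cdf(list(`2` = M, `3` = M)))
  expect_equal(unname(sel3$area[1]), 5 / 6, tolerance = 0.01)
})

test_that("degenerate identical consensus matrices fall back to smallest k", {
  M <- diag(10) * 0 + 0.5; diag(M) <- 1
  expect_warning(sel <- select_k_by_cdf(list(`2` = M, `3` = M, `4` = M)),
                 "identical")
  expect_equal(sel$chosen_k, 2)
})

test_that("subtype assignment is rank-invariant and recovers planted cohorts", {
  pb <- planted_blobs(n_per = 20, n_groups = 3, n_feat = 12, shift = 5,
                      seed = 6)
  cc <- consensus_cluster(pb$X, k_range = 2:4, n_resamples = 150, seed = 3)
  expect_equal(cc$chosen_k, 3)
  # each training medoid maps to its own cluster
  med_lab <- assign_subtype(cc, cc$medoids)
  expect_equal(med_lab, cc$labels[cc$medoid_ids])
  # monotone transform of a medoid keeps its cluster
  tr <- 2 * cc$medoids[1, ] + 1
  expect_equal(assign_subtype(cc, rbind(tr)), med_lab[1])
  # fresh validation cohort drawn around the same planted centers
  pv <- planted_blobs(n_per = 15, n_groups = 3, n_feat = 12, shift = 5,
                      seed = 60, centers = pb$centers)
  lab <- assign_subtype(cc, pv$X)
  expect_gte(adjusted_rand(lab, pv$truth), 0.9)
  bad <- pv$X; colnames(bad) <- paste0("f", seq_len(ncol(bad)))
  colnames(cc$medoids) <- paste0("g", seq_len(ncol(cc$medoids)))
  expect_error(assign_subtype(cc, bad), "feature names")
})

test_that("PAM returns exactly k non-empty clusters on distinct points", {
  set.seed(8)
  X <- matrix(rnorm(40 * 6), 40, 6)
  D <- spearman_distance(X)
  for (k in 2:5) {
    cl <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE,
                       cluster.only = TRUE)
    expect_equal(length(unique(cl)), k)
  }
})
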