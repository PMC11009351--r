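make_stack <- function(seed = 1, dims = c(12, 12, 12)) {
  set.seed(seed)
  m <- array(0L, dims); m[3:10, 3:10, 3:10] <- 1L
  mk <- tumor_mask(m)
  ch <- lapply(1:4, function(i)
    image_volume(array(runif(prod(dims)), dims), modality = "NORMALIZED"))
  list(mask = mk, ch = ch)
}

test_that("channel fusion sums scaled channels and validates grids", {
  s <- make_stack()
  z <- image_volume(array(0, dim(s$mask$data)), modality = "NORMALIZED")
  st0 <- fuse_channels(z, z, z, z, s$mask)
  expect_true(all(st0$composite$data == 0))
  one <- image_volume(array(1, dim(s$mask$data)), modality = "NORMALIZED")
  st1 <- fuse_channels(one, z, z, z, s$mask)
  expect_true(all(st1$composite$data[s$mask$data == 1] == 1))
  # composite equals an independently recomputed elementwise sum
  st <- fuse_channels(s$ch[[1]], s$ch[[2]], s$ch[[3]], s$ch[[4]], s$mask,
                      entropy_bins = 2)  # log2(2)=1: entropy channels as-is
  want <- clip(s$ch[[1]]$data, 0, 1) + clip(s$ch[[2]]$data, 0, 1) +
    clip(s$ch[[3]]$data, 0, 1) + clip(s$ch[[4]]$data, 0, 1)
  expect_equal(st$composite$data, want)
  expect_true(all(st$composite$data >= 0 & st$composite$data <= 4))
  small <- tumor_mask(array(c(1, rep(0, 7)), c(2, 2, 2)))
  expect_error(fuse_channels(z, z, z, z, small), "grid mismatch")
})

test_that("oversegmentation partitions the mask exactly", {
  cs <- generate_phantom(spec4(grid = c(32L, 32L, 32L), radii = c(9, 7, 6)),
                         1, seed = 3)
  pp <- preprocess_case(cs$ct, cs$suv, cs$mask)
  st <- fuse_channels(pp$ct_norm, pp$ct_entropy, pp$suv_norm,
                      pp$suv_entropy, pp$mask)
  sp <- oversegment(st, seed = 11)
  expect_true(all((sp$labels > 0) == (st$mask$data == 1)))   # exact partition
  expect_setequal(unique(sp$labels[sp$labels > 0]), seq_len(sp$n))
  sizes <- table(sp$labels[sp$labels > 0])
  expect_true(all(sizes >= 10))                              # min_size
  # determinism
  sp2 <- oversegment(st, seed = 11)
  expect_identical(sp$labels, sp2$labels)
  # single-superpixel degenerate case
  sp1 <- oversegment(st, n_superpixels = 1)
  expect_equal(sp1$n, 1)
  expect_true(all(sp1$labels[st$mask$data == 1] == 1))
})

test_that("superpixel count lands near target for a 1000-voxel tumor", {
  dims <- c(16, 16, 16)
  m <- array(0L, dims); m[3:12, 3:12, 3:12] <- 1L   # 1000 voxels
  mk <- tumor_mask(m)
  set.seed(2)
  ch <- lapply(1:4, function(i)
    image_volume(array(runif(prod(dims)), dims), modality = "NORMALIZED"))
  st <- fuse_channels(ch[[1]], ch[[2]], ch[[3]], ch[[4]], mk)
  sp <- suppressWarnings(oversegment(st, target_size = 100, seed = 5))
  expect_gte(sp$n, 8)
  expect_lte(sp$n, 15)
})

test_that("first-order features match a brute-force recomputation", {
  s <- make_stack(seed = 4)
  st <- fuse_channels(s$ch[[1]], s$ch[[2]], s$ch[[3]], s$ch[[4]], s$mask,
                      entropy_bins = 2)
  sp <- suppressWarnings(oversegment(st, n_superpixels = 4, seed = 2))
  ft <- superpixel_features(st, sp)
  expect_equal(sum(grepl("_", names(ft))), 40 + 2)  # 40 features (+ids)
  fcols <- setdiff(names(ft), c("patient_id", "superpixel_id", "size"))
  expect_length(fcols, 40)
  # oracle: straight-line recomputation for one superpixel and channel
  idx <- which(sp$labels == 2)
  x <- st$channels$suv$data[idx]
  n <- length(x)
  expect_equal(ft$mean_suv[2], mean(x))
  expect_equal(ft$median_suv[2], median(x))
  expect_equal(ft$q2_suv[2], ft$median_suv[2])      # q2 == median, both kept
  expect_equal(ft$q1_suv[2], quantile(x, .25, names = FALSE))
  expect_equal(ft$iqr_suv[2],
               quantile(x, .75, names = FALSE) - quantile(x, .25, names = FALSE))
  expect_equal(ft$sd_suv[2], sd(x))
  expect_equal(ft$variance_suv[2], var(x))
  expect_equal(ft$energy_suv[2], sum(x^2))
  m3 <- sum((x - mean(x))^3) / n
  g1 <- m3 / (sum((x - mean(x))^2) / n)^1.5
  expect_equal(ft$skewness_suv[2], g1 * sqrt(n * (n - 1)) / (n - 2))
})

test_that("degenerate (constant) superpixels give finite convention values", {
  dims <- c(6, 6, 6)
  m <- array(0L, dims); m[2:5, 2:5, 2:5] <- 1L
  mk <- tumor_mask(m)
  cv <- image_volume(array(0.5, dims), modality = "NORMALIZED")
  st <- fuse_channels(cv, cv, cv, cv, mk, entropy_bins = 2)
  sp <- oversegment(st, n_superpixels = 1)
  ft <- superpixel_features(st, sp)
  expect_equal(ft$variance_ct, 0)
  expect_equal(ft$sd_ct, 0)
  expect_equal(ft$iqr_ct, 0)
  expect_equal(ft$skewness_ct, 0)
  expect_equal(ft$kurtosis_ct, 0)
  expect_true(all(is.finite(as.matrix(ft[, -(1:3)]))))
})

test_that("population clustering recovers well-separated planted blobs", {
  pb <- planted_blobs(n_per = 60, n_groups = 2, n_feat = 5, shift = 10,
                      seed = 13)
  lab <- population_cluster(pb$X, knn = 15, seed = 3)
  expect_equal(attr(lab, "K"), 2)
  expect_equal(adjusted_rand(lab, pb$truth), 1)
  # determinism
  lab2 <- population_cluster(pb$X, knn = 15, seed = 3)
  expect_identical(as.integer(lab), as.integer(lab2))
  expect_error(population_cluster(pb$X[1:10, ], knn = 15), "at least")
})

test_that("duplicating rows leaves per-point community assignment invariant", {
  pb <- planted_blobs(n_per = 20, n_groups = 3, n_feat = 6, shift = 8,
                      seed = 17)
  lab1 <- population_cluster(pb$X, knn = 10, seed = 5)
  lab2 <- population_cluster(rbind(pb$X, pb$X), knn = 10, seed = 5)
  n <- nrow(pb$X)
  expect_equal(adjusted_rand(lab2[1:n], lab1), 1)
  expect_equal(adjusted_rand(lab2[1:n], lab2[(n + 1):(2 * n)]), 1)
})

test_that("habitat map rendering relabels voxels and conserves counts", {
  cs <- generate_phantom(spec4(grid = c(32L, 32L, 32L), radii = c(9, 7, 6)),
                         1, seed = 6)
  pp <- preprocess_case(cs$ct, cs$suv, cs$mask)
  st <- fuse_channels(pp$ct_norm, pp$ct_entropy, pp$suv_norm,
                      pp$suv_entropy, pp$mask)
  sp <- oversegment(st, seed = 2)
  ids <- rep_len(1:3, sp$n)
  hm <- render_habitat_map(sp, ids)
  expect_true(all(hm$labels[st$mask$data == 0] == 0))
  sp_sizes <- table(sp$labels[sp$labels > 0])
  for (h in 1:3)
    expect_equal(sum(hm$labels == h),
                 sum(sp_sizes[which(ids == h)]))
  # single superpixel uniform id
  sp1 <- oversegment(st, n_superpixels = 1)
  hm1 <- render_habitat_map(sp1, 3L)
  expect_true(all(hm1$labels[st$mask$data == 1] == 3))
  expect_error(render_habitat_map(sp, ids[-1]), "one habitat id")
  expect_error(render_habitat_map(sp, c(NA, ids[-1])), "missing")
})

test_that("cluster matching aligns permuted labellings", {
  set.seed(1)
  a <- sample(1:3, 100, TRUE)
  b <- c(2L, 3L, 1L)[a]            # permuted copy
  mp <- match_clusters(a, b)
  expect_equal(unname(mp[as.character(1:3)]), c(2L, 3L, 1L))
})
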