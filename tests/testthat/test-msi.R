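test_that("border labelling matches hand enumeration and morphology", {
  m <- array(0L, c(3, 3, 3)); m[2, 2, 2] <- 1L
  h <- array(0L, c(3, 3, 3)); h[2, 2, 2] <- 1L
  lb <- add_border_label(h, m)
  expect_equal(lb[2, 2, 2], 1L)
  expect_equal(sum(lb == 0L, na.rm = TRUE), 26)   # all 26 surrounding voxels
  expect_true(all(is.na(lb) == FALSE))            # 3^3 grid fully labeled
  # tumor and border are disjoint; morphology oracle: dilate(mask) - mask
  set.seed(3)
  m2 <- array(0L, c(8, 8, 8)); m2[3:6, 3:6, 3:6] <- 1L
  h2 <- array(0L, c(8, 8, 8)); h2[m2 == 1L] <- sample(1:3, 64, TRUE)
  lb2 <- add_border_label(h2, m2)
  border_set <- which(!is.na(lb2) & lb2 == 0L)
  expect_length(intersect(border_set, which(m2 == 1L)), 0)
  oracle <- which(dilate26(m2) == 1L & m2 == 0L)
  expect_setequal(border_set, oracle)
  # a mask filling the grid has no border
  full <- array(1L, c(3, 3, 3))
  expect_error(add_border_label(full, full), "no border")
  expect_error(add_border_label(array(0L, dim(m)), m), "unlabeled")
})

test_that("two-voxel volume yields the hand-counted MSI matrix", {
  lab <- array(c(1L, 2L), c(1, 1, 2))
  M <- build_msi_matrix(lab, K = 2)
  expect_equal(M["SR1", "SR2"], 1)
  expect_equal(M["SR2", "SR1"], 1)
  expect_equal(sum(M), 2)
})

test_that("uniform single-label tumor touches only itself and the border", {
  m <- array(0L, c(6, 6, 6)); m[2:5, 2:5, 2:5] <- 1L
  h <- m                                     # all label 1
  M <- build_msi_matrix(add_border_label(h, m), K = 1)
  expect_gt(M["SR1", "SR1"], 0)
  expect_gt(M["SR1", "border"], 0)
  expect_equal(M["border", "border"], 0)
})

test_that("MSI matrix is symmetric and matches the brute-force oracle", {
  for (seed in 1:10) {
    dims <- c(sample(3:6, 1), sample(3:6, 1), sample(3:6, 1))
    lab <- random_label_volume(dims, K = 3, seed = seed)
    labNA <- lab
    labNA[sample(length(lab), 5)] <- NA      # some voxels outside
    M <- build_msi_matrix(labNA, K = 3)
    bare <- unclass(M)
    attributes(bare) <- list(dim = dim(bare))
    expect_identical(bare, msi_oracle(labNA, K = 3),
                     info = paste("seed", seed))
    expect_identical(bare, t(bare))
  }
})

test_that("second-order statistics reproduce hand-derived cases", {
  u <- matrix(1, 2, 2)                       # uniform P = 1/4
  so <- msi_second_order(u)
  expect_equal(unname(so["contrast"]), 0.5)
  expect_equal(unname(so["homogeneity"]), 0.75)
  expect_equal(unname(so["energy"]), 0.25)
  expect_equal(unname(so["correlation"]), 0)
  # point mass on one diagonal cell
  pm <- matrix(0, 3, 3); pm[2, 2] <- 7
  expect_warning(so2 <- msi_second_order(pm), "degenerate")
  expect_equal(unname(so2["contrast"]), 0)
  expect_equal(unname(so2["homogeneity"]), 1)
  expect_equal(unname(so2["energy"]), 1)
  # symmetry: P and t(P) identical outputs
  set.seed(2)
  A <- matrix(rpois(16, 5), 4, 4); A <- A + t(A)
  expect_equal(msi_second_order(A), msi_second_order(t(A)))
  expect_error(msi_second_order(matrix(0, 2, 2)), "empty")
})

test_that("feature vector has 92 canonical entries for K = 8", {
  cs <- generate_phantom(spec8_small(), "low", seed = 12)
  lb <- add_border_label(cs$truth_labels, cs$mask)
  M <- build_msi_matrix(lb, K = 8)
  fv <- extract_msi_features(M, cs$truth_labels, K = 8)
  expect_length(fv, 92)
  expect_identical(names(fv), paste0("MSI", 1:92))
  expect_equal(sum(fv[49:56]), 100, tolerance = 1e-6)
  expect_true(all(fv[49:56] >= 0 & fv[49:56] <= 100))
  expect_true(all(fv[57:92] >= 0 & fv[57:92] <= 1))
  expect_length(attr(fv, "description"), 92)
})

test_that("single-habitat tumor collapses the interaction features", {
  m <- array(0L, c(6, 6, 6)); m[2:5, 2:5, 2:5] <- 1L
  M <- build_msi_matrix(add_border_label(m, m), K = 8)
  fv <- extract_msi_features(M, m, K = 8)
  expect_equal(unname(fv["MSI5"]), 64)        # SR1 voxel count
  expect_equal(unname(fv["MSI49"]), 100)      # 100% volume in SR1
  expect_true(all(fv[paste0("MSI", 21:48)] == 0))
  expect_true(all(fv[paste0("MSI", 65:92)] == 0))
})

test_that("habitat relabelling permutes per-subregion features consistently", {
  cs <- generate_phantom(spec8_small(), "high", seed = 14)
  perm <- c(3L, 1L, 2L, 5L, 4L, 8L, 6L, 7L)   # habitat h -> perm[h]
  relab <- cs$truth_labels
  relab[cs$truth_labels > 0] <- perm[cs$truth_labels[cs$truth_labels > 0]]
  f1 <- extract_msi_features(
    build_msi_matrix(add_border_label(cs$truth_labels, cs$mask), K = 8),
    cs$truth_labels, K = 8)
  f2 <- extract_msi_features(
    build_msi_matrix(add_border_label(relab, cs$mask), K = 8), relab, K = 8)
  # volumes and border interactions permute exactly
  expect_equal(unname(f2[4 + perm]), unname(f1[4 + 1:8]))        # MSI5-12
  expect_equal(unname(f2[12 + perm]), unname(f1[12 + 1:8]))      # MSI13-20
  expect_equal(unname(f2[48 + perm]), unname(f1[48 + 1:8]))      # MSI49-56
  # pairwise block permutes as unordered pairs
  pairs <- which(upper.tri(matrix(0, 8, 8)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), ]
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  idx2 <- match(key(perm[pairs[, 1]], perm[pairs[, 2]]),
                key(pairs[, 1], pairs[, 2]))
  expect_equal(unname(f2[20 + idx2]), unname(f1[20 + seq_len(28)]))
})

test_that("feature vector equals an independent recomputation from labels", {
  cs <- generate_phantom(spec8_small(), "intermediate", seed = 15)
  lb <- add_border_label(cs$truth_labels, cs$mask)
  M <- build_msi_matrix(lb, K = 8)
  fv <- extract_msi_features(M, cs$truth_labels, K = 8)
  oracleM <- msi_oracle(lb, K = 8)
  expect_equal(unname(fv[paste0("MSI", 5:12)]),
               as.numeric(tabulate(cs$truth_labels[cs$truth_labels > 0], 8)))
  expect_equal(unname(fv[paste0("MSI", 13:20)]), oracleM[2:9, 1])
  k <- 21
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(unname(fv[paste0("MSI", k)]), oracleM[i + 1, j + 1])
    k <- k + 1
  }
  tot <- sum(oracleM[upper.tri(oracleM)])
  expect_equal(unname(fv["MSI57"]), oracleM[2, 1] / tot)
})

test_that("conventional PET metrics match hand arithmetic", {
  dims <- c(10, 10, 10)
  m <- array(0L, dims); m[1:10, 1:10, 1:10][1:1000] <- 1L
  mk <- tumor_mask(m)
  suv <- image_volume(array(4, dims), modality = "SUV")
  pm <- conventional_pet_metrics(suv, mk, mtv_threshold = 2.5)
  expect_equal(pm$mtv, 1.0)        # 1000 voxels x 1 mm3 = 1 mL
  expect_equal(pm$tlg, 4.0)
  expect_equal(pm$suv_max, 4.0)
  expect_equal(pm$tumor_volume, 1.0)
  # threshold above SUVmax empties the MTV
  pm2 <- conventional_pet_metrics(suv, mk, mtv_threshold = 10)
  expect_equal(pm2$mtv, 0)
  expect_equal(pm2$tlg, 0)
  set.seed(4)
  rv <- image_volume(array(runif(prod(dims), 0, 12), dims), modality = "SUV")
  pm3 <- conventional_pet_metrics(rv, mk)
  expect_lte(pm3$suv_mean, pm3$suv_max)
  expect_equal(pm3$tlg, pm3$mtv * mean(rv$data[m == 1L & rv$data >= 2.5]),
               tolerance = 1e-6)
})
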