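# Shared fixtures, all built in code at test time.

# 4-habitat phantom spec with distinct intensity and texture phenotypes and
# low noise relative to the between-habitat separation; used for end-to-end
# habitat recovery.
spec4 <- function(grid = c(48L, 48L, 48L), radii = c(14, 11, 10)) {
  phantom_spec(
    grid_shape = grid, tumor_radii = radii,
    habitat_means = cbind(ct = c(-600, 20, -450, 60),
                          suv = c(1, 1.5, 6, 11)),
    habitat_sds = cbind(ct = c(40, 15, 70, 25),
                        suv = c(0.2, 0.15, 0.9, 0.5)),
    subtype_mixtures = matrix(0.25, 1, 4,
                              dimnames = list("only", NULL)))
}

# small default-phenotype spec (8 habitats, 3 subtype mixtures) at reduced
# grid scale, for cohort-level tests
spec8_small <- function() {
  phantom_spec(grid_shape = c(48L, 48L, 48L), tumor_radii = c(14, 11, 10))
}

# random label volume with values in 0..K over a dims grid (0 = outside)
random_label_volume <- function(dims, K, seed) {
  set.seed(seed)
  arr <- array(sample(0:K, prod(dims), replace = TRUE), dim = dims)
  arr
}

# brute-force MSI oracle: triple loop over voxels and 26 neighbors
msi_oracle <- function(labeled, K) {
  d <- dim(labeled)
  counts <- matrix(0, K + 1, K + 1)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    lv <- labeled[x, y, z]
    if (is.na(lv)) next
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] ||
          zz < 1 || zz > d[3]) next
      lu <- labeled[xx, yy, zz]
      if (is.na(lu)) next
      if (lv == 0 && lu == 0) next
      counts[lv + 1, lu + 1] <- counts[lv + 1, lu + 1] + 1
    }
  }
  counts
}

# brute-force local entropy oracle: per-voxel histogram over the ball
entropy_oracle <- function(data, radius, n_bins) {
  d <- dim(data)
  rng <- range(data)
  w <- diff(rng) / n_bins
  out <- array(0, dim = d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    vals <- c()
    for (dx in -radius:radius) for (dy in -radius:radius)
      for (dz in -radius:radius) {
        if (dx^2 + dy^2 + dz^2 > radius^2) next
        xx <- x + dx; yy <- y + dy; zz <- z + dz
        if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] ||
            zz < 1 || zz > d[3]) next
        vals <- c(vals, data[xx, yy, zz])
      }
    b <- pmin(n_bins, floor((vals - rng[1]) / w) + 1)
    p <- tabulate(b, n_bins)
    p <- p / sum(p)
    p <- p[p > 0]
    out[x, y, z] <- -sum(p * log2(p))
  }
  out
}

# planted Gaussian feature blobs: n_per points per group, each group centred
# on its own random feature profile of magnitude `shift` (in units of the
# unit within-group sd), so groups differ in both location and rank pattern
planted_blobs <- function(n_per, n_groups, n_feat, shift, seed,
                          centers = NULL) {
  set.seed(seed)
  if (is.null(centers))
    centers <- matrix(stats::rnorm(n_groups * n_feat, sd = shift),
                      n_groups, n_feat)
  X <- do.call(rbind, lapply(seq_len(n_groups), function(g)
    matrix(stats::rnorm(n_per * n_feat), n_per, n_feat) +
      matrix(centers[g, ], n_per, n_feat, byrow = TRUE)))
  list(X = X, truth = rep(seq_len(n_groups), each = n_per),
       centers = centers)
}
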