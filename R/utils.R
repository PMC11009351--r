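# Low-level voxel-grid helpers shared by the preprocessing, habitat and MSI
# stages. All use 26-connectivity (face, edge or corner contact) unless noted.

# 26-neighborhood offsets as a 26 x 3 integer matrix
offsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# For one (dx,dy,dz) offset, linear indices of all in-bounds (center, neighbor)
# voxel pairs of a grid with dims `d`.
offset_pairs <- function(d, off) {
  lo <- pmax(1L, 1L - off)
  hi <- pmin(d, d - off)
  if (any(hi < lo)) return(list(center = integer(0), nb = integer(0)))
  xr <- lo[1]:hi[1]; yr <- lo[2]:hi[2]; zr <- lo[3]:hi[3]
  idx <- array(seq_len(prod(d)), dim = d)
  list(center = as.vector(idx[xr, yr, zr, drop = FALSE]),
       nb = as.vector(idx[xr + off[1], yr + off[2], zr + off[3],
                          drop = FALSE]))
}

# linear index -> integer coords (n x 3) and back, for dims d
lin_to_coord <- function(i, d) {
  i0 <- i - 1L
  x <- i0 %% d[1]
  y <- (i0 %/% d[1]) %% d[2]
  z <- i0 %/% (d[1] * d[2])
  cbind(x + 1L, y + 1L, z + 1L)
}

coord_to_lin <- function(xyz, d) {
  (xyz[, 3] - 1L) * (d[1] * d[2]) + (xyz[, 2] - 1L) * d[1] + xyz[, 1]
}

# Connected-component labelling of a label array under 26-connectivity.
# Voxels with value `background` are ignored; two voxels join a component only
# if they carry the same label and touch by face, edge or corner. Returns an
# integer array with dense component ids 1..C (0 on background).
label_components <- function(labels, background = 0L) {
  d <- dim(labels)
  lab <- as.integer(labels)
  n <- prod(d)
  comp <- integer(n)
  offs <- offsets26()
  todo <- which(lab != background & !is.na(lab))
  cur <- 0L
  seen <- logical(n)
  for (start in todo) {
    if (seen[start]) next
    cur <- cur + 1L
    target <- lab[start]
    frontier <- start
    seen[start] <- TRUE
    comp[start] <- cur
    while (length(frontier)) {
      xyz <- lin_to_coord(frontier, d)
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        nb <- cbind(xyz[, 1] + offs[o, 1], xyz[, 2] + offs[o, 2],
                    xyz[, 3] + offs[o, 3])
        ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
              nb[, 2] >= 1L & nb[, 2] <= d[2] &
              nb[, 3] >= 1L & nb[, 3] <= d[3]
        if (!any(ok)) next
        nl <- coord_to_lin(nb[ok, , drop = FALSE], d)
        nl <- nl[!seen[nl] & lab[nl] == target & !is.na(lab[nl])]
        if (length(nl)) {
          nl <- unique(nl)
          seen[nl] <- TRUE
          comp[nl] <- cur
          nxt <- c(nxt, nl)
        }
      }
      frontier <- nxt
    }
  }
  array(comp, dim = d)
}

# binary dilation by one voxel under 26-connectivity
dilate26 <- function(mask) {
  d <- dim(mask)
  m <- array(as.integer(mask != 0), dim = d)
  out <- m
  offs <- offsets26()
  for (o in seq_len(nrow(offs))) {
    p <- offset_pairs(d, offs[o, ])
    hit <- p$nb[m[p$center] == 1L]
    out[hit] <- 1L
  }
  out
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# deterministic child seed derived from a base seed (kept < 2^31)
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Adjusted Rand index between two partitions
#'
#' Thin wrapper around [mclust::adjustedRandIndex()] for comparing recovered
#' habitat or subtype labels against planted ground truth.
#'
#' @param a,b label vectors of equal length.
#' @return Scalar ARI in \[-1, 1\].
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}
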