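# Harmonization of multi-site CT and PET volumes: lung windowing, body-weight
# SUV, isotropic resampling and local entropy maps. These four channels feed
# the habitat discovery stage.

#' Lung-window normalization of a CT volume
#'
#' Linearly maps Hounsfield units inside the window
#' `[center - width/2, center + width/2]` to \[0, 1\], clipping outside.
#'
#' @param vol CT [image_volume()] in Hounsfield units.
#' @param center window centre in HU (default -400, standard lung window).
#' @param width window width in HU (default 1500); must be > 0.
#' @return An `image_volume` with modality `NORMALIZED`, values in \[0, 1\].
#' @export
ct_lung_window <- function(vol, center = -400, width = 1500) {
  stopifnot(is_image_volume(vol))
  if (width <= 0) stop("ct_lung_window: width must be > 0")
  lo <- center - width / 2
  out <- clip((vol$data - lo) / width, 0, 1)
  image_volume(out, vol$spacing, vol$origin, modality = "NORMALIZED")
}

#' Body-weight standardized uptake value (SUVbw)
#'
#' `SUV = activity / (injected_dose / body_weight)`, assuming tissue density
#' 1 g/mL, so activity in Bq/mL, dose in Bq and weight in g give a unitless
#' SUV.
#'
#' @param pet PET [image_volume()] of activity concentration (Bq/mL).
#' @param injected_dose injected dose in Bq (> 0).
#' @param body_weight patient body weight in g (> 0).
#' @return An `image_volume` with modality `SUV`.
#' @export
compute_suv <- function(pet, injected_dose, body_weight) {
  stopifnot(is_image_volume(pet))
  if (injected_dose <= 0) stop("compute_suv: injected_dose must be > 0")
  if (body_weight <= 0) stop("compute_suv: body_weight must be > 0")
  if (any(pet$data < 0))
    stop("compute_suv: negative activity in ", sum(pet$data < 0), " voxel(s)")
  suv <- pet$data / (injected_dose / body_weight)
  image_volume(suv, pet$spacing, pet$origin, modality = "SUV")
}

#' Resample a volume to isotropic spacing
#'
#' Trilinear interpolation for intensity volumes, nearest-neighbour for masks
#' and label maps. The output grid is anchored at the input origin; the
#' physical extent is preserved to within one voxel.
#'
#' @param vol an [image_volume()].
#' @param target_spacing isotropic target spacing in mm (> 0), default 1.
#' @param interpolation `"linear"` or `"nearest"`; defaults to `"nearest"`
#'   for `MASK`/`LABEL` modalities and `"linear"` otherwise.
#' @return An `image_volume` with spacing `target_spacing` on all axes.
#' @export
resample_isotropic <- function(vol, target_spacing = 1,
                               interpolation = NULL) {
  stopifnot(is_image_volume(vol))
  if (target_spacing <= 0)
    stop("resample_isotropic: target_spacing must be > 0")
  if (is.null(interpolation))
    interpolation <- if (vol$modality %in% c("MASK", "LABEL"))
      "nearest" else "linear"
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  d <- dim(vol$data)
  # voxel-centre positions: origin + (i-1)*spacing; keep the same extent
  n_out <- pmax(1L, as.integer(floor((d - 1L) * vol$spacing /
                                       target_spacing + 1e-9)) + 1L)
  if (all(abs(vol$spacing - target_spacing) < 1e-12)) {
    out <- vol$data                     # identity grid
  } else {
    # fractional input coordinates of each output voxel centre, per axis
    u <- lapply(1:3, function(ax)
      (seq_len(n_out[ax]) - 1) * target_spacing / vol$spacing[ax] + 1)
    if (interpolation == "nearest") {
      iv <- lapply(1:3, function(ax) clip(round(u[[ax]]), 1L, d[ax]))
      out <- vol$data[iv[[1]], iv[[2]], iv[[3]], drop = FALSE]
    } else {
      i0 <- lapply(1:3, function(ax) clip(floor(u[[ax]]), 1, d[ax] - 1))
      fr <- lapply(1:3, function(ax) clip(u[[ax]] - i0[[ax]], 0, 1))
      out <- array(0, dim = n_out)
      for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
        wx <- if (a == 0) 1 - fr[[1]] else fr[[1]]
        wy <- if (b == 0) 1 - fr[[2]] else fr[[2]]
        wz <- if (cc == 0) 1 - fr[[3]] else fr[[3]]
        w <- outer(outer(wx, wy), wz)
        out <- out + w * vol$data[i0[[1]] + a, i0[[2]] + b, i0[[3]] + cc,
                                  drop = FALSE]
      }
    }
  }
  res <- image_volume(out, rep(target_spacing, 3), vol$origin, vol$modality)
  if (inherits(vol, "tumor_mask"))
    res <- tumor_mask(res$data, res$spacing, res$origin)
  res
}

# integer offsets of a Euclidean ball of the given voxel radius (centre incl.)
ball_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

#' Local entropy map
#'
#' Shannon entropy (bits) of the intensity histogram in the spherical
#' neighborhood of each voxel. The histogram uses `n_bins` equal-width bins
#' spanning the volume's full intensity range; neighborhoods are truncated at
#' the volume boundary. Output values lie in \[0, log2(n_bins)\].
#'
#' @param vol an [image_volume()] with finite intensities.
#' @param radius neighborhood radius in voxels (>= 1), default 2.
#' @param n_bins histogram bin count (>= 2), default 32.
#' @return An `image_volume` with modality `ENTROPY`.
#' @export
local_entropy <- function(vol, radius = 2, n_bins = 32) {
  stopifnot(is_image_volume(vol))
  if (radius < 1) stop("local_entropy: radius must be >= 1")
  if (n_bins < 2) stop("local_entropy: n_bins must be >= 2")
  d <- dim(vol$data)
  rng <- range(vol$data)
  if (diff(rng) == 0) {
    warning("local_entropy: degenerate intensity range (max = min); ",
            "returning all-zero entropy")
    return(image_volume(array(0, d), vol$spacing, vol$origin, "ENTROPY"))
  }
  wbin <- diff(rng) / n_bins
  binidx <- pmin(n_bins, floor((as.vector(vol$data) - rng[1]) / wbin) + 1L)
  n <- prod(d)
  counts <- matrix(0L, nrow = n, ncol = n_bins)
  offs <- ball_offsets(radius)
  for (o in seq_len(nrow(offs))) {
    off <- offs[o, ]
    if (all(off == 0L)) {
      counts[cbind(seq_len(n), binidx)] <-
        counts[cbind(seq_len(n), binidx)] + 1L
    } else {
      p <- offset_pairs(d, off)
      ij <- cbind(p$center, binidx[p$nb])
      counts[ij] <- counts[ij] + 1L
    }
  }
  tot <- rowSums(counts)
  pm <- counts / tot
  plogp <- pm * log2(pm)
  plogp[pm == 0] <- 0
  ent <- -rowSums(plogp)
  image_volume(array(ent, d), vol$spacing, vol$origin, "ENTROPY")
}

# bounding box of a mask, expanded by `pad` voxels and clipped to the grid
mask_bbox <- function(mask, pad = 0L) {
  d <- dim(mask)
  idx <- which(mask != 0)
  xyz <- lin_to_coord(idx, d)
  lo <- pmax(1L, apply(xyz, 2, min) - pad)
  hi <- pmin(d, apply(xyz, 2, max) + pad)
  list(lo = lo, hi = hi)
}

#' Harmonize one CT/PET case into the four habitat channels
#'
#' Resamples to an isotropic grid, applies lung windowing to CT, clips SUV,
#' and computes local entropy of the windowed CT and of the (clipped, scaled)
#' SUV inside the tumor bounding box. Entropy is computed on a subvolume
#' cropped to the mask bounding box (padded by the entropy radius) for speed;
#' only voxels inside the tumor are consumed downstream.
#'
#' @param ct CT [image_volume()] in HU.
#' @param suv SUV [image_volume()] (use [compute_suv()] first if starting from
#'   activity).
#' @param mask [tumor_mask()] on the same grid.
#' @param target_spacing isotropic grid spacing in mm (default 1).
#' @param window_center,window_width lung window parameters (HU).
#' @param suv_cap SUV ceiling before \[0,1\] scaling (default 20).
#' @param entropy_radius,entropy_bins local entropy parameters.
#' @return A list with `image_volume`s `ct_norm`, `ct_entropy`, `suv_norm`
#'   (clipped SUV / `suv_cap`), `suv_entropy`, the resampled `mask`, and
#'   `entropy_bins` (needed to scale entropy channels at fusion).
#' @export
preprocess_case <- function(ct, suv, mask, target_spacing = 1,
                            window_center = -400, window_width = 1500,
                            suv_cap = 20,
                            entropy_radius = 2, entropy_bins = 32) {
  check_same_grid(ct, suv, "CT and SUV")
  check_same_grid(ct, mask, "CT and mask")
  ct <- resample_isotropic(ct, target_spacing, "linear")
  suv <- resample_isotropic(suv, target_spacing, "linear")
  mask <- resample_isotropic(mask, target_spacing, "nearest")
  ct_norm <- ct_lung_window(ct, window_center, window_width)
  suv_norm <- image_volume(clip(suv$data, 0, suv_cap) / suv_cap,
                           suv$spacing, suv$origin, "NORMALIZED")
  bb <- mask_bbox(mask$data, pad = entropy_radius + 1L)
  ent_of <- function(v) {
    sub <- v$data[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
                  drop = FALSE]
    subvol <- image_volume(sub, v$spacing, v$origin, "NORMALIZED")
    e <- local_entropy(subvol, entropy_radius, entropy_bins)
    full <- array(0, dim = dim(v$data))
    full[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <- e$data
    image_volume(full, v$spacing, v$origin, "ENTROPY")
  }
  list(ct_norm = ct_norm,
       ct_entropy = ent_of(ct_norm),
       suv_norm = suv_norm,
       suv_entropy = ent_of(suv_norm),
       mask = mask,
       entropy_bins = entropy_bins)
}
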