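#' 3-D image volume
#'
#' Light container for a 3-D scalar grid with voxel spacing, origin and a
#' modality tag. All pipeline stages operate on these objects; voxel data are
#' plain R arrays so base-R array semantics apply throughout.
#'
#' @param data numeric 3-D array of voxel values; must be finite everywhere.
#' @param spacing numeric length-3, mm per axis (all > 0).
#' @param origin numeric length-3, mm position of the first voxel centre.
#' @param modality one of `"CT"`, `"PET_ACT"`, `"SUV"`, `"ENTROPY"`,
#'   `"NORMALIZED"`, `"MASK"`, `"LABEL"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         modality = "CT") {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("image_volume: 'data' must be a 3-D array, got ",
         length(dim(data)), " dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_volume: spacing must be 3 positive finite values")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("image_volume: origin must be 3 finite values")
  modality <- match.arg(modality,
                        c("CT", "PET_ACT", "SUV", "ENTROPY", "NORMALIZED",
                          "MASK", "LABEL"))
  nbad <- sum(!is.finite(data))
  if (nbad > 0L)
    stop("image_volume: ", nbad, " non-finite voxel(s) in data")
  structure(list(data = data, spacing = spacing, origin = origin,
                 modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %s  %d x %d x %d voxels  spacing %.3g x %.3g x %.3g mm\n",
              x$modality, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

is_image_volume <- function(x) inherits(x, "image_volume")

#' Binary tumor mask
#'
#' @param data logical or 0/1 numeric 3-D array; at least one voxel set.
#' @param spacing,origin as for [image_volume()].
#' @return An object of class `tumor_mask` (also an `image_volume`).
#' @export
tumor_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("tumor_mask: 'data' must be a 3-D array")
  u <- unique(as.vector(data))
  if (!all(u %in% c(0, 1, TRUE, FALSE)))
    stop("tumor_mask: data must be binary (0/1)")
  data <- array(as.integer(data != 0), dim = dim(data))
  if (sum(data) == 0L)
    stop("tumor_mask: mask is empty (no voxel set)")
  v <- image_volume(data, spacing, origin, modality = "MASK")
  class(v) <- c("tumor_mask", class(v))
  v
}

# check that two grids are identical (shape + spacing); registration is out of
# scope so mismatched grids are a hard error everywhere downstream
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)))
    stop("grid mismatch between ", what, ": shapes ",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"),
         " (inputs must be co-registered and resampled to a common grid)")
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop("grid mismatch between ", what, ": spacings differ")
  invisible(TRUE)
}

#' Read a NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param modality modality tag to record, see [image_volume()].
#' @return An [image_volume()].
#' @export
load_volume <- function(path, modality = "CT") {
  if (!file.exists(path)) stop("load_volume: file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("load_volume: expected a 3-D image, got ", length(d),
         " dimensions in ", path)
  arr <- array(as.numeric(img), dim = d)
  nbad <- sum(!is.finite(arr))
  if (nbad > 0L)
    stop("load_volume: ", nbad, " non-finite voxel(s) in ", path)
  sp <- RNifti::pixdim(img)[1:3]
  or <- tryCatch(RNifti::origin(img), error = function(e) c(0, 0, 0))
  image_volume(arr, spacing = sp, origin = as.numeric(or)[1:3],
               modality = modality)
}

#' Write a volume as NIfTI
#'
#' Voxel data are stored as 64-bit floats so that
#' `load_volume(write_volume(v, f))` round-trips bit-exactly.
#'
#' @param vol an [image_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_image_volume(vol))
  img <- RNifti::asNifti(
    vol$data,
    reference = list(pixdim = c(1, vol$spacing, 1, 1, 1, 1)),
    datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a clinical table from CSV
#'
#' Expected columns: `patient_id`, `age`, `sex`, `stage`, `histology`,
#' `treatment`, `rfs_time`, `rfs_event`, `os_time`, `os_event`, and optional
#' `ctdna_baseline`, `ctdna_clearance`.
#'
#' @param path CSV file path.
#' @return A `data.frame`, validated.
#' @export
load_clinical <- function(path) {
  if (!file.exists(path)) stop("load_clinical: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical(df)
}

validate_clinical <- function(df) {
  need <- c("patient_id", "age", "sex", "stage", "histology", "treatment",
            "rfs_time", "rfs_event", "os_time", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("clinical table: duplicated patient_id")
  for (tc in c("rfs_time", "os_time"))
    if (any(df[[tc]] < 0, na.rm = TRUE)) stop("clinical table: ", tc, " < 0")
  for (ec in c("rfs_event", "os_event"))
    if (!all(df[[ec]] %in% c(0, 1))) stop("clinical table: ", ec,
                                          " must be 0/1")
  df
}
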