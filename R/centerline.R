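# Centerline volume I/O. A centerline volume is the imaging-derived
# representation of the vasculature: nonzero voxels lie on vessel
# centerlines and carry the local vessel radius in mm; the affine maps
# 0-based voxel indices to physical mm coordinates.

#' Construct a centerline volume
#'
#' @param values 3D non-negative numeric array; voxel value = centerline
#'   radius in mm, 0 = background.
#' @param affine 4x4 voxel-to-mm transform (0-based voxel indices). Defaults
#'   to a diagonal scaling by `spacing`.
#' @param spacing Per-axis voxel size in mm; ignored when `affine` is given
#'   (then derived from the affine column norms).
#' @return An object of class `centerline_volume` with fields `values`,
#'   `affine`, `spacing`.
#' @export
centerline_volume <- function(values, affine = NULL, spacing = c(1, 1, 1)) {
  if (length(dim(values)) != 3L)
    stop("centerline volume must be a 3D array")
  if (any(values < 0)) stop("centerline radii must be non-negative")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(values = values, affine = affine, spacing = spacing),
            class = "centerline_volume")
}

#' Read a centerline volume from a NIfTI file
#'
#' Nonzero voxels are centerline points and carry the local vessel radius in
#' mm. The affine is taken from the NIfTI xform; spacing is derived from its
#' column norms.
#'
#' @param path Path to a 3D `.nii` / `.nii.gz` file.
#' @return A [centerline_volume()].
#' @export
read_centerline <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(arr)), " dimensions")
  vol <- centerline_volume(arr, affine = unname(RNifti::xform(img)))
  if (n_centerline_voxels(vol) == 0L)
    stop("centerline volume is empty (all voxels zero)")
  vol
}

#' Write a centerline (or mask) volume to NIfTI
#'
#' @param vol A [centerline_volume()] or a plain 3D array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param spacing Voxel spacing in mm, used when `vol` is a plain array.
#' @return `path`, invisibly.
#' @export
write_centerline <- function(vol, path, spacing = c(1, 1, 1)) {
  if (inherits(vol, "centerline_volume")) {
    arr <- vol$values
    spacing <- vol$spacing
  } else arr <- vol
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Number of centerline (nonzero) voxels
#' @param vol A [centerline_volume()].
#' @return Integer count.
#' @export
n_centerline_voxels <- function(vol) sum(vol$values > 0)

# Map 0-based voxel index rows (n x 3) to physical mm coordinates.
voxel_to_mm <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3L)
  xyz1 <- cbind(ijk, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}
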