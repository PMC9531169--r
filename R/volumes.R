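#' Image volume container
#'
#' A 3D scalar grid with voxel spacing, a physical unit, and an optional
#' voxel-to-world affine. Volumes carry either tracer activity
#' concentration (kBq/ml) or the dimensionless standardized uptake value
#' (SUV).
#'
#' @param values numeric 3D array.
#' @param spacing_mm numeric length-3, voxel edge lengths in mm (all > 0).
#' @param unit `"activity_kBq_per_ml"` or `"suv"`.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices). The
#'   default places the grid at the world origin with axes scaled by
#'   `spacing_mm`. Pass `NULL` explicitly for a volume with no world frame
#'   (such volumes cannot be resampled).
#'
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing_mm,
                         unit = c("activity_kBq_per_ml", "suv"),
                         affine = default_affine(spacing_mm)) {
  unit <- match.arg(unit)
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array, got ", length(dim(values)), " dims")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive finite numbers")
  if (any(!is.finite(values)))
    stop("volume contains non-finite values")
  if (!is.null(affine)) affine <- check_affine(affine)
  structure(list(values = values, spacing_mm = spacing_mm,
                 unit = unit, affine = affine),
            class = "image_volume")
}

#' Binary mask container
#'
#' @param values logical (or coercible 0/1) 3D array.
#' @param spacing_mm voxel spacing in mm.
#' @param role one of `"roi"`, `"reference"`, `"mri_target"`, `"isocontour"`.
#' @param affine 4x4 voxel-to-world matrix; see [image_volume()].
#'
#' @return An object of class `pet_mask`.
#' @export
pet_mask <- function(values, spacing_mm,
                     role = c("roi", "reference", "mri_target", "isocontour"),
                     affine = default_affine(spacing_mm)) {
  role <- match.arg(role)
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("mask `values` must be a 3D array")
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask contains NA voxels")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive numbers")
  if (!is.null(affine)) affine <- check_affine(affine)
  structure(list(values = values, spacing_mm = spacing_mm,
                 role = role, affine = affine),
            class = "pet_mask")
}

default_affine <- function(spacing_mm) {
  a <- diag(c(as.numeric(spacing_mm), 1))
  a
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || any(!is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  affine
}

#' @exportS3Method base::print
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s, %s voxels, spacing %s mm, range [%.3g, %.3g]\n",
              x$unit, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @exportS3Method base::print
print.pet_mask <- function(x, ...) {
  cat(sprintf("<pet_mask> role=%s, %s voxels, %d set (%.3f ml)\n",
              x$role, paste(dim(x$values), collapse = "x"),
              sum(x$values), volume_ml(x)))
  invisible(x)
}

same_grid <- function(a, b) identical(dim(a$values), dim(b$values))

stopifnot_same_grid <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(what, " are on different grids: ",
         paste(dim(a$values), collapse = "x"), " vs ",
         paste(dim(b$values), collapse = "x"))
  invisible(TRUE)
}

#' Volume of a binary mask in millilitres
#'
#' Voxel count times voxel volume; 1000 mm^3 = 1 ml = 1 cm^3, matching the
#' cm^3 unit used for radiotherapy volumes.
#'
#' @param mask a [pet_mask()].
#' @return Non-negative volume in ml; 0 for an empty mask.
#' @export
volume_ml <- function(mask) {
  stopifnot(inherits(mask, "pet_mask"))
  sum(mask$values) * prod(mask$spacing_mm) / 1000
}

#' Nearest-neighbour resampling of a mask onto a target grid
#'
#' Harmonizes grids of images that already share a world coordinate frame
#' (e.g. PET and planning MRI after rigid registration). Each target voxel
#' centre is mapped through the target affine into world space and back
#' through the source affine; the nearest source voxel supplies the value.
#' Idempotent when the grids already coincide. Registration itself is out
#' of scope: both affines must express the same world frame.
#'
#' @param mask a [pet_mask()] with a non-NULL affine.
#' @param target an [image_volume()] or [pet_mask()] with a non-NULL affine.
#' @return A [pet_mask()] on the target grid (same role as `mask`).
#' @export
resample_to_grid <- function(mask, target) {
  stopifnot(inherits(mask, "pet_mask"))
  if (is.null(mask$affine) || is.null(target$affine))
    stop("resample_to_grid requires affines on both mask and target")
  dt <- dim(target$values)
  if (identical(dt, dim(mask$values)) && isTRUE(all.equal(mask$affine, target$affine)))
    return(pet_mask(mask$values, target$spacing_mm, role = mask$role,
                    affine = target$affine))
  idx <- as.matrix(expand.grid(i = seq_len(dt[1]) - 1,
                               j = seq_len(dt[2]) - 1,
                               k = seq_len(dt[3]) - 1))
  world <- target$affine %*% rbind(t(idx), 1)
  src <- solve(mask$affine) %*% world
  si <- round(src[1, ]) + 1; sj <- round(src[2, ]) + 1; sk <- round(src[3, ]) + 1
  ds <- dim(mask$values)
  inside <- si >= 1 & si <= ds[1] & sj >= 1 & sj <= ds[2] & sk >= 1 & sk <= ds[3]
  out <- logical(nrow(idx))
  out[inside] <- mask$values[cbind(si[inside], sj[inside], sk[inside])]
  pet_mask(array(out, dt), target$spacing_mm, role = mask$role,
           affine = target$affine)
}

#' Write a volume or mask as NIfTI-1
#'
#' Masks are written as 0/1 integers. The voxel spacing is stored in the
#' NIfTI pixdim; the affine (when present) in the sform/qform.
#'
#' @param x an [image_volume()] or [pet_mask()].
#' @param path output path, conventionally ending in `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  vals <- if (inherits(x, "pet_mask")) array(as.integer(x$values), dim(x$values)) else x$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 file as an image volume
#'
#' @param path NIfTI file.
#' @param unit unit to stamp on the volume.
#' @return An [image_volume()].
#' @export
read_nifti_volume <- function(path, unit = c("activity_kBq_per_ml", "suv")) {
  unit <- match.arg(unit)
  img <- RNifti::readNifti(path)
  image_volume(as.array(img), RNifti::pixdim(img), unit = unit)
}

#' Read a NIfTI-1 file as a binary mask
#'
#' Voxels > 0 are in the mask.
#'
#' @param path NIfTI file.
#' @param role mask role; see [pet_mask()].
#' @return A [pet_mask()].
#' @export
read_nifti_mask <- function(path, role = "roi") {
  img <- RNifti::readNifti(path)
  pet_mask(as.array(img) > 0, RNifti::pixdim(img), role = role)
}
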