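#' Percent-SUVmax isocontours within a ROI
#'
#' For each level x the isocontour Ix is the set of ROI voxels with
#' SUV >= x% of the ROI SUVmax. The threshold is inclusive (a voxel exactly
#' at the threshold is kept, so level 100 returns the argmax voxel(s)), no
#' connected-component pruning is applied, and thresholds are relative, so
#' rescaling the image by a positive constant leaves every contour
#' unchanged. Volumes are reported in ml (= cm^3).
#'
#' @param suv an [image_volume()]; thresholds are relative to the in-ROI
#'   maximum, so either SUV or raw activity gives identical contours.
#' @param roi non-empty [pet_mask()] on the same grid.
#' @param levels_pct percentage levels in (0, 100], conventionally
#'   `c(40, 50, 60, 70)`.
#' @return An object of class `isocontour_set`: `levels_pct` (ascending),
#'   `masks` (named list of [pet_mask()]), `volumes_ml` (named numeric) and
#'   `suvmax_used`. Masks are nested: for a < b, Ib is a subset of Ia.
#' @export
isocontours <- function(suv, roi, levels_pct = c(40, 50, 60, 70)) {
  stopifnot(inherits(suv, "image_volume"), inherits(roi, "pet_mask"))
  stopifnot_same_grid(suv, roi, "image and ROI")
  if (!any(roi$values)) stop("ROI mask is empty")
  if (length(levels_pct) == 0) stop("no isocontour levels given")
  levels_pct <- sort(as.numeric(levels_pct))
  if (any(levels_pct <= 0 | levels_pct > 100))
    stop("isocontour levels must lie in (0, 100]")
  smax <- max(suv$values[roi$values])
  masks <- lapply(levels_pct, function(lev) {
    pet_mask(roi$values & (suv$values >= lev / 100 * smax),
             suv$spacing_mm, role = "isocontour", affine = suv$affine)
  })
  names(masks) <- as.character(levels_pct)
  vols <- vapply(masks, volume_ml, numeric(1))
  structure(list(levels_pct = levels_pct, masks = masks,
                 volumes_ml = vols, suvmax_used = smax),
            class = "isocontour_set")
}

#' @exportS3Method base::print
print.isocontour_set <- function(x, ...) {
  cat("<isocontour_set> SUVmax", signif(x$suvmax_used, 4), "\n")
  for (lev in names(x$masks))
    cat(sprintf("  I%s: %.3f ml\n", lev, x$volumes_ml[[lev]]))
  invisible(x)
}
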