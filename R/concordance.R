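#' Conformity index and Dice overlap of two masks
#'
#' The conformity index (CI) is the Jaccard overlap: intersection volume of
#' the PET-defined and MRI-defined structures divided by their union. Dice
#' is 2*intersection / (sum of volumes) and satisfies dice = 2 ci / (1 + ci).
#' `added_volume_ml` is the volume the PET structure would add to the MRI
#' target (union minus MRIvol) and `pct_increase` expresses it as a
#' percentage of MRIvol.
#'
#' @param pet_mask a [pet_mask()] (typically an isocontour); may be empty,
#'   in which case ci = dice = 0.
#' @param mri_mask a non-empty [pet_mask()] on the same grid (GTV, or CTV
#'   where no GTV is defined).
#' @return A one-row data frame with columns petvol_ml, mrivol_ml,
#'   intersection_ml, union_ml, ci, dice, added_volume_ml, pct_increase.
#' @export
conformity <- function(pet_mask, mri_mask) {
  stopifnot(inherits(pet_mask, "pet_mask"), inherits(mri_mask, "pet_mask"))
  stopifnot_same_grid(pet_mask, mri_mask, "PET and MRI masks")
  if (!any(mri_mask$values)) stop("MRI target mask is empty")
  vox_ml <- prod(pet_mask$spacing_mm) / 1000
  n_pet <- sum(pet_mask$values)
  n_mri <- sum(mri_mask$values)
  n_int <- sum(pet_mask$values & mri_mask$values)
  n_uni <- n_pet + n_mri - n_int
  ci <- n_int / n_uni
  dice <- if (n_pet + n_mri > 0) 2 * n_int / (n_pet + n_mri) else 0
  added <- (n_uni - n_mri) * vox_ml
  data.frame(petvol_ml = n_pet * vox_ml,
             mrivol_ml = n_mri * vox_ml,
             intersection_ml = n_int * vox_ml,
             union_ml = n_uni * vox_ml,
             ci = ci, dice = dice,
             added_volume_ml = added,
             pct_increase = 100 * added / (n_mri * vox_ml))
}

#' Best matching isocontour against an MRI target volume
#'
#' Computes one concordance record per isocontour level and identifies the
#' level with the largest CI as the best matching isocontour. Ties are
#' broken toward the smallest level (the largest, most target-covering
#' contour).
#'
#' @param iso an [isocontours()] result.
#' @param mri_mask non-empty MRI target mask on the same grid.
#' @param patient identifier carried into the output table.
#' @return An object of class `concordance_table`: `patient`, `records`
#'   (data frame with level_pct and concordance columns plus `is_best`),
#'   `best_level_pct`, `best_ci`.
#' @export
best_matching_isocontour <- function(iso, mri_mask, patient = "patient") {
  stopifnot(inherits(iso, "isocontour_set"))
  if (length(iso$levels_pct) == 0) stop("isocontour set has no levels")
  recs <- do.call(rbind, lapply(seq_along(iso$levels_pct), function(i) {
    cbind(level_pct = iso$levels_pct[i],
          conformity(iso$masks[[i]], mri_mask))
  }))
  best <- which.max(recs$ci)  # levels ascending, so first max = smallest level
  recs$is_best <- seq_len(nrow(recs)) == best
  structure(list(patient = patient, records = recs,
                 best_level_pct = recs$level_pct[best],
                 best_ci = recs$ci[best]),
            class = "concordance_table")
}

#' @exportS3Method base::print
print.concordance_table <- function(x, ...) {
  cat(sprintf("<concordance_table> %s: best matching isocontour I%g (CI %.3f)\n",
              x$patient, x$best_level_pct, x$best_ci))
  print(x$records[, c("level_pct", "petvol_ml", "mrivol_ml", "ci", "dice",
                      "pct_increase", "is_best")], row.names = FALSE)
  invisible(x)
}
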