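#' Tracer injection record
#'
#' Per-scan administration metadata required to convert an activity
#' concentration volume into standardized uptake values.
#'
#' @param injected_activity_MBq injected activity in MBq (> 0).
#' @param body_weight_kg patient body weight in kg (> 0).
#' @param injection_time,acquisition_time ISO-8601 strings or POSIXct;
#'   acquisition must not precede injection.
#' @param decay_corrected logical; `TRUE` (the DICOM norm) means the
#'   activity image is already decay-corrected to injection time.
#' @param half_life_min radionuclide half-life in minutes; default 109.77
#'   (fluorine-18).
#'
#' @return An object of class `injection_record`.
#' @export
injection_record <- function(injected_activity_MBq, body_weight_kg,
                             injection_time, acquisition_time,
                             decay_corrected = TRUE,
                             half_life_min = 109.77) {
  if (!is.numeric(injected_activity_MBq) || injected_activity_MBq <= 0)
    stop("injected_activity_MBq must be > 0")
  if (!is.numeric(body_weight_kg) || body_weight_kg <= 0)
    stop("body_weight_kg must be > 0")
  if (half_life_min <= 0) stop("half_life_min must be > 0")
  inj <- as_time(injection_time)
  acq <- as_time(acquisition_time)
  if (acq < inj) stop("acquisition_time precedes injection_time")
  structure(list(injected_activity_MBq = injected_activity_MBq,
                 body_weight_kg = body_weight_kg,
                 injection_time = inj, acquisition_time = acq,
                 decay_corrected = isTRUE(decay_corrected),
                 half_life_min = half_life_min),
            class = "injection_record")
}

as_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (is.na(out)) stop("unparseable timestamp: ", x)
  out
}

#' Convert an activity volume to SUV
#'
#' Body-weight SUV under the 1 g/ml tissue-density convention:
#' `SUV(v) = C(v) / (injected activity / body weight)`, with `C` in kBq/ml
#' and dose-per-weight in kBq/g (numerically MBq/kg). If the image is not
#' decay-corrected to injection time, the activity is first scaled by
#' `exp(ln 2 * dt / half_life)` where `dt` is the injection-to-acquisition
#' interval in minutes.
#'
#' @param activity an [image_volume()] with unit `activity_kBq_per_ml`.
#' @param injection an [injection_record()].
#' @return An [image_volume()] with unit `suv`.
#' @export
to_suv <- function(activity, injection) {
  stopifnot(inherits(activity, "image_volume"), inherits(injection, "injection_record"))
  if (activity$unit != "activity_kBq_per_ml")
    stop("to_suv expects an activity volume, got unit ", activity$unit)
  conc <- activity$values
  if (!injection$decay_corrected) {
    dt_min <- as.numeric(difftime(injection$acquisition_time,
                                  injection$injection_time, units = "mins"))
    conc <- conc * exp(log(2) * dt_min / injection$half_life_min)
  }
  dose_per_weight <- injection$injected_activity_MBq / injection$body_weight_kg # kBq/g
  image_volume(conc / dose_per_weight, activity$spacing_mm, unit = "suv",
               affine = activity$affine)
}

#' Maximum SUV within a region of interest
#'
#' Voxels outside the ROI are ignored; this is how hot non-tumor structures
#' (vessels, basal ganglia) are excluded — they are simply left out of the
#' ROI at delineation time.
#'
#' @param suv an [image_volume()] with unit `suv`.
#' @param roi a non-empty [pet_mask()] on the same grid.
#' @return The maximum SUV over ROI voxels.
#' @export
suvmax_in_roi <- function(suv, roi) {
  stopifnot(inherits(suv, "image_volume"), inherits(roi, "pet_mask"))
  stopifnot_same_grid(suv, roi, "SUV volume and ROI")
  if (!any(roi$values)) stop("ROI mask is empty")
  max(suv$values[roi$values])
}

#' Maximum standardized uptake ratio (SURmax)
#'
#' SURmax = SUVmax of the tumor ROI divided by the mean SUV of a background
#' reference region (typically drawn in the contralateral hemisphere,
#' spanning gray and white matter). The reference mask is caller-supplied
#' and must be disjoint from the ROI.
#'
#' @param suv an [image_volume()] with unit `suv`.
#' @param roi tumor ROI mask.
#' @param reference background reference mask, disjoint from `roi`.
#' @return A list of class `uptake_metrics` with `suvmax`, `ref_mean_suv`
#'   and `surmax` (= suvmax / ref_mean_suv).
#' @export
surmax <- function(suv, roi, reference) {
  stopifnot(inherits(reference, "pet_mask"))
  stopifnot_same_grid(suv, reference, "SUV volume and reference")
  if (!any(reference$values)) stop("reference mask is empty")
  if (any(roi$values & reference$values))
    stop("ROI and reference masks overlap; the reference must be tumor-free")
  smax <- suvmax_in_roi(suv, roi)
  ref_mean <- mean(suv$values[reference$values])
  if (ref_mean <= 0) stop("reference region mean SUV is not positive")
  structure(list(suvmax = smax, ref_mean_suv = ref_mean,
                 surmax = smax / ref_mean),
            class = "uptake_metrics")
}

#' @exportS3Method base::print
print.uptake_metrics <- function(x, ...) {
  cat(sprintf("<uptake_metrics> SUVmax %.3f, reference mean %.3f, SURmax %.3f\n",
              x$suvmax, x$ref_mean_suv, x$surmax))
  invisible(x)
}
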