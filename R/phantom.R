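#' Specification of a synthetic PET phantom
#'
#' Describes a focal-hotspot phantom: a uniform tissue background with one
#' or more anisotropic Gaussian hotspots and additive Gaussian voxel noise
#' (clipped at zero). This emulates the focal amino-acid uptake pattern of
#' a glioma over brain background; it deliberately models no scanner
#' physics (PSF, attenuation, reconstruction artefacts).
#'
#' @param grid_shape three positive integers, voxels per axis.
#' @param voxel_spacing_mm three positive reals, mm.
#' @param background_uptake background activity concentration, kBq/ml (>= 0).
#' @param hotspots list of hotspots, each a list with `center` (voxel
#'   indices, 1-based, inside the grid), `sigma_mm` (per-axis Gaussian
#'   sigma in mm, scalar recycled, all > 0), `amplitude` (peak activity
#'   above background, kBq/ml).
#' @param noise_sd standard deviation of i.i.d. Gaussian voxel noise,
#'   kBq/ml (>= 0).
#' @param seed integer seed; all randomness in [make_pet_phantom()] flows
#'   through it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_spacing_mm, background_uptake,
                         hotspots, noise_sd = 0, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1))
    stop("grid_shape must be three positive integers")
  voxel_spacing_mm <- as.numeric(voxel_spacing_mm)
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0))
    stop("voxel_spacing_mm must be three positive reals")
  if (background_uptake < 0) stop("background_uptake must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  hotspots <- lapply(hotspots, function(h) {
    h$center <- as.numeric(h$center)
    if (length(h$center) != 3L ||
        any(h$center < 1) || any(h$center > grid_shape))
      stop("hotspot center ", paste(h$center, collapse = ","),
           " lies outside the grid")
    h$sigma_mm <- rep_len(as.numeric(h$sigma_mm), 3L)
    if (any(h$sigma_mm <= 0)) stop("hotspot sigmas must be > 0")
    if (h$amplitude < 0) stop("hotspot amplitude must be >= 0")
    h
  })
  structure(list(grid_shape = grid_shape, voxel_spacing_mm = voxel_spacing_mm,
                 background_uptake = background_uptake, hotspots = hotspots,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

noise_free_phantom_values <- function(spec) {
  d <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  vals <- array(spec$background_uptake, d)
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a])
  for (h in spec$hotspots) {
    g <- lapply(1:3, function(a) {
      dmm <- ax[[a]] - (h$center[a] - 1) * sp[a]
      exp(-0.5 * (dmm / h$sigma_mm[a])^2)
    })
    vals <- vals + h$amplitude * (g[[1]] %o% g[[2]] %o% g[[3]])
  }
  vals
}

#' Generate a synthetic PET activity phantom with ground truth
#'
#' The emitted volume is background + sum of Gaussian hotspots + i.i.d.
#' Gaussian noise, clipped at 0. The attached ground truth records the
#' noise-free peak activity, the corresponding true SUVmax under the given
#' injection record, and the noise-free isocontour volumes at the standard
#' 40--70% levels (brute-force voxel count on the noise-free image, whole
#' grid as ROI).
#'
#' @param spec a [phantom_spec()].
#' @param injection an [injection_record()] used to express the true peak
#'   as a SUV.
#' @param levels_pct levels for the ground-truth isocontour volumes.
#' @return A list with `volume` (activity [image_volume()]) and `truth`
#'   (list: `true_peak_activity`, `true_suvmax`,
#'   `true_isocontour_volumes_ml`).
#' @export
make_pet_phantom <- function(spec, injection,
                             levels_pct = c(40, 50, 60, 70)) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(injection, "injection_record"))
  clean <- noise_free_phantom_values(spec)
  vals <- clean
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vals <- vals + array(stats::rnorm(length(vals), 0, spec$noise_sd), dim(vals))
  }
  vals[vals < 0] <- 0
  vol <- image_volume(vals, spec$voxel_spacing_mm, unit = "activity_kBq_per_ml")
  peak <- max(clean)
  dose_per_weight <- injection$injected_activity_MBq / injection$body_weight_kg
  vox_ml <- prod(spec$voxel_spacing_mm) / 1000
  tiv <- vapply(levels_pct, function(lev)
    sum(clean >= lev / 100 * peak) * vox_ml, numeric(1))
  names(tiv) <- as.character(levels_pct)
  list(volume = vol,
       truth = list(true_peak_activity = peak,
                    true_suvmax = peak / dose_per_weight,
                    true_isocontour_volumes_ml = tiv))
}

#' Closed-form isocontour volume of an isotropic Gaussian hotspot
#'
#' For a noise-free isotropic hotspot of amplitude A over background b, the
#' level-L% contour of the peak (A + b) is the sphere of radius
#' `sigma * sqrt(2 log(A / (t - b)))` with threshold `t = L/100 (A + b)`;
#' the volume is returned in ml. Defined only while t > b (the contour
#' closes); above-background thresholds below b would span the whole
#' domain and yield `Inf`.
#'
#' @param amplitude hotspot peak amplitude above background.
#' @param background background level.
#' @param sigma_mm isotropic Gaussian sigma in mm.
#' @param level_pct contour level as percent of peak.
#' @return Volume in ml.
#' @export
gaussian_isocontour_volume_ml <- function(amplitude, background, sigma_mm,
                                          level_pct) {
  thr <- level_pct / 100 * (amplitude + background)
  if (thr <= background) return(Inf)
  if (thr > amplitude + background) return(0)
  r <- sigma_mm * sqrt(2 * log(amplitude / (thr - background)))
  4 / 3 * pi * r^3 / 1000
}

dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

#' Construct an MRI-style target mask with a planted conformity index
#'
#' Starting from the level-% isocontour of the supplied PET volume, builds
#' a mask whose Jaccard overlap (conformity index) with that isocontour is
#' within +/- 0.05 of `target_ci`. With contour size n, removing r interior
#' voxels and adding r exterior voxels gives Jaccard (n - r)/(n + r)
#' exactly, so r = round(n (1 - J)/(1 + J)) lands inside the band whenever
#' the contour is not degenerately small; the achieved index is verified by
#' direct voxel counting before returning. Added voxels are drawn from
#' successive dilation rings so the mask stays spatially coherent.
#'
#' @param pet activity or SUV [image_volume()].
#' @param roi ROI mask for the isocontour.
#' @param level_pct isocontour level (one of 40, 50, 60, 70 in the standard
#'   analysis).
#' @param target_ci target conformity index in (0, 1].
#' @param seed integer seed for the voxel draws.
#' @return A [pet_mask()] with role `mri_target`.
#' @export
make_target_mask <- function(pet, roi, level_pct, target_ci, seed = 1L) {
  if (!(target_ci > 0 && target_ci <= 1)) stop("target_ci must be in (0, 1]")
  iso <- isocontours(pet, roi, levels_pct = level_pct)$masks[[1]]
  n <- sum(iso$values)
  if (n == 0)
    stop("isocontour at level ", level_pct, "% is empty; target unreachable")
  if (target_ci == 1)
    return(pet_mask(iso$values, pet$spacing_mm, role = "mri_target",
                    affine = pet$affine))
  r <- round(n * (1 - target_ci) / (1 + target_ci))
  set.seed(as.integer(seed))
  inside <- which(iso$values)
  drop_idx <- if (r > 0) sample(inside, r) else integer(0)
  ring <- dilate6(iso$values) & !iso$values
  while (sum(ring) < r) {
    grown <- dilate6(ring | iso$values)
    new_ring <- grown & !iso$values
    if (sum(new_ring) == sum(ring))
      stop("cannot reach target CI ", target_ci, " at level ", level_pct,
           "%: no room to grow the mask")
    ring <- new_ring
  }
  add_idx <- if (r > 0) sample(which(ring), r) else integer(0)
  vals <- iso$values
  vals[drop_idx] <- FALSE
  vals[add_idx] <- TRUE
  achieved <- sum(vals & iso$values) / sum(vals | iso$values)
  if (abs(achieved - target_ci) > 0.05)
    stop(sprintf("achieved CI %.3f outside +/-0.05 of target %.3f at level %g%% (contour too small)",
                 achieved, target_ci, level_pct))
  pet_mask(vals, pet$spacing_mm, role = "mri_target", affine = pet$affine)
}

#' Simulate a right-censored survival cohort with a SUVmax threshold effect
#'
#' Event times follow a log-logistic distribution with shape `shape` and
#' scale `scale_base * exp(-effect_log_scale)` for subjects above the true
#' SUVmax cutoff (time acceleration: positive effects shorten survival),
#' `scale_base` otherwise — the same model family the survival analysis
#' fits. SUVmax is uniform over `suv_range`. Censoring is independent
#' uniform on (0, c) with c solved numerically so the expected censored
#' fraction equals `censor_rate` (non-informative by construction).
#'
#' @param n cohort size (>= 2).
#' @param cutoff true SUVmax cutoff.
#' @param effect_log_scale effect on log scale; > 0 means worse survival
#'   above the cutoff.
#' @param shape log-logistic shape (> 0).
#' @param scale_base baseline log-logistic scale, i.e. the median survival
#'   time (months) of the low-uptake group.
#' @param censor_rate target fraction censored, in [0, 1).
#' @param suv_range length-2 numeric, min < max.
#' @param seed integer seed.
#' @return A data frame of class `survival_cohort` with columns `id`,
#'   `time` (months), `event` (1 = progression/death), `suvmax`; the true
#'   generating parameters are attached as attribute `truth`.
#' @export
make_survival_cohort <- function(n, cutoff, effect_log_scale, shape,
                                 scale_base, censor_rate = 0,
                                 suv_range = c(1, 8), seed = 1L) {
  if (n < 2) stop("n must be >= 2")
  if (shape <= 0 || scale_base <= 0) stop("shape and scale_base must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  suv_range <- as.numeric(suv_range)
  if (length(suv_range) != 2L || suv_range[1] >= suv_range[2])
    stop("degenerate suv_range: min must be < max")
  set.seed(as.integer(seed))
  suv <- stats::runif(n, suv_range[1], suv_range[2])
  hi <- suv > cutoff
  alpha <- scale_base * exp(-effect_log_scale * hi)
  u <- stats::runif(n)
  t_event <- alpha * (u / (1 - u))^(1 / shape)
  if (censor_rate > 0) {
    p_hi <- min(max((suv_range[2] - cutoff) / diff(suv_range), 0), 1)
    cmax <- censor_bound(censor_rate, shape, scale_base,
                         scale_base * exp(-effect_log_scale), p_hi)
    cens <- stats::runif(n, 0, cmax)
    time <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  out <- data.frame(id = sprintf("subj_%04d", seq_len(n)),
                    time = time, event = event, suvmax = suv)
  attr(out, "truth") <- list(true_cutoff = cutoff,
                             true_effect_log_scale = effect_log_scale,
                             shape = shape, scale_base = scale_base)
  class(out) <- c("survival_cohort", "data.frame")
  out
}

# Expected censored fraction with C ~ U(0, c):
# P(T > C) = (1/c) * int_0^c S_mix(t) dt; solve for c.
censor_bound <- function(censor_rate, shape, alpha_lo, alpha_hi, p_hi) {
  surv_mix <- function(t)
    (1 - p_hi) / (1 + (t / alpha_lo)^shape) + p_hi / (1 + (t / alpha_hi)^shape)
  f <- function(cc)
    stats::integrate(surv_mix, 0, cc, rel.tol = 1e-8)$value / cc - censor_rate
  upper <- alpha_lo
  while (f(upper) > 0) upper <- upper * 2
  stats::uniroot(f, c(1e-8, upper), tol = 1e-8)$root
}

#' Simulate a whole-blood expression study with planted SUVmax-linked genes
#'
#' Generates a Gaussian genes-by-samples matrix emulating a normalized,
#' log-scale microarray study with repeated blood draws per patient.
#' Planted genes carry slope `beta` on per-sample SUVmax; every gene gets a
#' grade main effect scaled by `grade_confounding` and a per-patient,
#' per-gene Gaussian random intercept shared across that patient's
#' timepoints. Tumor grade is derived from the patient's baseline SUVmax
#' tercile, so grade is a genuine confounder of the SUVmax-expression
#' relationship whenever `grade_confounding > 0`.
#'
#' @param n_genes,n_samples matrix dimensions (`n_samples` >= 3).
#' @param n_planted number of planted genes (<= `n_genes`).
#' @param beta expression change per SUVmax unit for planted genes.
#' @param grade_confounding scale of the per-gene grade main effect.
#' @param n_timepoints_per_patient blood draws per patient; patients are
#'   assigned cyclically so `ceiling(n_samples / n_timepoints)` patients
#'   are used.
#' @param seed integer seed.
#' @param residual_sd residual noise sd (log-expression units).
#' @param patient_sd sd of the per-patient random intercepts.
#' @return An object of class `expression_study`: `expr` (genes x samples),
#'   `samples` (data frame: sample_id, patient_id, timepoint, suvmax,
#'   initial_grade), `planted` (data frame: gene, coefficient).
#' @export
make_expression_study <- function(n_genes, n_samples, n_planted, beta,
                                  grade_confounding = 0,
                                  n_timepoints_per_patient = 1,
                                  seed = 1L, residual_sd = 1,
                                  patient_sd = 0.5) {
  if (n_samples < 3) stop("n_samples must be >= 3 for the downstream models")
  if (n_planted > n_genes) stop("n_planted exceeds n_genes")
  if (n_timepoints_per_patient < 1) stop("n_timepoints_per_patient must be >= 1")
  set.seed(as.integer(seed))
  n_patients <- ceiling(n_samples / n_timepoints_per_patient)
  patient <- rep(seq_len(n_patients), each = n_timepoints_per_patient)[seq_len(n_samples)]
  timepoint <- stats::ave(patient, patient, FUN = seq_along)
  suv_lo <- 1.5; suv_hi <- 8
  base_suv <- stats::runif(n_patients, suv_lo, suv_hi)
  terciles <- suv_lo + diff(c(suv_lo, suv_hi)) * c(1, 2) / 3
  grade <- 2L + (base_suv > terciles[1]) + (base_suv > terciles[2])
  suv <- base_suv[patient] + stats::rnorm(n_samples, 0, 0.3)
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  planted_idx <- if (n_planted > 0) sort(sample.int(n_genes, n_planted)) else integer(0)
  beta_g <- numeric(n_genes)
  beta_g[planted_idx] <- beta
  grade_coef <- stats::rnorm(n_genes) * grade_confounding
  u <- matrix(stats::rnorm(n_genes * n_patients, 0, patient_sd),
              n_genes, n_patients)
  expr <- beta_g %o% suv +
    grade_coef %o% as.numeric(grade[patient]) +
    u[, patient, drop = FALSE] +
    matrix(stats::rnorm(n_genes * n_samples, 0, residual_sd), n_genes, n_samples)
  dimnames(expr) <- list(gene_ids, sprintf("sample_%03d", seq_len(n_samples)))
  samples <- data.frame(sample_id = colnames(expr),
                        patient_id = sprintf("pat_%03d", patient),
                        timepoint = as.integer(timepoint),
                        suvmax = suv,
                        initial_grade = as.integer(grade[patient]))
  structure(list(expr = expr, samples = samples,
                 planted = data.frame(gene = gene_ids[planted_idx],
                                      coefficient = rep(beta, n_planted))),
            class = "expression_study")
}

#' @exportS3Method base::print
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %d genes x %d samples, %d patients, %d planted genes\n",
              nrow(x$expr), ncol(x$expr),
              length(unique(x$samples$patient_id)), nrow(x$planted)))
  invisible(x)
}
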