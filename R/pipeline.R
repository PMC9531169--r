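#' Read and validate a pipeline run configuration
#'
#' The configuration is a single JSON file (or an equivalent list) with
#' sections `imaging`, `survival` and `wbt`. Each section either carries
#' `synthetic = true` plus generator parameters, or paths to existing
#' inputs (NIfTI volumes/masks, cohort and expression CSVs). Every
#' referenced path must exist at validation time; validation happens before
#' any computation or output.
#'
#' @param config path to a JSON file, or a list with the same structure.
#' @return The validated configuration list, class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  for (sec in c("imaging", "survival", "wbt")) {
    if (is.null(config[[sec]])) stop("config lacks section: ", sec)
  }
  if (is.null(config$seed)) stop("config lacks a top-level seed")
  img <- config$imaging
  if (!isTRUE(img$synthetic)) {
    if (is.null(img$patients) || length(img$patients) == 0)
      stop("imaging section needs either synthetic = true or a patients list")
    for (p in img$patients) {
      for (f in c("pet", "roi", "reference", "mri_target", "injection")) {
        if (is.null(p[[f]])) stop("patient entry lacks path: ", f)
        if (!file.exists(p[[f]])) stop("missing input file: ", p[[f]])
      }
    }
  }
  if (!isTRUE(config$survival$synthetic) && !is.null(config$survival$cohort_csv) &&
      !file.exists(config$survival$cohort_csv))
    stop("missing input file: ", config$survival$cohort_csv)
  lv <- config$imaging$levels_pct
  if (!is.null(lv) && is.unsorted(lv))
    stop("isocontour levels must be sorted ascending")
  class(config) <- c("run_config", class(config))
  config
}

#' Run the full analysis pipeline
#'
#' Executes, as configured: phantom generation (optional) -> SUV
#' quantification -> isocontours -> concordance -> feature assembly and
#' grade ranking -> survival cutoff analysis -> whole-blood transcriptome
#' association. All tables are written as CSV ('.' decimal, LF) under
#' `output_dir`, and a JSON manifest records the package version, all
#' seeds, per-stage outputs and their MD5 hashes. Any stage failure aborts
#' with an error naming the stage; given identical config and seeds the
#' outputs are byte-identical across runs.
#'
#' @param config a [read_run_config()] input (path or list).
#' @param output_dir directory for outputs (created if needed).
#' @param quiet suppress stage progress messages on stderr.
#' @return The manifest list, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  cfg <- read_run_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) if (!quiet) message("[", stage, "] ", ...)
  manifest <- list(package = "fetpet",
                   version = as.character(utils::packageVersion("fetpet")),
                   seed = cfg$seed, stages = list())
  outputs <- character(0)
  run_stage <- function(name, fn) {
    say(name, "running")
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(status = "complete",
                                     outputs = basename(res))
    outputs <<- c(outputs, res)
    res
  }

  img <- cfg$imaging
  levels_pct <- if (is.null(img$levels_pct)) c(40, 50, 60, 70) else as.numeric(img$levels_pct)
  patients <- NULL

  run_stage("phantom", function() {
    if (isTRUE(img$synthetic)) {
      patients <<- synth_imaging_cohort(img, seed = cfg$seed, dir = output_dir)
      unlist(lapply(patients, `[[`, "files"))
    } else {
      patients <<- lapply(img$patients, load_patient_inputs)
      character(0)
    }
  })

  metrics <- NULL
  run_stage("suvquant", function() {
    metrics <<- lapply(patients, function(p) {
      suv <- to_suv(p$pet, p$injection)
      list(suv = suv, metrics = surmax(suv, p$roi, p$reference))
    })
    names(metrics) <<- vapply(patients, `[[`, character(1), "id")
    tab <- data.frame(patient = names(metrics),
                      suvmax = vapply(metrics, function(m) m$metrics$suvmax, 1),
                      ref_mean_suv = vapply(metrics, function(m) m$metrics$ref_mean_suv, 1),
                      surmax = vapply(metrics, function(m) m$metrics$surmax, 1))
    write_table(tab, file.path(output_dir, "uptake_metrics.csv"))
  })

  isosets <- NULL
  run_stage("isocontour", function() {
    isosets <<- lapply(seq_along(patients), function(i)
      isocontours(metrics[[i]]$suv, patients[[i]]$roi, levels_pct))
    names(isosets) <<- names(metrics)
    tab <- do.call(rbind, lapply(names(isosets), function(p)
      data.frame(patient = p, level_pct = isosets[[p]]$levels_pct,
                 volume_ml = unname(isosets[[p]]$volumes_ml))))
    write_table(tab, file.path(output_dir, "isocontour_volumes.csv"))
  })

  tables <- NULL
  run_stage("concordance", function() {
    tables <<- lapply(seq_along(patients), function(i) {
      mri <- resample_to_grid(patients[[i]]$mri_target, metrics[[i]]$suv)
      best_matching_isocontour(isosets[[i]], mri, patient = patients[[i]]$id)
    })
    tab <- do.call(rbind, lapply(tables, function(tb)
      cbind(patient = tb$patient, tb$records)))
    write_table(tab, file.path(output_dir, "concordance.csv"))
  })

  run_stage("features", function() {
    grades <- stats::setNames(vapply(patients, `[[`, numeric(1), "grade"),
                              vapply(patients, `[[`, character(1), "id"))
    fm <- assemble_features(tables, lapply(metrics, `[[`, "metrics"), grades)
    f1 <- write_table(cbind(patient = rownames(fm$data), fm$data, grade = fm$grade),
                      file.path(output_dir, "features.csv"))
    n_res <- if (is.null(img$n_resamples)) 100 else img$n_resamples
    rk <- rank_features_by_grade(fm, n_resamples = n_res, seed = cfg$seed + 1)
    f2 <- write_table(rk, file.path(output_dir, "feature_ranking.csv"))
    c(f1, f2)
  })

  run_stage("cohortstats", function() {
    sv <- cfg$survival
    cohort <- if (isTRUE(sv$synthetic)) {
      make_survival_cohort(n = sv$n, cutoff = sv$cutoff,
                           effect_log_scale = sv$effect_log_scale,
                           shape = sv$shape, scale_base = sv$scale_base,
                           censor_rate = sv$censor_rate %||% 0,
                           suv_range = as.numeric(sv$suv_range %||% c(1, 8)),
                           seed = cfg$seed + 2)
    } else {
      as_survival_cohort(utils::read.csv(sv$cohort_csv))
    }
    f0 <- write_table(cohort, file.path(output_dir, "cohort.csv"))
    model <- sv$model %||% "loglogistic_aft"
    scan <- scan_cutoffs(cohort, model = model, min_group = sv$min_group %||% 5)
    f1 <- write_table(scan$grid, file.path(output_dir, "cutoff_scan.csv"))
    ms <- median_split(cohort)
    dat <- cohort; dat$hi <- as.numeric(ms$group == "high")
    med_fit <- fit_loglogistic(dat, "hi")
    co <- med_fit$coefficients[med_fit$coefficients$term == "hi", ]
    summ <- data.frame(model = model,
                       median_cutoff = ms$cutoff, median_or = co$or,
                       median_p = co$p,
                       optimal_cutoff = scan$optimal_cutoff,
                       optimal_p = scan$optimal_p)
    f2 <- write_table(summ, file.path(output_dir, "survival_summary.csv"))
    km <- km_coordinates(cohort, ms$group)
    f3 <- write_table(km, file.path(output_dir, "km_coordinates.csv"))
    c(f0, f1, f2, f3)
  })

  run_stage("wbt", function() {
    wb <- cfg$wbt
    study <- if (isTRUE(wb$synthetic)) {
      make_expression_study(n_genes = wb$n_genes, n_samples = wb$n_samples,
                            n_planted = wb$n_planted, beta = wb$beta,
                            grade_confounding = wb$grade_confounding %||% 0,
                            n_timepoints_per_patient = wb$n_timepoints_per_patient %||% 1,
                            seed = cfg$seed + 3)
    } else {
      expression_study(as.matrix(utils::read.csv(wb$expr_csv, row.names = 1,
                                                 check.names = FALSE)),
                       utils::read.csv(wb$meta_csv))
    }
    filtered <- mad_filter(study, wb$mad_top_fraction %||% 0.10)
    assoc <- associate_genes(filtered)
    f1 <- write_table(assoc, file.path(output_dir, "wbt_associations.csv"))
    n_chk <- min(wb$n_checkpoint_genes %||% 5, nrow(filtered$expr))
    chk_genes <- assoc$gene[order(assoc$p)][seq_len(n_chk)]
    chk <- mixed_checkpoint_model(study, chk_genes)
    f2 <- write_table(chk, file.path(output_dir, "wbt_checkpoint.csv"))
    c(f1, f2)
  })

  manifest$outputs <- lapply(stats::setNames(outputs, basename(outputs)),
                             function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done", "manifest written to ", file.path(output_dir, "manifest.json"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", eol = "\n")
  path
}

# Generate a small synthetic imaging cohort: per patient one hotspot whose
# amplitude/extent and MRI-target conformity depend on grade, so the
# downstream feature ranking has a real signal to find.
synth_imaging_cohort <- function(img, seed, dir) {
  n <- img$n_patients %||% 15
  shape <- as.integer(img$grid_shape %||% c(32, 32, 32))
  sp <- as.numeric(img$voxel_spacing_mm %||% c(2, 2, 2))
  bg <- img$background_uptake %||% 1
  noise <- img$noise_sd %||% 0.05
  lev <- img$target_level_pct %||% 40
  grades <- rep(2:4, length.out = n)
  inj <- injection_record(
    injected_activity_MBq = img$injection$injected_activity_MBq %||% 180,
    body_weight_kg = img$injection$body_weight_kg %||% 72,
    injection_time = img$injection$injection_time %||% "2021-01-01T09:00:00",
    acquisition_time = img$injection$acquisition_time %||% "2021-01-01T09:12:00")
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    id <- sprintf("pat_%02d", i)
    g <- grades[i]
    amp <- bg * (1.5 + 0.8 * g) + stats::runif(1, -0.3, 0.3)
    sig <- 4 + 1.5 * (g - 2) + stats::runif(1, 0, 1)
    ctr <- round(shape / 2 + stats::runif(3, -2, 2))
    spec <- phantom_spec(shape, sp, bg,
                         list(list(center = ctr, sigma_mm = sig, amplitude = amp)),
                         noise_sd = noise, seed = seed + 100 + i)
    ph <- make_pet_phantom(spec, inj)
    roi_vals <- array(FALSE, shape)
    roi_vals[3:(shape[1] - 2), 3:(shape[2] - 2), 5:shape[3]] <- TRUE
    roi <- pet_mask(roi_vals, sp, role = "roi")
    ref_vals <- array(FALSE, shape)
    ref_vals[2:6, 2:6, 1:3] <- TRUE
    ref <- pet_mask(ref_vals, sp, role = "reference")
    target_ci <- min(0.95, max(0.15, 0.22 + 0.1 * (g - 2) + stats::runif(1, -0.05, 0.05)))
    mri <- make_target_mask(ph$volume, roi, lev, target_ci, seed = seed + 200 + i)
    files <- c(pet = file.path(dir, paste0(id, "_pet.nii.gz")),
               roi = file.path(dir, paste0(id, "_roi.nii.gz")),
               reference = file.path(dir, paste0(id, "_ref.nii.gz")),
               mri = file.path(dir, paste0(id, "_gtv.nii.gz")))
    write_nifti_volume(ph$volume, files["pet"])
    write_nifti_volume(roi, files["roi"])
    write_nifti_volume(ref, files["reference"])
    write_nifti_volume(mri, files["mri"])
    list(id = id, grade = as.numeric(g), pet = ph$volume, roi = roi,
         reference = ref, mri_target = mri, injection = inj,
         truth = ph$truth, files = files)
  })
}

load_patient_inputs <- function(p) {
  inj <- jsonlite::read_json(p$injection, simplifyVector = TRUE)
  list(id = p$id %||% basename(p$pet),
       grade = as.numeric(p$grade %||% NA),
       pet = read_nifti_volume(p$pet, unit = "activity_kBq_per_ml"),
       roi = read_nifti_mask(p$roi, role = "roi"),
       reference = read_nifti_mask(p$reference, role = "reference"),
       mri_target = read_nifti_mask(p$mri_target, role = "mri_target"),
       injection = injection_record(inj$injected_activity_MBq,
                                    inj$body_weight_kg,
                                    inj$injection_time, inj$acquisition_time,
                                    decay_corrected = inj$decay_corrected %||% TRUE,
                                    half_life_min = inj$half_life_min %||% 109.77),
       files = character(0))
}
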