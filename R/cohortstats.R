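#' Coerce a data frame to a survival cohort
#'
#' Validates the column contract used throughout the survival machinery:
#' `time` (months, > 0), `event` (0/1), `suvmax`, plus arbitrary covariate
#' columns (age, grade, resection, ...). Times are measured from the onset
#' of radiotherapy; subjects lost to follow-up are censored at last
#' contact (event = 0).
#'
#' @param df a data frame.
#' @return The validated data frame with class `survival_cohort`.
#' @export
as_survival_cohort <- function(df) {
  req <- c("time", "event", "suvmax")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "))
  if (any(df$time <= 0)) stop("survival times must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  if (!inherits(df, "survival_cohort"))
    class(df) <- c("survival_cohort", class(df))
  df
}

check_fit_inputs <- function(cohort, covariate_names) {
  cohort <- as_survival_cohort(cohort)
  if (sum(cohort$event) < 1) stop("no events in cohort; cannot fit")
  for (cv in covariate_names) {
    if (!cv %in% names(cohort)) stop("covariate not in cohort: ", cv)
    if (length(unique(cohort[[cv]])) < 2)
      stop("covariate is constant: ", cv)
  }
  cohort
}

#' Fit a log-logistic accelerated-failure-time model
#'
#' Parameterization S(t | x) = 1 / (1 + (t / alpha(x))^beta) with
#' log alpha(x) = mu + x'theta; the right-censored likelihood is maximized
#' (via [survival::survreg()] with the log-logistic distribution, whose
#' location-scale form on log time is exactly this AFT model: alpha =
#' exp(linear predictor), beta = 1/scale). Wald p-values come from the
#' observed information. The reported per-covariate effect is
#' `or = exp(-theta)`, a time-ratio-based odds-ratio analogue oriented so
#' values > 1 mean worse (accelerated) survival.
#'
#' @param cohort a `survival_cohort` (or compatible data frame).
#' @param covariate_names character vector of covariate columns; empty for
#'   an intercept-only fit.
#' @return An object of class `fit_result`: `model = "loglogistic_aft"`,
#'   `coefficients` (term, estimate, se, z, p, or), `alpha` (baseline
#'   scale = median survival at x = 0), `shape`, `loglik`, and the
#'   underlying `fit`.
#' @export
fit_loglogistic <- function(cohort, covariate_names = character()) {
  cohort <- check_fit_inputs(cohort, covariate_names)
  rhs <- if (length(covariate_names)) paste(covariate_names, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- withCallingHandlers(
    survival::survreg(fml, data = cohort, dist = "loglogistic"),
    warning = function(w) {
      if (grepl("Ran out of iterations", conditionMessage(w)))
        stop("log-logistic fit did not converge: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  est <- fit$coefficients
  vc <- stats::vcov(fit)
  se <- sqrt(diag(vc))[seq_along(est)]
  if (any(!is.finite(se)) || any(se <= 0))
    stop("log-logistic fit produced a degenerate information matrix")
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), z = unname(z), p = unname(p),
                      or = exp(-unname(est)), row.names = NULL)
  coefs$or[coefs$term == "(Intercept)"] <- NA_real_
  structure(list(model = "loglogistic_aft", coefficients = coefs,
                 alpha = exp(unname(est[["(Intercept)"]])),
                 shape = 1 / fit$scale,
                 loglik = fit$loglik[length(fit$loglik)],
                 fit = fit),
            class = "fit_result")
}

#' Fit a Cox proportional-hazards model
#'
#' Partial likelihood with Breslow tie handling; hazard ratios
#' `exp(coef)` and Wald p-values. Monotone likelihood (perfect separation
#' of risk sets) is reported as an error suggesting penalization.
#'
#' @inheritParams fit_loglogistic
#' @return A `fit_result` with `model = "cox_ph"`; the `or` column holds
#'   the hazard ratio.
#' @export
fit_coxph <- function(cohort, covariate_names) {
  if (length(covariate_names) == 0) stop("Cox model needs >= 1 covariate")
  cohort <- check_fit_inputs(cohort, covariate_names)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariate_names, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = cohort, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        stop("monotone partial likelihood (coefficient diverging); ",
             "consider a penalized fit: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(model = "cox_ph",
                 coefficients = data.frame(term = names(est),
                                           estimate = unname(est),
                                           se = unname(se), z = unname(z),
                                           p = unname(p),
                                           or = exp(unname(est)),
                                           row.names = NULL),
                 loglik = fit$loglik[length(fit$loglik)],
                 fit = fit),
            class = "fit_result")
}

#' @exportS3Method base::print
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$model, "\n")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Median split of a cohort by SUVmax
#'
#' Dichotomizes at the sample median with a strict `>` rule: subjects
#' exactly at the median go to the low-uptake group (matching the
#' "> cutoff" phrasing of uptake stratification).
#'
#' @param cohort a `survival_cohort` with >= 4 subjects.
#' @return List with `cutoff` (the median) and `group` (factor
#'   `"low"`/`"high"`).
#' @export
median_split <- function(cohort) {
  cohort <- as_survival_cohort(cohort)
  if (nrow(cohort) < 4) stop("median split needs >= 4 subjects")
  if (length(unique(cohort$suvmax)) < 2) stop("SUVmax is constant; cannot split")
  cutoff <- stats::median(cohort$suvmax)
  group <- factor(ifelse(cohort$suvmax > cutoff, "high", "low"),
                  levels = c("low", "high"))
  list(cutoff = cutoff, group = group)
}

#' Minimal-p-value scan over SUVmax cutoffs
#'
#' The candidate grid consists of midpoints between consecutive distinct
#' observed SUVmax values that leave at least `min_group` subjects on each
#' side of the strict `suvmax > c` split. At each candidate the chosen
#' survival model is fitted with the single binary covariate
#' `1[suvmax > c]`; the optimal cutoff is the one with the smallest Wald
#' p-value (ties broken toward the smaller cutoff). No multiplicity
#' adjustment is applied inside the scan — the minimum over the grid
#' inflates significance, so the full per-cutoff trace is returned for any
#' downstream correction.
#'
#' @param cohort a `survival_cohort`.
#' @param model `"loglogistic_aft"` or `"cox_ph"`.
#' @param min_group minimum subjects on each side of every candidate.
#' @return An object of class `cutoff_scan_result`: `grid` (data frame:
#'   cutoff, n_low, n_high, estimate, or, p), `optimal_cutoff`,
#'   `optimal_p`, `median_cutoff`, `model`.
#' @export
scan_cutoffs <- function(cohort, model = c("loglogistic_aft", "cox_ph"),
                         min_group = 5) {
  model <- match.arg(model)
  cohort <- as_survival_cohort(cohort)
  if (nrow(cohort) < 2 * min_group)
    stop("cohort smaller than 2 * min_group (", min_group, ")")
  s <- sort(unique(cohort$suvmax))
  if (length(s) < 2) stop("SUVmax is constant; no admissible cutoffs")
  mids <- (s[-1] + s[-length(s)]) / 2
  admissible <- vapply(mids, function(cc) {
    sum(cohort$suvmax > cc) >= min_group && sum(cohort$suvmax <= cc) >= min_group
  }, logical(1))
  grid <- mids[admissible]
  if (length(grid) == 0) stop("no admissible cutoffs with min_group = ", min_group)
  rows <- lapply(grid, function(cc) {
    dat <- cohort
    dat$hi <- as.numeric(dat$suvmax > cc)
    res <- tryCatch({
      f <- if (model == "loglogistic_aft") fit_loglogistic(dat, "hi")
           else fit_coxph(dat, "hi")
      co <- f$coefficients[f$coefficients$term == "hi", ]
      data.frame(cutoff = cc, n_low = sum(dat$hi == 0), n_high = sum(dat$hi == 1),
                 estimate = co$estimate, or = co$or, p = co$p)
    }, error = function(e)
      data.frame(cutoff = cc, n_low = sum(dat$hi == 0), n_high = sum(dat$hi == 1),
                 estimate = NA_real_, or = NA_real_, p = NA_real_))
    res
  })
  grid_df <- do.call(rbind, rows)
  if (all(is.na(grid_df$p))) stop("every cutoff fit failed")
  best <- which.min(grid_df$p)  # ascending grid: first minimum = smaller cutoff
  structure(list(grid = grid_df,
                 optimal_cutoff = grid_df$cutoff[best],
                 optimal_p = grid_df$p[best],
                 median_cutoff = stats::median(cohort$suvmax),
                 model = model),
            class = "cutoff_scan_result")
}

#' @exportS3Method base::print
print.cutoff_scan_result <- function(x, ...) {
  cat(sprintf("<cutoff_scan_result> %s: %d candidates, optimal cutoff %.3g (p = %.3g), median %.3g\n",
              x$model, nrow(x$grid), x$optimal_cutoff, x$optimal_p,
              x$median_cutoff))
  invisible(x)
}

#' Univariate screening table for survival covariates
#'
#' Fits one single-covariate log-logistic AFT model per candidate and flags
#' covariates with Wald p below `alpha` for inclusion in a multivariate
#' Cox model. A covariate whose fit fails (e.g. constant) is marked
#' `failed` and the remaining candidates are still processed. Factor
#' covariates should be pre-encoded with their reference level documented
#' by the caller (e.g. resection reference = biopsy).
#'
#' @param cohort a `survival_cohort`.
#' @param candidate_covariates character vector of covariate columns.
#' @param alpha selection threshold for the multivariate step.
#' @return List with `table` (covariate, estimate, or, p, status) and
#'   `selected` (character vector with p < alpha).
#' @export
univariate_table <- function(cohort, candidate_covariates, alpha = 0.05) {
  cohort <- as_survival_cohort(cohort)
  rows <- lapply(candidate_covariates, function(cv) {
    tryCatch({
      f <- fit_loglogistic(cohort, cv)
      co <- f$coefficients[f$coefficients$term != "(Intercept)", , drop = FALSE]
      data.frame(covariate = cv, estimate = co$estimate[1], or = co$or[1],
                 p = co$p[1], status = "ok")
    }, error = function(e)
      data.frame(covariate = cv, estimate = NA_real_, or = NA_real_,
                 p = NA_real_, status = paste("failed:", conditionMessage(e))))
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       selected = tab$covariate[!is.na(tab$p) & tab$p < alpha])
}

#' Kaplan-Meier curve coordinates
#'
#' Convenience export of step-function coordinates for plotting stratified
#' survival, one row per event/censoring time per stratum.
#'
#' @param cohort a `survival_cohort`.
#' @param group optional factor splitting the cohort (e.g. from
#'   [median_split()]).
#' @return Data frame with columns `group`, `time`, `surv`, `n_risk`,
#'   `n_event`.
#' @export
km_coordinates <- function(cohort, group = NULL) {
  cohort <- as_survival_cohort(cohort)
  if (is.null(group)) group <- factor(rep("all", nrow(cohort)))
  sf <- survival::survfit(survival::Surv(time, event) ~ g,
                          data = data.frame(cohort, g = group))
  strata <- if (is.null(sf$strata)) setNames(length(sf$time), levels(group)[1])
            else sf$strata
  data.frame(group = rep(sub("^g=", "", names(strata)), strata),
             time = sf$time, surv = sf$surv,
             n_risk = sf$n.risk, n_event = sf$n.event)
}
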