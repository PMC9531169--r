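make_test_cohort <- function(n = 200, effect = 0.8, seed = 1, censor = 0) {
  make_survival_cohort(n = n, cutoff = 3, effect_log_scale = effect,
                       shape = 2, scale_base = 12, censor_rate = censor,
                       suv_range = c(1, 8), seed = seed)
}

test_that("the three-subject Cox worked example matches the closed form", {
  co <- as_survival_cohort(data.frame(time = c(1, 2, 3), event = c(1, 1, 1),
                                      suvmax = c(4, 2, 5), x = c(1, 0, 1)))
  fit <- fit_coxph(co, "x")
  expect_equal(fit$coefficients$estimate, -0.5 * log(2), tolerance = 1e-4)
  expect_equal(fit$coefficients$or, exp(-0.5 * log(2)), tolerance = 1e-4)
})

test_that("Cox fits recover a planted hazard ratio and reject constants", {
  betas <- vapply(1:5, function(seed) {
    set.seed(30 + seed)
    n <- 1000
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, rate = 0.05 * exp(log(2) * x))
    co <- as_survival_cohort(data.frame(time = t, event = 1,
                                        suvmax = runif(n), x = x))
    fit_coxph(co, "x")$coefficients$estimate
  }, numeric(1))
  expect_gt(mean(betas), 0.62)   # true log HR = ln 2 = 0.693
  expect_lt(mean(betas), 0.77)

  co <- as_survival_cohort(data.frame(time = rexp(20) + 0.1, event = 1,
                                      suvmax = runif(20), z = 0))
  expect_error(fit_coxph(co, "z"), "constant")
  expect_error(fit_coxph(co, character(0)), "covariate")
})

test_that("log-logistic AFT fit matches the grid-search oracle at n = 50", {
  co <- make_test_cohort(n = 50, effect = 0, seed = 17)
  fit <- fit_loglogistic(co)
  oracle <- grid_loglogistic_mle(co$time,
                                 alpha_grid = seq(6, 24, by = 0.05),
                                 beta_grid = seq(0.8, 4, by = 0.02))
  expect_lt(abs(fit$alpha - oracle$alpha), 0.05 + 1e-9)
  expect_lt(abs(fit$shape - oracle$beta), 0.02 + 1e-9)
  # model identity: S(alpha) = 1/2 by construction of the parameterization
  expect_equal(1 / (1 + (fit$alpha / fit$alpha)^fit$shape), 0.5)
})

test_that("log-logistic covariate effects are oriented as worse-survival > 1", {
  co <- make_test_cohort(n = 400, effect = 0.8, seed = 5)
  co$hi <- as.numeric(co$suvmax > 3)
  fit <- fit_loglogistic(co, "hi")
  hi <- fit$coefficients[fit$coefficients$term == "hi", ]
  expect_lt(hi$estimate, 0)        # acceleration: shorter times above cutoff
  expect_gt(hi$or, 1)              # reported effect > 1 = worse survival
  expect_lt(hi$p, 0.001)
  expect_error(fit_loglogistic(data.frame(time = 1:3, event = 0,
                                          suvmax = 1:3)), "no events")
})

test_that("median split uses a strict greater-than rule", {
  co <- as_survival_cohort(data.frame(time = 1:4, event = 1,
                                      suvmax = c(1, 2, 3, 4)))
  ms <- median_split(co)
  expect_equal(ms$cutoff, 2.5)
  expect_equal(as.vector(table(ms$group)), c(2, 2))

  odd <- as_survival_cohort(data.frame(time = 1:5, event = 1,
                                       suvmax = c(1, 2, 3, 4, 5)))
  ms2 <- median_split(odd)
  expect_equal(ms2$cutoff, 3)
  expect_equal(ms2$group[odd$suvmax == 3], factor("low", c("low", "high")))

  const <- as_survival_cohort(data.frame(time = 1:4, event = 1, suvmax = 2))
  expect_error(median_split(const), "constant")
})

test_that("the cutoff scan localizes a planted threshold and respects min_group", {
  err <- vapply(1:12, function(seed) {
    co <- make_test_cohort(n = 120, effect = 0.8, seed = 100 + seed)
    abs(scan_cutoffs(co, "loglogistic_aft", min_group = 5)$optimal_cutoff - 3)
  }, numeric(1))
  expect_lt(median(err), 0.3)  # localizes the cutoff within a few data gaps

  co <- make_test_cohort(n = 120, effect = 0.8, seed = 11, censor = 0.2)
  scan <- scan_cutoffs(co, model = "loglogistic_aft", min_group = 5)
  expect_true(scan$optimal_cutoff %in% scan$grid$cutoff)
  expect_true(all(scan$grid$n_low >= 5 & scan$grid$n_high >= 5))
  expect_equal(scan$optimal_p, min(scan$grid$p, na.rm = TRUE))
  expect_error(scan_cutoffs(co, min_group = 80), "min_group")
})

test_that("the scan's optimal p never exceeds the median-split p", {
  for (seed in c(2, 9, 23)) {
    co <- make_test_cohort(n = 80, effect = 0.5, seed = seed)
    scan <- scan_cutoffs(co, model = "loglogistic_aft", min_group = 5)
    ms <- median_split(co)
    co$hi <- as.numeric(ms$group == "high")
    med_p <- fit_loglogistic(co, "hi")$coefficients$p[2]
    expect_lte(scan$optimal_p, med_p + 1e-12)
  }
})

test_that("heavier censoring widens standard errors on average", {
  se_at <- function(censor, seeds) {
    mean(vapply(seeds, function(s) {
      co <- make_test_cohort(n = 150, effect = 0.5, seed = s, censor = censor)
      co$hi <- as.numeric(co$suvmax > 3)
      fit_loglogistic(co, "hi")$coefficients$se[2]
    }, numeric(1)))
  }
  expect_gt(se_at(0.5, 1:8), se_at(0, 1:8))
})

test_that("univariate screening selects the planted covariate and survives failures", {
  set.seed(13)
  co <- make_test_cohort(n = 150, effect = 0.9, seed = 3)
  co$hi <- as.numeric(co$suvmax > 3)       # strong planted covariate
  co$noise <- rnorm(nrow(co))              # null covariate
  co$flat <- 1                             # unfittable covariate
  res <- univariate_table(co, c("hi", "noise", "flat"), alpha = 0.05)
  expect_true("hi" %in% res$selected)
  expect_false("noise" %in% res$selected)
  expect_match(res$table$status[res$table$covariate == "flat"], "failed")
  expect_equal(res$table$status[res$table$covariate == "noise"], "ok")

  all_sel <- univariate_table(co, c("hi", "noise"), alpha = 1)
  expect_setequal(all_sel$selected, c("hi", "noise"))
})

test_that("Kaplan-Meier coordinates are a valid survival step function", {
  co <- make_test_cohort(n = 60, effect = 0.8, seed = 2, censor = 0.2)
  km <- km_coordinates(co, median_split(co)$group)
  expect_setequal(unique(km$group), c("low", "high"))
  for (g in unique(km$group)) {
    s <- km$surv[km$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
})
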