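test_that("noise-free phantom peak is the superposition at the hotspot center", {
  spec <- hotspot_spec(dims = c(21, 21, 21), background = 1, amplitude = 10,
                       sigma = 4, noise_sd = 0)
  ph <- make_pet_phantom(spec, demo_injection())
  expect_equal(max(ph$volume$values), 11)
  expect_equal(ph$truth$true_peak_activity, 11)
  # true SUVmax under 180 MBq / 72 kg: 11 / 2.5
  expect_equal(ph$truth$true_suvmax, 11 / 2.5)
})

test_that("half-max voxels of an isotropic hotspot match the analytic radius and brute-force count", {
  sigma <- 5
  spec <- hotspot_spec(dims = c(41, 41, 41), background = 0, amplitude = 10,
                       sigma = sigma, noise_sd = 0)
  ph <- make_pet_phantom(spec, demo_injection())
  vals <- ph$volume$values
  thr <- 0.5 * max(vals)
  n_brute <- brute_count_ge(as.vector(vals), thr)
  # half-max sphere radius sigma * sqrt(2 ln 2): every counted voxel is inside
  r <- sigma * sqrt(2 * log(2))
  ctr <- ceiling(dim(vals) / 2)
  idx <- which(vals >= thr, arr.ind = TRUE)
  d <- sqrt(rowSums((t(t(idx) - ctr))^2))
  expect_true(all(d <= r + 1e-9))
  # analytic sphere volume within one voxel-shell of the voxel count
  v_count <- n_brute * prod(spec$voxel_spacing_mm) / 1000
  v_analytic <- gaussian_isocontour_volume_ml(10, 0, sigma, 50)
  shell <- 4 * pi * r^2 * max(spec$voxel_spacing_mm) / 1000
  expect_lt(abs(v_count - v_analytic), shell)
  expect_equal(unname(ph$truth$true_isocontour_volumes_ml[["50"]]), v_count)
})

test_that("phantom noise is reproducible under the seed and varies across seeds", {
  s1 <- hotspot_spec(noise_sd = 0.5, seed = 11)
  s2 <- hotspot_spec(noise_sd = 0.5, seed = 12)
  a <- make_pet_phantom(s1, demo_injection())$volume$values
  b <- make_pet_phantom(s1, demo_injection())$volume$values
  c <- make_pet_phantom(s2, demo_injection())$volume$values
  expect_identical(a, b)
  expect_gt(max(abs(a - c)), 0)
  expect_true(all(a >= 0))  # clipped at zero
})

test_that("phantom_spec rejects invalid geometry", {
  expect_error(hotspot_spec(center = c(50, 5, 5)), "outside the grid")
  expect_error(hotspot_spec(sigma = 0), "sigmas")
  expect_error(hotspot_spec(noise_sd = -1), "noise_sd")
})

test_that("make_target_mask plants the requested conformity index", {
  spec <- hotspot_spec(dims = c(31, 31, 31), background = 1, amplitude = 10,
                       sigma = 5, noise_sd = 0)
  ph <- make_pet_phantom(spec, demo_injection())
  roi <- full_mask(c(31, 31, 31), spacing = c(1, 1, 1))
  iso40 <- isocontours(ph$volume, roi, 40)$masks[[1]]

  identity_mask <- make_target_mask(ph$volume, roi, 40, target_ci = 1)
  expect_identical(identity_mask$values, iso40$values)

  for (seed in 1:5) {
    m <- make_target_mask(ph$volume, roi, 40, target_ci = 0.33, seed = seed)
    expect_gte(brute_jaccard(m$values, iso40$values), 0.28)
    expect_lte(brute_jaccard(m$values, iso40$values), 0.38)
  }
})

test_that("make_target_mask rejects unreachable targets", {
  # a single-voxel contour cannot land inside the +/-0.05 band around 0.33
  vol <- image_volume(array(c(10, rep(0, 26)), c(3, 3, 3)), c(1, 1, 1),
                      unit = "activity_kBq_per_ml")
  roi <- full_mask(c(3, 3, 3), spacing = c(1, 1, 1))
  expect_error(make_target_mask(vol, roi, 70, target_ci = 0.33),
               "outside")
  expect_error(isocontours(vol, roi, 140), "levels")
})

test_that("survival cohort generator matches its closed-form moments", {
  # uncensored: empirical low-group median near the log-logistic scale
  co <- make_survival_cohort(n = 10000, cutoff = 3, effect_log_scale = 0.8,
                             shape = 2, scale_base = 12, censor_rate = 0,
                             suv_range = c(1, 8), seed = 42)
  lo <- co$time[co$suvmax <= 3]
  expect_lt(abs(median(lo) - 12) / 12, 0.03)
  expect_true(all(co$time > 0))
  expect_true(all(co$event == 1))

  # censoring calibration: ~70% events at censor_rate 0.3
  cc <- make_survival_cohort(n = 5000, cutoff = 3, effect_log_scale = 0.5,
                             shape = 2, scale_base = 12, censor_rate = 0.3,
                             suv_range = c(1, 8), seed = 7)
  expect_lt(abs(mean(cc$event) - 0.7), 0.05)
})

test_that("null survival cohorts have exchangeable groups", {
  co <- make_survival_cohort(n = 1000, cutoff = 3, effect_log_scale = 0,
                             shape = 2, scale_base = 12, censor_rate = 0,
                             suv_range = c(1, 8), seed = 5)
  r <- compare_groups_ranksum(co$time[co$suvmax > 3], co$time[co$suvmax <= 3])
  expect_gt(r$p, 0.01)
  expect_error(make_survival_cohort(10, 3, 0.5, 2, 12, suv_range = c(5, 5)),
               "degenerate")
})

test_that("expression study generator is reproducible and honours planting", {
  s1 <- make_expression_study(50, 12, 5, beta = 1, seed = 3)
  s2 <- make_expression_study(50, 12, 5, beta = 1, seed = 3)
  expect_identical(s1$expr, s2$expr)
  expect_equal(nrow(s1$planted), 5)
  expect_true(all(s1$planted$gene %in% rownames(s1$expr)))
  expect_error(make_expression_study(10, 2, 1, 1), "n_samples")
  expect_error(make_expression_study(10, 9, 11, 1), "n_planted")

  # strong planted signal is detectable by the grade-adjusted model
  st <- make_expression_study(30, 9, 3, beta = 2, residual_sd = 0.1,
                              patient_sd = 0, seed = 8)
  assoc <- associate_genes(st)
  planted_p <- assoc$p[assoc$gene %in% st$planted$gene]
  expect_true(all(planted_p < 0.001))
  expect_true(all(planted_p * 30 < 0.05))  # survives Bonferroni at m = 30
})
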