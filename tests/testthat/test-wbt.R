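test_that("MAD filter ranks by raw MAD with deterministic tie-breaking", {
  expr <- rbind(gene_a = c(1, 2, 3, 4, 5),          # MAD 1
                gene_b = c(0, 0, 10, 0, 0),          # MAD 0
                gene_c = c(-5, 0, 5, 10, 15),        # MAD 5
                gene_d = rep(2, 5))                  # constant, MAD 0
  samples <- data.frame(sample_id = paste0("s", 1:5),
                        patient_id = paste0("p", 1:5), timepoint = 1,
                        suvmax = 1:5, initial_grade = c(2, 2, 3, 3, 4))
  st <- expression_study(expr, samples)
  f1 <- mad_filter(st, 0.25)   # keep ceil(1) = 1 gene
  expect_identical(rownames(f1$expr), "gene_c")
  expect_equal(unname(f1$mad["gene_a"]), 1)  # median of |{-2,-1,0,1,2}| = 1
  expect_equal(unname(f1$mad["gene_d"]), 0)

  f2 <- mad_filter(st, 0.5)    # keep 2: gene_c then gene_a
  expect_setequal(rownames(f2$expr), c("gene_c", "gene_a"))
  # ties at the boundary (gene_b, gene_d both MAD 0) break by gene id
  f3 <- mad_filter(st, 0.75)
  expect_true("gene_b" %in% rownames(f3$expr))
  expect_false("gene_d" %in% rownames(f3$expr))
})

test_that("MAD filter is invariant to location shifts and global rescaling", {
  st <- make_expression_study(60, 10, 0, beta = 0, seed = 2)
  base <- rownames(mad_filter(st, 0.2)$expr)
  shifted <- st
  shifted$expr <- st$expr + matrix(rnorm(nrow(st$expr)) * 10, nrow(st$expr),
                                   ncol(st$expr))
  expect_identical(rownames(mad_filter(shifted, 0.2)$expr), base)
  scaled <- st
  scaled$expr <- st$expr * 3.7
  expect_identical(rownames(mad_filter(scaled, 0.2)$expr), base)
  expect_error(mad_filter(st, 0), "top_fraction")
})

test_that("grade-adjusted association recovers planted genes and controls multiplicity bookkeeping", {
  st <- make_expression_study(50, 9, 4, beta = 2, residual_sd = 0.1,
                              patient_sd = 0, seed = 21)
  assoc <- associate_genes(st)
  planted <- assoc[assoc$gene %in% st$planted$gene, ]
  expect_true(all(planted$p < 0.001))
  expect_true(all(planted$p_bonferroni < 0.05))
  expect_true(all(planted$coefficient > 1 & planted$coefficient < 3))
  # Bonferroni >= BH >= raw p, gene-wise
  ok <- !assoc$excluded
  expect_true(all(assoc$p_bonferroni[ok] >= assoc$q_bh[ok] - 1e-12))
  expect_true(all(assoc$q_bh[ok] >= assoc$p[ok] - 1e-12))
  # BH q-values computed by the package match the hand step-up
  expect_equal(assoc$q_bh[ok], bh_stepup(assoc$p[ok]))
})

test_that("constant genes are excluded without aborting; collinearity errors", {
  st <- make_expression_study(10, 8, 0, beta = 0, seed = 4)
  st$expr[3, ] <- 7
  assoc <- associate_genes(st)
  expect_true(assoc$excluded[3])
  expect_true(is.na(assoc$p[3]))
  expect_equal(sum(!assoc$excluded), 9)
  # Bonferroni multiplier counts only tested genes
  expect_equal(assoc$p_bonferroni[1], min(1, assoc$p[1] * 9))

  st2 <- st
  st2$samples$initial_grade <- st2$samples$suvmax  # exact collinearity
  expect_error(associate_genes(st2), "collinear")
})

test_that("mixed checkpoint model equals OLS when between-patient variance is zero", {
  # construct a singular-fit dataset: pure residual noise, no patient offsets
  set.seed(106)
  n_pat <- 8; n_tp <- 3
  samples <- data.frame(sample_id = paste0("s", 1:(n_pat * n_tp)),
                        patient_id = rep(paste0("p", 1:n_pat), each = n_tp),
                        timepoint = rep(1:n_tp, n_pat),
                        suvmax = runif(n_pat * n_tp, 1, 8),
                        initial_grade = rep(c(2, 3, 4, 2, 3, 4, 2, 3), each = n_tp))
  y <- 0.5 * samples$suvmax + rnorm(n_pat * n_tp, 0, 0.05)
  st <- expression_study(matrix(y, 1, dimnames = list("g1", samples$sample_id)),
                         samples)
  res <- mixed_checkpoint_model(st, "g1")
  ols <- ols_slope_z(y, samples$suvmax)
  expect_equal(res$slope, ols$slope, tolerance = 1e-6)
  expect_equal(res$p, ols$p, tolerance = 1e-6)
})

test_that("mixed model recovers a planted slope with patient offsets", {
  set.seed(9)
  n_pat <- 12; n_tp <- 3
  pat <- rep(seq_len(n_pat), each = n_tp)
  suv <- runif(n_pat * n_tp, 1, 8)
  offs <- rnorm(n_pat, 0, 1.5)
  y <- 1.5 * suv + offs[pat] + rnorm(n_pat * n_tp, 0, 0.5)
  samples <- data.frame(sample_id = seq_along(y),
                        patient_id = paste0("p", pat),
                        timepoint = rep(1:n_tp, n_pat),
                        suvmax = suv, initial_grade = 3)
  st <- expression_study(matrix(y, 1, dimnames = list("g1", NULL)), samples)
  res <- mixed_checkpoint_model(st, "g1")
  expect_lt(abs(res$slope - 1.5) / 1.5, 0.2)
  expect_equal(res$method, "lmm_reml")
  expect_error(mixed_checkpoint_model(st, "missing_gene"), "not in study")
})

test_that("single-timepoint studies fall back to OLS with a warning", {
  st <- make_expression_study(5, 10, 0, beta = 0,
                              n_timepoints_per_patient = 1, seed = 12)
  expect_warning(res <- mixed_checkpoint_model(st, rownames(st$expr)[1:2]),
                 "falling back")
  expect_equal(unique(res$method), "ols_fallback")
})

test_that("mixed-model null type-I error is near nominal with patient offsets", {
  set.seed(77)
  n_pat <- 10; n_tp <- 2
  pat <- rep(seq_len(n_pat), each = n_tp)
  reps <- 200
  pvals <- vapply(seq_len(reps), function(i) {
    suv <- runif(n_pat * n_tp, 1, 8)
    offs <- rnorm(n_pat, 0, 1)
    y <- offs[pat] + rnorm(n_pat * n_tp, 0, 0.5)
    samples <- data.frame(sample_id = seq_along(y),
                          patient_id = paste0("p", pat),
                          timepoint = rep(1:n_tp, n_pat),
                          suvmax = suv, initial_grade = 3)
    st <- expression_study(matrix(y, 1, dimnames = list("g1", NULL)), samples)
    mixed_checkpoint_model(st, "g1")$p
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.01)
  expect_lte(mean(pvals < 0.05), 0.12)
})
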