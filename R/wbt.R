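#' Construct an expression study from a matrix and sample table
#'
#' @param expr numeric genes x samples matrix with row and column names.
#' @param samples data frame with one row per column of `expr`: columns
#'   `sample_id`, `patient_id`, `timepoint`, `suvmax`, `initial_grade`.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(expr, samples) {
  expr <- as.matrix(expr)
  if (anyNA(expr)) stop("expression matrix contains missing values")
  req <- c("sample_id", "patient_id", "timepoint", "suvmax", "initial_grade")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("sample table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(samples) != ncol(expr))
    stop("sample table rows (", nrow(samples), ") != expression columns (",
         ncol(expr), ")")
  if (length(unique(samples$suvmax)) < 2)
    stop("need >= 2 distinct SUVmax values")
  structure(list(expr = expr, samples = samples,
                 planted = data.frame(gene = character(0),
                                      coefficient = numeric(0))),
            class = "expression_study")
}

#' Keep the most variable genes by median absolute deviation
#'
#' Ranks genes by raw MAD (median of absolute deviations from the gene
#' median, no 1.4826 consistency scaling — scaling does not change the
#' ranking) and keeps the top `ceiling(top_fraction * n_genes)`. Ties at
#' the boundary are broken by gene-id order. The filter is invariant to
#' per-gene location shifts and to positive rescaling of the whole matrix.
#'
#' @param study an `expression_study`.
#' @param top_fraction fraction of genes to keep, in (0, 1]; the standard
#'   analysis uses 0.10.
#' @return The filtered `expression_study`, with `mad` (named numeric, all
#'   genes) and `kept_by_mad` (named logical, all genes) attached.
#' @export
mad_filter <- function(study, top_fraction = 0.10) {
  stopifnot(inherits(study, "expression_study"))
  if (!(top_fraction > 0 && top_fraction <= 1))
    stop("top_fraction must be in (0, 1]")
  if (nrow(study$expr) == 0) stop("empty expression matrix")
  mads <- apply(study$expr, 1, stats::mad, constant = 1)
  k <- ceiling(top_fraction * nrow(study$expr))
  ord <- order(-mads, rownames(study$expr))
  keep_ids <- rownames(study$expr)[ord[seq_len(k)]]
  kept <- stats::setNames(rownames(study$expr) %in% keep_ids,
                          rownames(study$expr))
  out <- study
  out$expr <- study$expr[keep_ids, , drop = FALSE]
  out$planted <- study$planted[study$planted$gene %in% keep_ids, , drop = FALSE]
  out$mad <- mads
  out$kept_by_mad <- kept
  out
}

#' Grade-adjusted per-gene association with SUVmax
#'
#' For every gene, ordinary least squares of expression on per-sample
#' SUVmax plus initial WHO grade (as a numeric 2/3/4 covariate, matching
#' its ordinal use), with a two-sided t-test on the SUVmax coefficient.
#' Bonferroni adjustment and Benjamini-Hochberg q-values are computed over
#' the tested (non-constant) genes. Repeated blood draws enter as separate
#' samples here; within-patient correlation is modelled rigorously only in
#' [mixed_checkpoint_model()].
#'
#' @param study an `expression_study` (typically after [mad_filter()]).
#' @param grade_as_factor fit grade as an unordered factor instead of a
#'   numeric covariate.
#' @return Data frame (gene, coefficient, se, p, p_bonferroni, q_bh,
#'   kept_by_mad, excluded), one row per gene; constant genes are flagged
#'   `excluded` with NA statistics and do not count toward the
#'   multiplicity burden.
#' @export
associate_genes <- function(study, grade_as_factor = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  n <- ncol(study$expr)
  if (n < 3) stop("need >= 3 samples")
  suv <- study$samples$suvmax
  if (length(unique(suv)) < 2) stop("SUVmax is constant")
  grade <- study$samples$initial_grade
  X <- if (grade_as_factor && length(unique(grade)) > 1)
    stats::model.matrix(~ suv + factor(grade))
  else cbind(`(Intercept)` = 1, suv = suv, grade = as.numeric(grade))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("design is collinear (grade confounded with SUVmax)")
  df_res <- n - ncol(X)
  if (df_res < 1) stop("not enough samples for the grade-adjusted model")
  Y <- t(study$expr)  # samples x genes
  excluded <- apply(study$expr, 1, function(v) stats::var(v) == 0)
  coefs <- qr.coef(qr_x, Y)
  resid <- Y - X %*% coefs
  sigma2 <- colSums(resid^2) / df_res
  xtx_inv <- chol2inv(qr.R(qr_x))
  se_suv <- sqrt(sigma2 * xtx_inv[2, 2])
  beta_suv <- coefs[2, ]
  tval <- beta_suv / se_suv
  p <- 2 * stats::pt(-abs(tval), df_res)
  beta_suv[excluded] <- NA; se_suv[excluded] <- NA; p[excluded] <- NA
  m <- sum(!excluded)
  p_bonf <- pmin(1, p * m)
  q_bh <- rep(NA_real_, length(p))
  q_bh[!excluded] <- stats::p.adjust(p[!excluded], method = "BH")
  kept <- if (!is.null(study$kept_by_mad))
    unname(study$kept_by_mad[rownames(study$expr)]) else rep(TRUE, nrow(study$expr))
  data.frame(gene = rownames(study$expr),
             coefficient = unname(beta_suv), se = unname(se_suv),
             p = unname(p), p_bonferroni = unname(p_bonf),
             q_bh = q_bh, kept_by_mad = kept,
             excluded = unname(excluded), row.names = NULL)
}

#' Random-intercept models for selected (checkpoint) genes
#'
#' Per gene, a linear mixed model `expression ~ suvmax + (1 | patient)`
#' fitted by REML, with a Wald (normal-approximation) p-value on the
#' SUVmax slope — appropriate for repeated blood timepoints per patient.
#' When no patient has more than one timepoint the random intercept is
#' unidentifiable and the function falls back to ordinary least squares
#' (with the same normal-approximation Wald p) with a warning.
#'
#' @param study an `expression_study`.
#' @param gene_ids genes to model (must be rows of the matrix).
#' @return Data frame (gene, slope, se, p, method).
#' @export
mixed_checkpoint_model <- function(study, gene_ids) {
  stopifnot(inherits(study, "expression_study"))
  miss <- setdiff(gene_ids, rownames(study$expr))
  if (length(miss)) stop("genes not in study: ", paste(miss, collapse = ", "))
  tp_per_pat <- table(study$samples$patient_id)
  use_mixed <- sum(tp_per_pat >= 2) >= 2
  if (!use_mixed)
    warning("fewer than 2 patients with repeated timepoints; ",
            "falling back to ordinary least squares")
  suv <- study$samples$suvmax
  pat <- factor(study$samples$patient_id)
  rows <- lapply(gene_ids, function(g) {
    y <- study$expr[g, ]
    if (use_mixed) {
      fit <- suppressMessages(lme4::lmer(
        y ~ suv + (1 | pat),
        REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = "ignore",
                                    calc.derivs = FALSE)))
      est <- lme4::fixef(fit)[["suv"]]
      se <- sqrt(as.matrix(stats::vcov(fit))["suv", "suv"])
      method <- "lmm_reml"
    } else {
      fit <- stats::lm(y ~ suv)
      est <- stats::coef(fit)[["suv"]]
      se <- sqrt(stats::vcov(fit)["suv", "suv"])
      method <- "ols_fallback"
    }
    data.frame(gene = g, slope = est, se = se,
               p = 2 * stats::pnorm(-abs(est / se)), method = method)
  })
  do.call(rbind, rows)
}
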