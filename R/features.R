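#' Assemble the per-patient volumetric/uptake feature matrix
#'
#' For each isocontour level the concordance-derived features petvol_ml,
#' intersection_ml, union_ml, ci, dice, added_volume_ml and pct_increase
#' are collected, plus mrivol_ml, SUVmax and SURmax — with the default four
#' levels, 4 x 7 + 3 = 31 base columns (clinical feature sets typically add
#' further derived structures on top of these). Column order is
#' deterministic. A z-scaled copy (population sd) is attached; constant
#' columns are flagged and excluded from scaling.
#'
#' @param tables named list of `concordance_table` objects (names or
#'   `$patient` give patient ids).
#' @param metrics named list of `uptake_metrics`, one per patient.
#' @param grades named integer vector of tumor grades (2/3/4) per patient.
#' @return An object of class `feature_matrix`: `data` (data frame, rows =
#'   patients), `scaled` (matrix, constant columns dropped), `constant`
#'   (character vector of flagged columns), `grade` (integer vector).
#' @export
assemble_features <- function(tables, metrics, grades) {
  pid <- vapply(tables, function(tb) tb$patient, character(1))
  names(tables) <- pid
  missing_m <- setdiff(pid, names(metrics))
  missing_g <- setdiff(pid, names(grades))
  extra <- union(setdiff(names(metrics), pid), setdiff(names(grades), pid))
  if (length(missing_m) || length(missing_g) || length(extra))
    stop("patients not present in all inputs: ",
         paste(unique(c(missing_m, missing_g, extra)), collapse = ", "))
  levels_pct <- tables[[1]]$records$level_pct
  per_level_cols <- c("petvol_ml", "intersection_ml", "union_ml", "ci",
                      "dice", "added_volume_ml", "pct_increase")
  rows <- lapply(pid, function(p) {
    rec <- tables[[p]]$records
    if (!identical(rec$level_pct, levels_pct))
      stop("patient ", p, " has a different isocontour level set")
    v <- unlist(lapply(levels_pct, function(lev) {
      r <- rec[rec$level_pct == lev, per_level_cols]
      stats::setNames(as.numeric(r), paste0("I", lev, "_", per_level_cols))
    }))
    c(v, mrivol_ml = rec$mrivol_ml[1],
      suvmax = metrics[[p]]$suvmax, surmax = metrics[[p]]$surmax)
  })
  data <- as.data.frame(do.call(rbind, rows))
  rownames(data) <- pid
  const <- names(data)[vapply(data, function(x) stats::sd(x) == 0, logical(1))]
  keep <- setdiff(names(data), const)
  scaled <- vapply(keep, function(cn) {
    x <- data[[cn]]
    n <- length(x)
    (x - mean(x)) / (stats::sd(x) * sqrt((n - 1) / n))  # population sd
  }, numeric(nrow(data)))
  rownames(scaled) <- pid
  if (anyNA(data)) stop("feature matrix contains missing values")
  structure(list(data = data, scaled = scaled, constant = const,
                 grade = as.integer(grades[pid])),
            class = "feature_matrix")
}

#' Rank features by their ability to separate tumor grades
#'
#' Resampled random-forest importance: for each of `n_resamples`
#' grade-stratified 80% subsamples (without replacement) a random-forest
#' classifier of grade on the features is fitted and the permutation
#' importance (out-of-bag) recorded. Features are reported with their mean
#' importance across resamples and the frequency with which they rank
#' first. Permutation (not impurity) importance is used as it is less
#' biased toward high-cardinality features; tree ensembles make the
#' ranking invariant to monotone rescaling of individual features.
#'
#' @param fm a [assemble_features()] result, or a plain data frame of
#'   features (then `grade` must be supplied).
#' @param n_resamples number of resamples (default 200).
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @param grade integer grade vector when `fm` is a plain data frame.
#' @param num_trees trees per forest.
#' @return Data frame (feature, mean_importance, top_rank_frequency),
#'   ordered by decreasing mean importance.
#' @export
rank_features_by_grade <- function(fm, n_resamples = 200, seed = 1L,
                                   grade = NULL, num_trees = 200) {
  if (inherits(fm, "feature_matrix")) {
    feats <- fm$data
    grade <- fm$grade
  } else {
    feats <- as.data.frame(fm)
    if (is.null(grade)) stop("grade vector required for a plain feature data frame")
  }
  grade <- factor(grade)
  if (nlevels(grade) < 2) stop("need >= 2 distinct grades to rank features")
  if (any(table(grade) < 5))
    stop("need >= 5 patients per grade for stratified resampling")
  n <- nrow(feats)
  set.seed(as.integer(seed))
  feat_names <- colnames(feats)
  imp_sum <- stats::setNames(numeric(length(feat_names)), feat_names)
  top_count <- stats::setNames(numeric(length(feat_names)), feat_names)
  dat <- data.frame(.grade = grade, feats, check.names = FALSE)
  for (b in seq_len(n_resamples)) {
    idx <- unlist(lapply(levels(grade), function(g) {
      ig <- which(grade == g)
      sample(ig, max(2L, floor(0.8 * length(ig))))
    }))
    rf <- ranger::ranger(
      dependent.variable.name = ".grade",
      data = dat[idx, , drop = FALSE],
      num.trees = num_trees,
      importance = "permutation",
      num.threads = 1,
      seed = sample.int(.Machine$integer.max, 1))
    imp <- rf$variable.importance[feat_names]
    imp_sum <- imp_sum + imp
    top_count[which.max(imp)] <- top_count[which.max(imp)] + 1
  }
  out <- data.frame(feature = feat_names,
                    mean_importance = unname(imp_sum) / n_resamples,
                    top_rank_frequency = unname(top_count) / n_resamples)
  out[order(-out$mean_importance, out$feature), , drop = FALSE]
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 12 and there
#' are no ties; normal approximation (with tie correction and continuity
#' correction) otherwise. The `method` argument can force either path.
#'
#' @param x,y numeric samples (both non-empty).
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (x relative
#'   to y).
#' @param method `"auto"` (default rule), `"exact"` or `"normal"`.
#' @return List with `statistic` (Mann-Whitney W for x) and `p`.
#' @export
compare_groups_ranksum <- function(x, y,
                                   alternative = c("two_sided", "less", "greater"),
                                   method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  alt <- if (alternative == "two_sided") "two.sided" else alternative
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(method,
                  auto = (length(x) + length(y) <= 12) && !ties,
                  exact = TRUE,
                  normal = FALSE)
  if (exact && ties) stop("exact rank-sum p is unavailable with ties")
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = exact,
                       correct = !exact))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}
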