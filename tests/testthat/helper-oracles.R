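# Independent oracles used across the suite. These deliberately avoid the
# package's computation paths.

# Jaccard / Dice by explicit voxel-index set operations.
brute_jaccard <- function(a, b) {
  ia <- which(a); ib <- which(b)
  n_int <- length(intersect(ia, ib))
  n_uni <- length(union(ia, ib))
  if (n_uni == 0) return(NA_real_)
  n_int / n_uni
}

brute_dice <- function(a, b) {
  ia <- which(a); ib <- which(b)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# Count voxels at or above a threshold by an explicit loop.
brute_count_ge <- function(values, thr) {
  n <- 0L
  for (v in values) if (v >= thr) n <- n + 1L
  n
}

# Exact one-sided rank-sum p by enumeration of all group assignments.
enumerate_ranksum_p <- function(x, y, alternative = "less") {
  all_v <- c(x, y)
  n1 <- length(x)
  obs <- sum(rank(all_v)[seq_len(n1)])
  combos <- utils::combn(length(all_v), n1)
  sums <- apply(combos, 2, function(idx) sum(rank(all_v)[idx]))
  switch(alternative,
         less = mean(sums <= obs),
         greater = mean(sums >= obs),
         two_sided = min(1, 2 * min(mean(sums <= obs), mean(sums >= obs))))
}

# Benjamini-Hochberg step-up computed directly from its definition.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, q)
}

# Two-parameter grid-search MLE for an uncensored log-logistic sample.
# Density f(t) = (b/a) (t/a)^(b-1) / (1 + (t/a)^b)^2.
grid_loglogistic_mle <- function(t, alpha_grid, beta_grid) {
  n <- length(t)
  slt <- sum(log(t))
  best <- c(NA, NA); best_ll <- -Inf
  for (b in beta_grid) {
    tb <- t^b
    ab <- alpha_grid^b
    mat <- outer(tb, ab, "/")            # n x length(alpha_grid)
    ll <- n * log(b) - n * b * log(alpha_grid) + (b - 1) * slt -
      2 * colSums(log1p(mat))
    j <- which.max(ll)
    if (ll[j] > best_ll) { best_ll <- ll[j]; best <- c(alpha_grid[j], b) }
  }
  list(alpha = best[1], beta = best[2], loglik = best_ll)
}

# OLS slope with a normal-approximation Wald p (the convention the mixed
# checkpoint model uses), computed from first principles.
ols_slope_z <- function(y, x) {
  xc <- x - mean(x); yc <- y - mean(y)
  b <- sum(xc * yc) / sum(xc^2)
  res <- yc - b * xc
  se <- sqrt(sum(res^2) / (length(y) - 2) / sum(xc^2))
  list(slope = b, se = se, p = 2 * pnorm(-abs(b / se)))
}

# Small builders -------------------------------------------------------

demo_injection <- function(...) {
  injection_record(injected_activity_MBq = 180, body_weight_kg = 72,
                   injection_time = "2021-01-01T09:00:00",
                   acquisition_time = "2021-01-01T09:12:00", ...)
}

# A uniform-valued SUV volume.
uniform_suv <- function(value, dims = c(8, 8, 8), spacing = c(2, 2, 2)) {
  image_volume(array(value, dims), spacing, unit = "suv")
}

full_mask <- function(dims = c(8, 8, 8), spacing = c(2, 2, 2), role = "roi") {
  pet_mask(array(TRUE, dims), spacing, role = role)
}

box_mask <- function(dims, i, j, k, spacing = c(1, 1, 1), role = "roi") {
  v <- array(FALSE, dims)
  v[i, j, k] <- TRUE
  pet_mask(v, spacing, role = role)
}

random_mask <- function(dims, p = 0.3, role = "roi") {
  pet_mask(array(runif(prod(dims)) < p, dims), spacing = c(1, 1, 1), role = role)
}

# One isotropic hotspot phantom on a zero background (noise optional).
hotspot_spec <- function(dims = c(31, 31, 31), spacing = c(1, 1, 1),
                         background = 0, amplitude = 10, sigma = 5,
                         noise_sd = 0, seed = 1L,
                         center = ceiling(dims / 2)) {
  phantom_spec(dims, spacing, background,
               list(list(center = center, sigma_mm = sigma,
                         amplitude = amplitude)),
               noise_sd = noise_sd, seed = seed)
}
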