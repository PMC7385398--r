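# Independent oracles: deliberately naive implementations used to
# freeze expected values. They share no code with the package paths
# they check.

# Kendall's W by explicit ranking of each series, no vectorization.
oracle_kendall_w <- function(series_list) {
  K <- length(series_list)
  n <- length(series_list[[1]])
  R <- sapply(series_list, rank)          # n x K, average ties
  S <- rowSums(R)
  12 * sum((S - mean(S))^2) / (K^2 * (n^3 - n))
}

# Least-squares residuals via the normal equations.
oracle_ls_residuals <- function(y, X) {
  X <- cbind(1, X)
  y - X %*% solve(t(X) %*% X, t(X) %*% y)
}

# Classical pooled-variance two-sample t.
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# AUC by O(n^2) pairwise comparison, ties counting one half.
oracle_auc <- function(decision, positive) {
  dp <- decision[positive]; dn <- decision[!positive]
  tot <- 0
  for (a in dp) for (b in dn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(dp) * length(dn))
}

# Weighted degree by an explicit loop over edges.
oracle_weighted_degree <- function(edge_index, t_values, sig, n_regions) {
  pos <- neg <- numeric(n_regions)
  for (e in seq_along(t_values)) {
    if (!sig[e]) next
    for (r in c(edge_index$i[e], edge_index$j[e])) {
      if (t_values[e] > 0) pos[r] <- pos[r] + t_values[e]
      else neg[r] <- neg[r] + t_values[e]
    }
  }
  list(positive = pos, negative = neg)
}

# A fast, small stated world for unit tests.
tiny_spec <- function(seed = 1, ...) {
  defaults <- list(n_male = 6, n_female = 6, grid_shape = c(8L, 8L, 8L),
                   n_regions = 4, n_timepoints = 24,
                   gmv_effect_clusters = list(
                     list(center = c(4, 4, 4), radius = 1, d = 1.5)),
                   reho_effect_clusters = list(
                     list(center = c(5, 4, 5), radius = 1, d = 1.5)),
                   fc_effect_edges = list(
                     list(i = 1, j = 2, delta = 0.4)),
                   seed = seed)
  # name-wise override (modifyList would merge nested lists)
  args <- list(...)
  args$seed <- seed
  for (nm in setdiff(names(defaults), names(args)))
    args[[nm]] <- defaults[[nm]]
  do.call(cohort_spec, args)
}

# Two Gaussian classes with n_inf informative features at per-feature
# standardized difference d_per. The default (d = 4 per informative
# feature) is a well-separated world where any sane linear classifier
# should approach perfect accuracy.
sep_features <- function(n_per = 40, p = 50, n_inf = 10, d_per = 4,
                         seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per)
  y <- rep(c("male", "female"), each = n_per)
  X[y == "male", seq_len(n_inf)] <- X[y == "male", seq_len(n_inf)] + d_per
  list(X = feature_matrix(X, "gmv"), y = y)
}

# Random full-mask BOLD cube around a voxel, for KCC oracle tests.
random_cube_run <- function(n_timepoints = 20) {
  bold_run(array(rnorm(27 * n_timepoints), c(3, 3, 3, n_timepoints)),
           tr_seconds = 2)
}
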