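# Mass-univariate group statistics: voxel-wise and edge-wise GLM
# two-sample comparisons with covariates, family-wise error control
# (Bonferroni or max-statistic permutation), and the weighted-degree
# summary of significant edges.

# Vectorized GLM over columns of Y (n x V): value ~ intercept + gender
# + covariates. Returns the gender-coefficient t per column. Gender is
# coded female = 1, male = 0, so positive t means female > male.
glm_t_columns <- function(Y, gender, covariates = NULL) {
  g <- as.numeric(gender == "female")
  if (length(unique(g)) < 2) stop("both groups must be present")
  if (min(table(g)) < 2) stop("each group needs at least 2 subjects")
  X <- cbind(intercept = 1, gender = g)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  n <- nrow(X); p <- ncol(X)
  beta <- qr.coef(qx, Y)
  resid <- Y - X %*% beta
  dof <- n - p
  sigma2 <- colSums(resid^2) / dof
  xtxinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtxinv[2, 2])
  t <- beta[2, ] / se
  # constant (or exactly-fitted) columns: residual variance is zero up
  # to float noise and the t ratio is meaningless
  scale2 <- colMeans(Y^2)
  degenerate <- !is.finite(t) | sigma2 <= 1e-24 * (scale2 + 1e-300)
  if (any(degenerate)) {
    warning(sum(degenerate),
            " column(s) with zero residual variance; t set to 0")
    t[degenerate] <- 0
  }
  list(t = t, dof = dof,
       p = 2 * stats::pt(-abs(t), dof))
}

maps_to_matrix <- function(maps, mask) {
  vidx <- which(mask)
  do.call(rbind, lapply(maps, function(m) m$values[vidx]))
}

#' Voxel-wise group-difference t-map with covariates
#'
#' Fits `value ~ intercept + gender + covariates` by least squares at
#' every in-mask voxel and returns the t statistic of the gender
#' coefficient. Sign convention is female-minus-male: positive t means
#' larger values in females.
#'
#' @param maps named list of per-subject `volume_map`s sharing one grid
#'   and mask.
#' @param gender character vector (`"male"`/`"female"`), one per map.
#' @param covariates optional data.frame/matrix of per-subject
#'   covariates (e.g. age, education).
#' @param mask optional analysis mask; defaults to the first map's.
#' @return An object of class `tmap`: list with `t_values` and
#'   `p_values` (`volume_map`s), `dof`, `sig_mask` (NULL until
#'   [fwe_correct()]), and `contrast` (`"female_minus_male"`).
#' @export
glm_group_tmap <- function(maps, gender, covariates = NULL, mask = NULL) {
  stopifnot(length(maps) == length(gender))
  if (is.null(mask)) mask <- maps[[1]]$mask
  if (inherits(mask, "volume_map")) mask <- mask$mask
  Y <- maps_to_matrix(maps, mask)
  fit <- glm_t_columns(Y, gender, covariates)
  d <- dim(maps[[1]]$values)
  tv <- array(0, d); tv[which(mask)] <- fit$t
  pv <- array(1, d); pv[which(mask)] <- fit$p
  structure(list(
    t_values = volume_map(tv, mask, maps[[1]]$voxel_size_mm),
    p_values = volume_map(pv, mask, maps[[1]]$voxel_size_mm),
    dof = fit$dof, sig_mask = NULL,
    contrast = "female_minus_male"), class = "tmap")
}

#' @export
print.tmap <- function(x, ...) {
  tv <- x$t_values$values[x$t_values$mask]
  cat("<tmap> ", length(tv), " voxels, dof = ", x$dof,
      ", |t| range ", signif(min(abs(tv)), 3), "..",
      signif(max(abs(tv)), 3),
      if (!is.null(x$sig_mask))
        paste0(", ", sum(x$sig_mask$values > 0), " significant"),
      "\n", sep = "")
  invisible(x)
}

#' Family-wise error correction of a voxel-wise t-map
#'
#' Two methods. `"bonferroni"`: significant where `p <= alpha / V`
#' (V = mask voxels). `"max_t_permutation"`: gender labels are permuted
#' wholesale `n_perm` times, the t-map recomputed each time, and the
#' observed |t| compared against the `(1 - alpha)` quantile of the
#' permutation distribution of the maximum |t| (two-sided, strong FWE
#' control without distributional assumptions). The permutation method
#' needs the per-subject maps and design to recompute t-maps.
#'
#' @param tmap a `tmap` from [glm_group_tmap()].
#' @param method `"max_t_permutation"` (default) or `"bonferroni"`.
#' @param alpha family-wise alpha in (0, 1).
#' @param maps,gender,covariates the inputs of [glm_group_tmap()];
#'   required for the permutation method.
#' @param n_perm number of permutations (must be >= 1/alpha).
#' @param seed integer seed for the permutations.
#' @return The `tmap` with `sig_mask` (binary `volume_map`) filled in,
#'   plus `fwe_method`, `fwe_alpha` and (for permutation) `t_threshold`
#'   and `max_t_null`.
#' @export
fwe_correct <- function(tmap, method = c("max_t_permutation", "bonferroni"),
                        alpha = 0.05, maps = NULL, gender = NULL,
                        covariates = NULL, n_perm = 1000, seed = 1) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1)
  mask <- tmap$t_values$mask
  V <- sum(mask)
  d <- dim(tmap$t_values$values)
  sig <- array(0, d)
  if (method == "bonferroni") {
    sig[mask] <- as.numeric(tmap$p_values$values[mask] <= alpha / V)
    tmap$sig_mask <- volume_map(sig, mask, tmap$t_values$voxel_size_mm)
    tmap$fwe_method <- "bonferroni"
    tmap$fwe_alpha <- alpha
    return(tmap)
  }
  if (is.null(maps) || is.null(gender))
    stop("max_t_permutation needs `maps` and `gender`")
  if (n_perm < 1 / alpha)
    stop("n_perm must be at least 1/alpha = ", ceiling(1 / alpha))
  Y <- maps_to_matrix(maps, mask)
  set.seed(as.integer(seed))
  maxt <- vapply(seq_len(n_perm), function(i) {
    gperm <- sample(gender)
    max(abs(suppressWarnings(
      glm_t_columns(Y, gperm, covariates))$t))
  }, numeric(1))
  thr <- sort(maxt)[ceiling((1 - alpha) * n_perm)]
  sig[mask] <- as.numeric(abs(tmap$t_values$values[mask]) >= thr)
  tmap$sig_mask <- volume_map(sig, mask, tmap$t_values$voxel_size_mm)
  tmap$fwe_method <- "max_t_permutation"
  tmap$fwe_alpha <- alpha
  tmap$t_threshold <- thr
  tmap$max_t_null <- maxt
  tmap
}

#' Uncorrected trend mask at a voxel-wise p threshold
#'
#' Convenience for the "trend" maps (two-sided p < 0.001 uncorrected)
#' used by the overlap analysis.
#'
#' @param tmap a `tmap`.
#' @param p_threshold uncorrected two-sided p threshold.
#' @return Binary `volume_map`.
#' @export
trend_mask <- function(tmap, p_threshold = 0.001) {
  mask <- tmap$p_values$mask
  d <- dim(tmap$p_values$values)
  sig <- array(0, d)
  sig[mask] <- as.numeric(tmap$p_values$values[mask] < p_threshold)
  volume_map(sig, mask, tmap$p_values$voxel_size_mm)
}

#' Edge-wise group comparison of functional connectivity
#'
#' The same GLM as [glm_group_tmap()], run on the Fisher-z value of
#' every unordered region pair, with Bonferroni family control: an edge
#' is significant where `p <= alpha_family / E`, `E = R(R-1)/2` (for
#' 116 regions, 0.05/6670 = 7.5e-6). Set `covariates = NULL` for a
#' plain two-sample t.
#'
#' @param fc_list list of per-subject `fc_matrix` objects with
#'   identical region ordering.
#' @param gender character vector, one per subject.
#' @param covariates optional per-subject covariates.
#' @param alpha_family family-wise alpha (default 0.05).
#' @return An object of class `edge_stats`: `t_values`, `p_values`,
#'   `sig_mask` (logical), `edge_index` (data.frame `i`,`j`), `dof`,
#'   `n_edges`, `region_labels`, `alpha_family`.
#' @export
edge_group_tests <- function(fc_list, gender, covariates = NULL,
                             alpha_family = 0.05) {
  labs <- fc_list[[1]]$region_labels
  for (fc in fc_list)
    if (!identical(fc$region_labels, labs))
      stop("subjects have inconsistent region sets")
  Z <- do.call(rbind, lapply(fc_list, edge_vector))
  fit <- glm_t_columns(Z, gender, covariates)
  E <- ncol(Z)
  structure(list(
    t_values = fit$t, p_values = fit$p,
    sig_mask = fit$p <= alpha_family / E,
    edge_index = edge_index(length(labs)),
    dof = fit$dof, n_edges = E, region_labels = labs,
    alpha_family = alpha_family), class = "edge_stats")
}

#' @export
print.edge_stats <- function(x, ...) {
  cat("<edge_stats> ", x$n_edges, " edges over ",
      length(x$region_labels), " regions, ", sum(x$sig_mask),
      " significant at ", x$alpha_family, "/", x$n_edges, "\n", sep = "")
  invisible(x)
}

#' Positive and negative weighted degree per region
#'
#' For each region, the positive weighted degree is the sum of the
#' positive t-values over that region's significant edges and the
#' negative weighted degree the sum of the negative t-values; only
#' edges in `sig_mask` contribute. Positive degree marks connections
#' stronger in females, negative stronger in males.
#'
#' @param edges an `edge_stats` object.
#' @return data.frame with `region`, `positive_degree` (>= 0),
#'   `negative_degree` (<= 0).
#' @export
weighted_degree <- function(edges) {
  R <- length(edges$region_labels)
  pos <- neg <- numeric(R)
  sig <- which(edges$sig_mask)
  for (e in sig) {
    i <- edges$edge_index$i[e]; j <- edges$edge_index$j[e]
    t <- edges$t_values[e]
    if (t > 0) { pos[i] <- pos[i] + t; pos[j] <- pos[j] + t }
    else       { neg[i] <- neg[i] + t; neg[j] <- neg[j] + t }
  }
  data.frame(region = edges$region_labels,
             positive_degree = pos, negative_degree = neg)
}

#' Pooled-variance two-sample t-test
#'
#' Classical equal-variance two-sample t with two-sided p; the
#' work-horse behind the demographics comparison.
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @return list with `t` (mean(x) - mean(y) scaled), `p`, `dof`.
#' @export
pooled_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs at least 2 values")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  if (!is.finite(t)) t <- 0
  list(t = t, p = 2 * stats::pt(-abs(t), nx + ny - 2),
       dof = nx + ny - 2)
}

#' Group comparison of a demographic field
#'
#' Pooled-variance two-sample t-test of `age` or `education` between
#' the male group (first) and the female group.
#'
#' @param table subject table with `gender` and the field.
#' @param field `"age"` or `"education"`.
#' @return list with `t`, `p`, `dof`.
#' @export
demographics_test <- function(table, field = c("age", "education")) {
  field <- match.arg(field)
  x <- table[[field]][table$gender == "male"]
  y <- table[[field]][table$gender == "female"]
  pooled_t_test(x, y)
}

#' Cluster summary of a significant t-map
#'
#' Labels the connected components (6-connectivity) of the significance
#' mask and reports each cluster's size, peak |t| and peak voxel index,
#' mirroring the usual peak-coordinate tables. Coordinates are 1-based
#' voxel indices on the synthetic grid.
#'
#' @param tmap a `tmap` with `sig_mask` filled in.
#' @return data.frame with one row per cluster.
#' @export
cluster_summary <- function(tmap) {
  if (is.null(tmap$sig_mask)) stop("run fwe_correct() first")
  sig <- tmap$sig_mask$values > 0
  d <- dim(sig)
  lab <- array(0L, d)
  nextlab <- 0L
  idx <- which(sig)
  for (v in idx) {
    if (lab[v] > 0L) next
    nextlab <- nextlab + 1L
    queue <- v
    lab[v] <- nextlab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      co <- arrayInd(cur, d)
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        nb <- co; nb[ax] <- nb[ax] + s
        if (nb[ax] < 1 || nb[ax] > d[ax]) next
        ni <- nb[1] + d[1] * (nb[2] - 1 + d[2] * (nb[3] - 1))
        if (sig[ni] && lab[ni] == 0L) {
          lab[ni] <- nextlab
          queue <- c(queue, ni)
        }
      }
    }
  }
  if (nextlab == 0L)
    return(data.frame(cluster = integer(0), n_voxels = integer(0),
                      peak_t = numeric(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z = integer(0)))
  out <- lapply(seq_len(nextlab), function(k) {
    vox <- which(lab == k)
    tv <- tmap$t_values$values[vox]
    pk <- vox[which.max(abs(tv))]
    co <- arrayInd(pk, d)
    data.frame(cluster = k, n_voxels = length(vox),
               peak_t = tv[which.max(abs(tv))],
               peak_x = co[1], peak_y = co[2], peak_z = co[3])
  })
  do.call(rbind, out)
}
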