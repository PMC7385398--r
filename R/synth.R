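#' Specify a synthetic two-group cohort
#'
#' A `cohort_spec` is the complete stated world for one synthetic study:
#' group sizes, grid geometry, atlas size, acquisition length, planted
#' effects and nuisance structure. Defaults mirror the emulated study:
#' 135 males and 155 females aged 18-29, 180 volumes at TR = 2 s, a
#' 24x24x24 grid (3 mm voxels) with an ellipsoidal brain mask of roughly
#' 5,000 voxels partitioned into 12 regions.
#'
#' Effect clusters are spheres given as `list(center = c(x, y, z),
#' radius = r, d = effect)` with voxel-index centers (1-based). For GMV
#' clusters `d` is the Cohen-type standardized mean difference
#' (female minus male, in units of `noise_sd`). For ReHo clusters `d` is
#' mapped to an increment of the local shared-signal weight,
#' `delta_c = 0.1 * d`, applied to the female group (see the methods
#' vignette for the variance-share rationale). FC effect edges are
#' `list(i = , j = , delta = )` with `delta` the female-minus-male
#' difference in latent inter-region correlation.
#'
#' @param n_male,n_female positive subject counts.
#' @param grid_shape integer vector of 3 positive grid dimensions.
#' @param voxel_size_mm positive voxel edge length (mm).
#' @param n_regions number of atlas regions (>= 2).
#' @param n_timepoints number of BOLD volumes (>= 8).
#' @param tr_seconds repetition time (s).
#' @param gmv_effect_clusters,reho_effect_clusters lists of effect
#'   spheres (see Details).
#' @param fc_effect_edges list of edge effects (see Details).
#' @param confound_slopes named list with elements `age` and `education`
#'   giving the per-year slope added to every GMV voxel.
#' @param noise_sd positive observation noise SD for GMV maps.
#' @param gmv_baseline baseline gray-matter value inside the mask.
#' @param local_coherence_base base weight of the shared local signal in
#'   BOLD voxel series, in [0, 1).
#' @param region_signal_weight weight of the region latent signal in
#'   BOLD voxel series.
#' @param base_fc latent correlation between all region pairs before
#'   planted deltas.
#' @param seed integer master seed; all generator randomness derives
#'   from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_male = 135, n_female = 155,
                        grid_shape = c(24L, 24L, 24L),
                        voxel_size_mm = 3,
                        n_regions = 12,
                        n_timepoints = 180,
                        tr_seconds = 2,
                        gmv_effect_clusters = list(
                          list(center = c(9, 9, 12), radius = 3, d = 1.5),
                          list(center = c(16, 16, 12), radius = 3, d = -1.5)),
                        reho_effect_clusters = list(
                          list(center = c(12, 9, 15), radius = 3, d = 1.5)),
                        fc_effect_edges = list(
                          list(i = 1, j = 2, delta = 0.4),
                          list(i = 3, j = 4, delta = -0.3)),
                        confound_slopes = list(age = -0.003,
                                               education = 0.001),
                        noise_sd = 0.1,
                        gmv_baseline = 0.6,
                        local_coherence_base = 0.3,
                        region_signal_weight = 0.4,
                        base_fc = 0.1,
                        seed = 1L) {
  stopifnot(n_male >= 1, n_female >= 1,
            length(grid_shape) == 3, all(grid_shape >= 1),
            voxel_size_mm > 0, n_regions >= 2,
            n_timepoints >= 8, tr_seconds > 0, noise_sd > 0,
            local_coherence_base >= 0, local_coherence_base < 1)
  for (cl in c(gmv_effect_clusters, reho_effect_clusters)) {
    if (any(cl$center < 1) || any(cl$center > grid_shape))
      stop("effect cluster center outside the grid")
  }
  for (e in fc_effect_edges) {
    stopifnot(e$i >= 1, e$j >= 1, e$i <= n_regions, e$j <= n_regions,
              e$i != e$j)
    if (abs(base_fc + e$delta) >= 1)
      stop("fc delta drives a target correlation outside (-1, 1)")
  }
  spec <- list(n_male = as.integer(n_male), n_female = as.integer(n_female),
               grid_shape = as.integer(grid_shape),
               voxel_size_mm = voxel_size_mm,
               n_regions = as.integer(n_regions),
               n_timepoints = as.integer(n_timepoints),
               tr_seconds = tr_seconds,
               gmv_effect_clusters = gmv_effect_clusters,
               reho_effect_clusters = reho_effect_clusters,
               fc_effect_edges = fc_effect_edges,
               confound_slopes = confound_slopes,
               noise_sd = noise_sd, gmv_baseline = gmv_baseline,
               local_coherence_base = local_coherence_base,
               region_signal_weight = region_signal_weight,
               base_fc = base_fc,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

# Named substreams keep the stages independently reproducible while all
# randomness flows from the one master seed. Result stays below 2^31.
substream_seed <- function(seed, stage) {
  offsets <- c(table = 101L, gmv = 202L, bold = 303L, motion = 404L,
               folds = 505L, perm = 606L, fwe = 707L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

#' Ellipsoidal brain mask for a synthetic grid
#'
#' Semi-axes are 0.45 of each grid dimension, centered; on the default
#' 24-cube this gives roughly 5,200 in-mask voxels.
#'
#' @param grid_shape integer vector of 3.
#' @param voxel_size_mm voxel size passed through to the container.
#' @return A binary `volume_map`.
#' @export
make_brain_mask <- function(grid_shape, voxel_size_mm = 3) {
  d <- grid_shape
  ctr <- (d + 1) / 2
  ax <- 0.45 * d
  co <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                              z = seq_len(d[3])))
  r2 <- ((co[, 1] - ctr[1]) / ax[1])^2 + ((co[, 2] - ctr[2]) / ax[2])^2 +
    ((co[, 3] - ctr[3]) / ax[3])^2
  m <- array(r2 <= 1, d)
  volume_map(array(as.numeric(m), d), mask = m,
             voxel_size_mm = voxel_size_mm)
}

#' Deterministic parcellation of a mask into regions
#'
#' In-mask voxels are ordered by (z, y, x) and chopped into
#' `n_regions` contiguous, near-equal slabs. This is not anatomy; it is
#' a deterministic partition that guarantees every region is nonempty
#' and reproducible without randomness.
#'
#' @param mask a binary `volume_map` (or logical array).
#' @param n_regions number of regions; must not exceed mask size.
#' @param voxel_size_mm voxel size for the returned label volume.
#' @return An integer-valued `volume_map` with labels 1..n_regions
#'   inside the mask and 0 outside.
#' @export
make_atlas <- function(mask, n_regions, voxel_size_mm = 3) {
  m <- if (inherits(mask, "volume_map")) mask$mask else mask
  v <- sum(m)
  if (n_regions > v) stop("more regions than mask voxels")
  ord <- which(m)                       # column-major = x fastest, z slowest
  lab <- as.integer(cut(seq_along(ord), breaks = n_regions, labels = FALSE))
  vol <- array(0L, dim(m))
  vol[ord] <- lab
  volume_map(vol, mask = m, voxel_size_mm = voxel_size_mm)
}

sphere_mask <- function(grid_shape, center, radius) {
  co <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                              y = seq_len(grid_shape[2]),
                              z = seq_len(grid_shape[3])))
  d2 <- (co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 +
    (co[, 3] - center[3])^2
  array(d2 <= radius^2, grid_shape)
}

clusters_mask <- function(grid_shape, clusters, brain_mask) {
  out <- array(FALSE, grid_shape)
  for (cl in clusters) {
    sm <- sphere_mask(grid_shape, cl$center, cl$radius)
    if (!any(sm & brain_mask))
      stop("effect cluster falls entirely outside the brain mask")
    out <- out | (sm & brain_mask)
  }
  out
}

#' Generate the subject demographics table
#'
#' Ages are uniform on [18, 29] in both groups. Education (years) is
#' uniform on group mean +/- 2 SD with group means 15.13 (male) / 15.86
#' (female) and SDs 2.33 / 2.61, matching the emulated cohort's printed
#' summary statistics; uniform draws are used because only ranges and
#' moments, not distributions, are stated.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `id`, `gender`, `age`, `education`.
#' @export
generate_subject_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(substream_seed(spec$seed, "table"))
  n <- spec$n_male + spec$n_female
  gender <- rep(c("male", "female"), c(spec$n_male, spec$n_female))
  age <- stats::runif(n, 18, 29)
  edu_mean <- ifelse(gender == "male", 15.13, 15.86)
  edu_sd <- ifelse(gender == "male", 2.33, 2.61)
  education <- stats::runif(n, edu_mean - 2 * edu_sd, edu_mean + 2 * edu_sd)
  data.frame(id = sprintf("sub-%03d", seq_len(n)),
             gender = gender, age = age, education = education,
             stringsAsFactors = FALSE)
}

#' Generate per-subject gray-matter-volume maps with planted effects
#'
#' Each in-mask voxel is `baseline + I(female) * d * noise_sd *
#' I(cluster) + (age - 23) * slope_age + (education - 15.5) * slope_edu +
#' N(0, noise_sd)`, clipped at zero. Covariates are centered so the
#' baseline is the cohort-typical value.
#'
#' @param spec a [cohort_spec()].
#' @param table subject table from [generate_subject_table()].
#' @param mask optional brain mask `volume_map`; defaults to
#'   [make_brain_mask()] on the spec's grid.
#' @return list with `maps` (named list of `volume_map`, one per
#'   subject) and `ground_truth` (binary effect `volume_map` plus the
#'   signed cluster list).
#' @export
generate_gmv_maps <- function(spec, table, mask = NULL) {
  stopifnot(inherits(spec, "cohort_spec"),
            nrow(table) == spec$n_male + spec$n_female)
  if (is.null(mask)) mask <- make_brain_mask(spec$grid_shape,
                                             spec$voxel_size_mm)
  m <- mask$mask
  set.seed(substream_seed(spec$seed, "gmv"))
  effect <- array(0, spec$grid_shape)
  for (cl in spec$gmv_effect_clusters) {
    sm <- sphere_mask(spec$grid_shape, cl$center, cl$radius) & m
    if (!any(sm)) stop("effect cluster falls entirely outside the brain mask")
    effect[sm] <- effect[sm] + cl$d * spec$noise_sd
  }
  female <- table$gender == "female"
  vmask <- which(m)
  nvox <- length(vmask)
  maps <- vector("list", nrow(table))
  names(maps) <- table$id
  for (s in seq_len(nrow(table))) {
    vals <- array(0, spec$grid_shape)
    base <- spec$gmv_baseline +
      (table$age[s] - 23) * spec$confound_slopes$age +
      (table$education[s] - 15.5) * spec$confound_slopes$education
    vals[vmask] <- base + if (female[s]) effect[vmask] else 0
    vals[vmask] <- vals[vmask] + stats::rnorm(nvox, 0, spec$noise_sd)
    vals[vals < 0] <- 0
    maps[[s]] <- volume_map(vals, mask = m,
                            voxel_size_mm = spec$voxel_size_mm)
  }
  gt_mask <- clusters_mask(spec$grid_shape, spec$gmv_effect_clusters, m)
  list(maps = maps,
       ground_truth = list(
         effect_mask = volume_map(array(as.numeric(gt_mask),
                                        spec$grid_shape),
                                  mask = m,
                                  voxel_size_mm = spec$voxel_size_mm),
         clusters = spec$gmv_effect_clusters))
}

# Eigenvalue clipping to the nearest correlation-like positive-definite
# matrix; diagonal rescaled back to 1.
nearest_pd_corr <- function(C, eps = 1e-6) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  C2 <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(C2))
  C2 <- C2 / outer(d, d)
  (C2 + t(C2)) / 2
}

# Per-gender latent correlation targets: base_fc everywhere, planted
# deltas added to the female matrix (delta = female minus male).
gender_corr_targets <- function(spec) {
  R <- spec$n_regions
  Cm <- matrix(spec$base_fc, R, R); diag(Cm) <- 1
  Cf <- Cm
  for (e in spec$fc_effect_edges) {
    Cf[e$i, e$j] <- Cf[e$i, e$j] + e$delta
    Cf[e$j, e$i] <- Cf[e$i, e$j]
  }
  list(male = nearest_pd_corr(Cm), female = nearest_pd_corr(Cf))
}

# Assign every in-mask voxel to a 3x3x3 spatial block; neighboring
# voxels mostly share a block, so a shared per-block signal produces
# local temporal coherence (the quantity ReHo measures).
block_labels <- function(grid_shape, mask) {
  co <- which(mask, arr.ind = TRUE)
  bx <- (co[, 1] - 1) %/% 3
  by <- (co[, 2] - 1) %/% 3
  bz <- (co[, 3] - 1) %/% 3
  nbx <- (grid_shape[1] + 2) %/% 3
  nby <- (grid_shape[2] + 2) %/% 3
  as.integer(bx + nbx * (by + nby * bz)) + 1L
}

#' Generate per-subject BOLD runs with planted FC and coherence effects
#'
#' Each in-mask voxel's series is
#' `w * L[region(v)] + c_v * B[block(v)] + N(0, 1)`, where `L` are
#' region latent signals drawn with the gender's target correlation
#' matrix (Cholesky-factorized; nearest-PD repaired if planted deltas
#' break positive-definiteness), `B` are shared signals of 3x3x3 local
#' blocks, `w` is `region_signal_weight`, and `c_v` is
#' `local_coherence_base`, incremented by `0.1 * d` for females inside
#' ReHo effect clusters. Six smooth pseudo-motion random walks and a
#' linear + sinusoidal drift regressor set are returned per subject so
#' nuisance regression is exercisable.
#'
#' @param spec a [cohort_spec()].
#' @param table subject table.
#' @param atlas integer label `volume_map` from [make_atlas()].
#' @param mask optional brain mask; defaults to the atlas mask.
#' @return list with `runs` (named list of `bold_run`), `motion` (named
#'   list of T x 6 matrices), and `ground_truth` (ReHo effect mask and
#'   FC effect edge list).
#' @export
generate_bold_runs <- function(spec, table, atlas, mask = NULL) {
  stopifnot(inherits(spec, "cohort_spec"),
            nrow(table) == spec$n_male + spec$n_female)
  m <- if (is.null(mask)) atlas$mask else mask$mask
  labs <- atlas$values[m]
  if (!setequal(unique(labs), seq_len(spec$n_regions)))
    stop("atlas does not partition the mask into n_regions labels")
  Tn <- spec$n_timepoints
  targets <- gender_corr_targets(spec)
  chol_g <- lapply(targets, chol)
  blocks <- block_labels(spec$grid_shape, m)
  nblocks <- max(blocks)
  nvox <- sum(m)
  vmask <- which(m)
  reho_mask <- clusters_mask(spec$grid_shape, spec$reho_effect_clusters, m)
  # per-voxel coherence increment (applied to females)
  dc <- numeric(nvox)
  for (cl in spec$reho_effect_clusters) {
    sm <- sphere_mask(spec$grid_shape, cl$center, cl$radius) & m
    dc[sm[vmask]] <- dc[sm[vmask]] + 0.1 * cl$d
  }
  set.seed(substream_seed(spec$seed, "bold"))
  female <- table$gender == "female"
  w <- spec$region_signal_weight
  runs <- vector("list", nrow(table))
  motion <- vector("list", nrow(table))
  names(runs) <- names(motion) <- table$id
  for (s in seq_len(nrow(table))) {
    ch <- if (female[s]) chol_g$female else chol_g$male
    L <- matrix(stats::rnorm(Tn * spec$n_regions), Tn) %*% ch
    B <- matrix(stats::rnorm(Tn * nblocks), Tn)
    cv <- pmin(spec$local_coherence_base +
                 if (female[s]) dc else 0, 0.95)
    Y <- w * L[, labs, drop = FALSE] +
      B[, blocks, drop = FALSE] * rep(cv, each = Tn) +
      matrix(stats::rnorm(Tn * nvox), Tn)
    arr <- array(0, c(spec$grid_shape, Tn))
    flat <- matrix(arr, ncol = Tn)
    flat[vmask, ] <- t(Y)
    arr <- array(flat, c(spec$grid_shape, Tn))
    runs[[s]] <- bold_run(arr, tr_seconds = spec$tr_seconds)
    mo <- apply(matrix(stats::rnorm(Tn * 6, 0, 0.02), Tn), 2, cumsum)
    motion[[s]] <- mo
  }
  edges <- edge_index(spec$n_regions)
  fc_truth <- vapply(spec$fc_effect_edges, function(e) {
    i <- min(e$i, e$j); j <- max(e$i, e$j)
    which(edges$i == i & edges$j == j)
  }, integer(1))
  list(runs = runs, motion = motion,
       ground_truth = list(
         reho_effect_mask = volume_map(array(as.numeric(reho_mask),
                                             spec$grid_shape),
                                       mask = m,
                                       voxel_size_mm = spec$voxel_size_mm),
         fc_effect_edges = data.frame(
           edge = fc_truth,
           delta = vapply(spec$fc_effect_edges, `[[`, numeric(1), "delta"))))
}

#' Standard drift regressors for a run
#'
#' Linear trend plus one slow sinusoid, the drift components the
#' preprocessing stage removes.
#'
#' @param n_timepoints run length.
#' @return T x 2 matrix.
#' @export
drift_regressors <- function(n_timepoints) {
  t <- seq_len(n_timepoints)
  cbind(linear = scale(t)[, 1],
        sine = sin(2 * pi * t / n_timepoints))
}

#' Simulate a full cohort and optionally write it to disk
#'
#' Runs the generator end to end. When `out_dir` is given, writes
#' per-subject NIfTI volumes (`*_gmv.nii.gz`, `*_bold.nii.gz`), the
#' brain mask and integer atlas, a TSV subject table, TSV motion
#' parameters and a JSON ground-truth sidecar.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional output directory.
#' @return list with `spec`, `table`, `mask`, `atlas`, `gmv`, `bold`.
#' @export
simulate_cohort <- function(spec, out_dir = NULL) {
  mask <- make_brain_mask(spec$grid_shape, spec$voxel_size_mm)
  atlas <- make_atlas(mask, spec$n_regions, spec$voxel_size_mm)
  table <- generate_subject_table(spec)
  gmv <- generate_gmv_maps(spec, table, mask)
  bold <- generate_bold_runs(spec, table, atlas, mask)
  out <- list(spec = spec, table = table, mask = mask, atlas = atlas,
              gmv = gmv, bold = bold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_tsv(table, file.path(out_dir, "participants.tsv"))
    write_nifti(array(as.numeric(mask$mask), spec$grid_shape),
                file.path(out_dir, "brain_mask.nii.gz"),
                voxel_size_mm = spec$voxel_size_mm, datatype = "uint8")
    write_volume(atlas, file.path(out_dir, "atlas.nii.gz"),
                 datatype = "int32")
    for (id in table$id) {
      write_volume(gmv$maps[[id]],
                   file.path(out_dir, paste0(id, "_gmv.nii.gz")),
                   datatype = "float32")
      write_bold(bold$runs[[id]],
                 file.path(out_dir, paste0(id, "_bold.nii.gz")))
      write_table_tsv(as.data.frame(bold$motion[[id]]),
                      file.path(out_dir, paste0(id, "_motion.tsv")))
    }
    gt <- list(
      gmv_effect_voxels = which(gmv$ground_truth$effect_mask$values > 0),
      reho_effect_voxels = which(
        bold$ground_truth$reho_effect_mask$values > 0),
      fc_effect_edges = bold$ground_truth$fc_effect_edges,
      seed = spec$seed)
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
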