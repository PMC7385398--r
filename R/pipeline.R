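# Orchestration: one configuration object drives simulate -> features
# -> stats -> convergence -> mvpa and leaves a manifest behind. Stage
# intermediates are cached as an RDS state file inside the output
# directory so CLI subcommands can resume individual stages.

#' Pipeline configuration
#'
#' All tunables of the end-to-end run. `cohort` is a list of arguments
#' for [cohort_spec()] (the master `seed` below is injected). All
#' stage randomness (simulation, fold assignment, FWE and MVPA
#' permutations) derives from the one master seed via named substreams.
#'
#' @param cohort list of [cohort_spec()] arguments.
#' @param band_hz length-2 band-pass limits in Hz.
#' @param fwhm_mm Gaussian smoothing FWHM (mm) for GMV and ReHo maps.
#' @param alpha voxel-level family-wise alpha.
#' @param trend_p uncorrected trend threshold for the overlap analysis.
#' @param fwe_method `"max_t_permutation"` or `"bonferroni"`.
#' @param fwe_n_perm permutations for max-T FWE.
#' @param edge_alpha family-wise alpha for the edge Bonferroni family.
#' @param cv_k number of CV folds.
#' @param grid_step_voxel feature-grid step for voxel-wise modalities
#'   and the combined matrix.
#' @param grid_step_fc feature-grid step for the FC modality.
#' @param n_perm MVPA permutation count.
#' @param svm_c SVM regularization constant.
#' @param strict_cv if TRUE, residualize covariates within training
#'   folds only (leakage-free variant; the emulated protocol uses
#'   FALSE).
#' @param write_cohort if TRUE, the simulated cohort is written as
#'   NIfTI/TSV under `<out>/cohort/`.
#' @param seed master integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = list(), band_hz = c(0.01, 0.08),
                            fwhm_mm = 4, alpha = 0.05, trend_p = 0.001,
                            fwe_method = "max_t_permutation",
                            fwe_n_perm = 200, edge_alpha = 0.05,
                            cv_k = 10, grid_step_voxel = 2000,
                            grid_step_fc = 100, n_perm = 200,
                            svm_c = 1, strict_cv = FALSE,
                            write_cohort = FALSE, seed = 1) {
  cfg <- list(cohort = cohort, band_hz = band_hz, fwhm_mm = fwhm_mm,
              alpha = alpha, trend_p = trend_p, fwe_method = fwe_method,
              fwe_n_perm = fwe_n_perm, edge_alpha = edge_alpha,
              cv_k = cv_k, grid_step_voxel = grid_step_voxel,
              grid_step_fc = grid_step_fc, n_perm = n_perm,
              svm_c = svm_c, strict_cv = strict_cv,
              write_cohort = write_cohort, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

stage_msg <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

# Nuisance regressors for one subject: drift (linear + sinusoid),
# 6 pseudo-motion parameters and the global in-mask mean. The emulated
# protocol also regresses WM and ventricle mean signals; the synthetic
# world has no non-GM tissue compartments, so those regressors do not
# exist here (regressing atlas-region means instead would null the
# very signals the FC stage measures).
nuisance_design <- function(run, motion, mask, atlas) {
  Y <- run_matrix(run, mask$mask)
  cbind(drift_regressors(dim(run$values)[4]), motion,
        global = rowMeans(Y))
}

#' Run the full pipeline
#'
#' Executes simulate, features (band-pass, nuisance regression, ReHo
#' with standardize + smooth, region time series, Fisher-z FC), stats
#' (GMV and ReHo t-maps with FWE correction, edge tests, weighted
#' degree), convergence (overlap + spatial correlation) and mvpa (per
#' modality and combined, with permutation nulls), then writes result
#' tables, a markdown report and a JSON manifest under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the full state list (`spec`, `cohort`,
#'   `features`, `stats`, `convergence`, `mvpa`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]

  spec <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
  stage_msg("simulate", spec$n_male, " males + ", spec$n_female,
            " females, grid ", paste(spec$grid_shape, collapse = "x"))
  sim <- run_stage("simulate", simulate_cohort(
    spec, out_dir = if (config$write_cohort)
      file.path(out_dir, "cohort") else NULL))
  state <- list(config = config, spec = spec, cohort = sim)

  stage_msg("features", "band ", config$band_hz[1], "-",
            config$band_hz[2], " Hz, FWHM ", config$fwhm_mm, " mm")
  state$features <- run_stage("features", {
    mask <- sim$mask; atlas <- sim$atlas; table <- sim$table
    reho_maps <- list(); fc_list <- list()
    for (id in table$id) {
      run <- sim$bold$runs[[id]]
      run <- bandpass_filter(run, config$band_hz[1], config$band_hz[2],
                             mask = mask$mask)
      reg <- nuisance_design(run, sim$bold$motion[[id]], mask, atlas)
      run <- regress_nuisance(run, reg, mask = mask$mask)
      reho <- compute_reho(run, mask, neighborhood = 26)
      reho <- smooth_volume(standardize_reho(reho), config$fwhm_mm)
      reho_maps[[id]] <- reho
      fc_list[[id]] <- fc_matrix(region_timeseries(run, atlas, mask))
    }
    gmv_maps <- lapply(sim$gmv$maps, smooth_volume, fwhm_mm = config$fwhm_mm)
    list(gmv = gmv_maps, reho = reho_maps, fc = fc_list)
  })

  stage_msg("stats", "FWE method ", config$fwe_method)
  state$stats <- run_stage("stats", {
    table <- sim$table
    covs <- table[, c("age", "education")]
    fwe_seed <- substream_seed(config$seed, "fwe")
    tm_gmv <- glm_group_tmap(state$features$gmv, table$gender, covs)
    tm_gmv <- fwe_correct(tm_gmv, config$fwe_method, config$alpha,
                          maps = state$features$gmv,
                          gender = table$gender, covariates = covs,
                          n_perm = config$fwe_n_perm, seed = fwe_seed)
    tm_reho <- glm_group_tmap(state$features$reho, table$gender, covs)
    tm_reho <- fwe_correct(tm_reho, config$fwe_method, config$alpha,
                           maps = state$features$reho,
                           gender = table$gender, covariates = covs,
                           n_perm = config$fwe_n_perm, seed = fwe_seed + 1L)
    edges <- edge_group_tests(state$features$fc, table$gender, covs,
                              alpha_family = config$edge_alpha)
    list(gmv = tm_gmv, reho = tm_reho, edges = edges,
         degree = weighted_degree(edges),
         demographics = list(age = demographics_test(table, "age"),
                             education = demographics_test(table,
                                                           "education")))
  })

  stage_msg("convergence", "overlap + spatial correlation")
  state$convergence <- run_stage("convergence", {
    list(overlap = overlap_analysis(
           state$stats$gmv$sig_mask, state$stats$reho$sig_mask,
           trend_mask(state$stats$gmv, config$trend_p),
           trend_mask(state$stats$reho, config$trend_p),
           tmapA = state$stats$gmv, tmapB = state$stats$reho),
         spatial_r = spatial_correlation(state$stats$gmv,
                                         state$stats$reho))
  })

  stage_msg("mvpa", "k = ", config$cv_k, ", ", config$n_perm,
            " permutations")
  state$mvpa <- run_stage("mvpa", {
    table <- sim$table
    covs <- table[, c("age", "education")]
    vox <- which(sim$mask$mask)
    mats <- list(
      gmv = feature_matrix(t(vapply(state$features$gmv,
        function(m) m$values[vox], numeric(length(vox)))), "gmv"),
      reho = feature_matrix(t(vapply(state$features$reho,
        function(m) m$values[vox], numeric(length(vox)))), "reho"),
      fc = feature_matrix(do.call(rbind,
        lapply(state$features$fc, edge_vector)), "fc"))
    folds <- make_folds(table$gender, k = config$cv_k,
                        seed = substream_seed(config$seed, "folds"))
    perm_seed <- substream_seed(config$seed, "perm")
    res <- list(folds = folds)
    parts <- list()
    for (mod in names(mats)) {
      Xr <- residualize_features(mats[[mod]], covs)
      parts[[mod]] <- Xr
      step <- if (mod == "fc") config$grid_step_fc
              else config$grid_step_voxel
      grid <- make_feature_grid(step, ncol(Xr))
      cv <- cv_classify(Xr, table$gender, folds, grid, C = config$svm_c)
      perm <- permutation_test(Xr, table$gender, folds,
                               cv$best_n_features,
                               n_perm = config$n_perm,
                               actual_accuracy =
                                 cv$mean_accuracy[cv$best_grid_point],
                               seed = perm_seed,
                               bonferroni_factor = length(grid),
                               C = config$svm_c)
      res[[mod]] <- list(cv = cv, perm = perm)
    }
    comb <- concat_modalities(lapply(parts, znorm_per_subject))
    grid <- make_feature_grid(config$grid_step_voxel, ncol(comb))
    cv <- cv_classify(comb, table$gender, folds, grid, C = config$svm_c)
    perm <- permutation_test(comb, table$gender, folds,
                             cv$best_n_features, n_perm = config$n_perm,
                             actual_accuracy =
                               cv$mean_accuracy[cv$best_grid_point],
                             seed = perm_seed + 1L,
                             bonferroni_factor = length(grid),
                             C = config$svm_c)
    res$combined <- list(cv = cv, perm = perm)
    res
  })

  write_pipeline_outputs(state, out_dir)
  state$manifest <- write_manifest(state, out_dir,
                                   proc.time()[["elapsed"]] - t0)
  saveRDS(state, file.path(out_dir, "state.rds"))
  invisible(state)
}

mvpa_summary_table <- function(mv) {
  mods <- setdiff(names(mv), "folds")
  do.call(rbind, lapply(mods, function(mod) {
    cv <- mv[[mod]]$cv; pe <- mv[[mod]]$perm
    data.frame(modality = mod,
               accuracy_pct = 100 * cv$mean_accuracy[cv$best_grid_point],
               n_features = cv$best_n_features,
               sensitivity_pct = 100 * cv$sensitivity,
               specificity_pct = 100 * cv$specificity,
               auc = cv$auc, p_perm = pe$p_value,
               p_bonferroni = pe$p_bonferroni)
  }))
}

write_pipeline_outputs <- function(state, out_dir) {
  st <- state$stats
  write_volume(st$gmv$t_values, file.path(out_dir, "gmv_tmap.nii.gz"))
  write_volume(st$reho$t_values, file.path(out_dir, "reho_tmap.nii.gz"))
  write_volume(st$gmv$sig_mask, file.path(out_dir, "gmv_sig.nii.gz"),
               datatype = "uint8")
  write_volume(st$reho$sig_mask, file.path(out_dir, "reho_sig.nii.gz"),
               datatype = "uint8")
  ed <- data.frame(st$edges$edge_index,
                   t = st$edges$t_values, p = st$edges$p_values,
                   significant = st$edges$sig_mask)
  write_table_tsv(ed, file.path(out_dir, "edge_stats.tsv"))
  write_table_tsv(st$degree, file.path(out_dir, "weighted_degree.tsv"))
  write_table_tsv(cluster_summary(st$gmv),
                  file.path(out_dir, "gmv_clusters.tsv"))
  write_table_tsv(cluster_summary(st$reho),
                  file.path(out_dir, "reho_clusters.tsv"))
  conv <- state$convergence
  jsonlite::write_json(
    c(unclass(conv$overlap), list(spatial_r = conv$spatial_r)),
    file.path(out_dir, "convergence.json"), auto_unbox = TRUE,
    digits = NA)
  write_table_tsv(mvpa_summary_table(state$mvpa),
                  file.path(out_dir, "mvpa_summary.tsv"))
  for (mod in setdiff(names(state$mvpa), "folds")) {
    cv <- state$mvpa[[mod]]$cv
    write_table_tsv(data.frame(n_features = cv$grid,
                               mean_accuracy = cv$mean_accuracy),
                    file.path(out_dir, paste0("mvpa_grid_", mod, ".tsv")))
    write_table_tsv(data.frame(
      null_accuracy = state$mvpa[[mod]]$perm$null_accuracies),
      file.path(out_dir, paste0("mvpa_null_", mod, ".tsv")))
  }
  invisible(out_dir)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(state, out_dir, elapsed) {
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        c("manifest.json", "state.rds")))
  manifest <- list(
    package = "sexdiffmri",
    package_version = as.character(utils::packageVersion("sexdiffmri")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(state$config),
    config_hash = config_hash(state$config),
    seed = state$config$seed,
    elapsed_seconds = round(elapsed, 1),
    outputs = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  manifest
}

#' Render a markdown + PNG report for a finished pipeline run
#'
#' Produces `report.md` plus figure panels (accuracy-vs-grid curves,
#' permutation null histograms with the observed accuracy, ROC curves,
#' weighted-degree bars) in `<out_dir>/figures/`.
#'
#' @param out_dir directory of a completed [run_pipeline()] run.
#' @return Path of `report.md`, invisibly.
#' @export
render_report <- function(out_dir) {
  state <- readRDS(file.path(out_dir, "state.rds"))
  figdir <- file.path(out_dir, "figures")
  dir.create(figdir, showWarnings = FALSE)
  mods <- setdiff(names(state$mvpa), "folds")
  grDevices::png(file.path(figdir, "mvpa_accuracy.png"), 900, 700)
  graphics::par(mfrow = c(2, 2))
  for (mod in mods) {
    cv <- state$mvpa[[mod]]$cv
    graphics::plot(cv$grid, 100 * cv$mean_accuracy, type = "b",
                   xlab = "selected features",
                   ylab = "mean accuracy (%)", main = mod)
    graphics::abline(v = cv$best_n_features, col = "red")
  }
  grDevices::dev.off()
  grDevices::png(file.path(figdir, "mvpa_null.png"), 900, 700)
  graphics::par(mfrow = c(2, 2))
  for (mod in mods) {
    pe <- state$mvpa[[mod]]$perm
    cv <- state$mvpa[[mod]]$cv
    graphics::hist(100 * pe$null_accuracies, breaks = 20,
                   xlim = c(0, 100), col = "lightblue",
                   xlab = "null accuracy (%)", main = mod)
    graphics::abline(v = 100 * cv$mean_accuracy[cv$best_grid_point],
                     col = "red", lwd = 2)
  }
  grDevices::dev.off()
  grDevices::png(file.path(figdir, "roc.png"), 700, 700)
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "gray",
                 xlab = "false positive rate",
                 ylab = "true positive rate", main = "ROC (pooled)")
  cols <- seq_along(mods) + 1
  for (i in seq_along(mods)) {
    cv <- state$mvpa[[mods[i]]]$cv
    graphics::lines(cv$roc$fpr, cv$roc$tpr, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", legend = sprintf(
    "%s (AUC %.3f)", mods,
    vapply(mods, function(m) state$mvpa[[m]]$cv$auc, numeric(1))),
    col = cols, lwd = 2)
  grDevices::dev.off()
  grDevices::png(file.path(figdir, "weighted_degree.png"), 900, 500)
  dg <- state$stats$degree
  graphics::barplot(rbind(dg$positive_degree, dg$negative_degree),
                    beside = TRUE, names.arg = dg$region,
                    col = c("red", "blue"), las = 2,
                    ylab = "weighted degree")
  graphics::legend("topright", c("female > male", "male > female"),
                   fill = c("red", "blue"))
  grDevices::dev.off()

  conv <- state$convergence
  tab <- mvpa_summary_table(state$mvpa)
  lines <- c(
    "# Pipeline report (synthetic cohort)", "",
    sprintf("- Subjects: %d male / %d female", state$spec$n_male,
            state$spec$n_female),
    sprintf("- Grid %s, %d regions, %d volumes, TR %.1f s",
            paste(state$spec$grid_shape, collapse = "x"),
            state$spec$n_regions, state$spec$n_timepoints,
            state$spec$tr_seconds), "",
    "## Univariate statistics",
    sprintf("- GMV: %d significant voxels (FWE %s, alpha %.2f)",
            sum(state$stats$gmv$sig_mask$values > 0),
            state$stats$gmv$fwe_method, state$config$alpha),
    sprintf("- ReHo: %d significant voxels",
            sum(state$stats$reho$sig_mask$values > 0)),
    sprintf("- FC edges: %d of %d significant (Bonferroni %g)",
            sum(state$stats$edges$sig_mask), state$stats$edges$n_edges,
            state$config$edge_alpha / state$stats$edges$n_edges), "",
    "## Structural/functional convergence",
    sprintf("- Corrected overlap: %d voxels (%.2f%% of GMV, %.2f%% of ReHo)",
            conv$overlap$n_overlap_corrected, conv$overlap$pct_of_A,
            conv$overlap$pct_of_B),
    sprintf("- Spatial correlation of t-maps: r = %.4f", conv$spatial_r),
    "", "## Classification",
    "", paste("|", paste(names(tab), collapse = " | "), "|"),
    paste("|", paste(rep("---", ncol(tab)), collapse = " | "), "|"),
    apply(tab, 1, function(r) paste("|", paste(
      vapply(r, function(x) format(x, digits = 4), ""),
      collapse = " | "), "|")),
    "", "![accuracy](figures/mvpa_accuracy.png)",
    "![null](figures/mvpa_null.png)", "![roc](figures/roc.png)",
    "![degree](figures/weighted_degree.png)", "")
  path <- file.path(out_dir, "report.md")
  writeLines(unlist(lines), path)
  invisible(path)
}
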