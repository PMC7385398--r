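# Classification protocol: feature preparation, 10-fold CV with
# embedded |weight|-ranked feature selection, accuracy / sensitivity /
# specificity / ROC / AUC, and the fold-wise label-shuffling
# permutation null.

#' Construct a feature matrix with provenance tags
#'
#' @param values subjects x features numeric matrix.
#' @param modality one of `"gmv"`, `"reho"`, `"fc"`, `"combined"`, or
#'   any label; stored per column.
#' @param feature_ids optional data.frame with columns `modality` and
#'   `index`; defaults to `modality` and column position.
#' @return A `feature_matrix`: the matrix with a `feature_ids`
#'   attribute.
#' @export
feature_matrix <- function(values, modality = "gmv", feature_ids = NULL) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("feature values must be finite")
  if (is.null(feature_ids))
    feature_ids <- data.frame(modality = modality,
                              index = seq_len(ncol(values)),
                              stringsAsFactors = FALSE)
  if (nrow(feature_ids) != ncol(values))
    stop("feature_ids must have one row per column")
  structure(values, feature_ids = feature_ids, class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  ids <- attr(x, "feature_ids")
  cat("<feature_matrix> ", nrow(x), " subjects x ", ncol(x),
      " features (", paste(unique(ids$modality), collapse = "+"),
      ")\n", sep = "")
  invisible(x)
}

fm_ids <- function(X) attr(X, "feature_ids")

#' Remove covariate effects from every feature
#'
#' Each column is replaced by the residuals of
#' `column ~ intercept + covariates`, fit over all subjects — faithful
#' to the emulated protocol, which residualizes before (outside) the
#' cross-validation loop. That choice leaks test-set covariate
#' structure into training; `fit_rows` lets a strict-CV caller fit the
#' regression on training rows only and apply it to all rows.
#'
#' @param X a [feature_matrix()].
#' @param covariates per-subject covariates (data.frame or matrix).
#' @param fit_rows optional integer rows used to fit the regressions.
#' @return A residualized `feature_matrix`.
#' @export
residualize_features <- function(X, covariates, fit_rows = NULL) {
  D <- cbind(1, as.matrix(covariates))
  if (qr(D)$rank < ncol(D)) stop("covariate design is rank deficient")
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(X))
  beta <- qr.coef(qr(D[fit_rows, , drop = FALSE]),
                  X[fit_rows, , drop = FALSE])
  res <- unclass(X) - D %*% beta
  feature_matrix(res, feature_ids = fm_ids(X))
}

#' Z-normalize each subject across the features of each modality
#'
#' Within every modality block, each subject's feature vector is
#' centred and scaled by its own mean and standard deviation across
#' that modality's features (population SD convention, dividing by n).
#' This puts differently-scaled modalities on a common footing before
#' concatenation.
#'
#' @param X a [feature_matrix()].
#' @return A normalized `feature_matrix`.
#' @export
znorm_per_subject <- function(X) {
  ids <- fm_ids(X)
  out <- unclass(X)
  for (mod in unique(ids$modality)) {
    cols <- which(ids$modality == mod)
    block <- out[, cols, drop = FALSE]
    mu <- rowMeans(block)
    sd_pop <- sqrt(rowMeans((block - mu)^2))
    if (any(sd_pop == 0))
      stop("zero feature variance for subject(s): ",
           paste(which(sd_pop == 0), collapse = ", "))
    out[, cols] <- (block - mu) / sd_pop
  }
  feature_matrix(out, feature_ids = ids)
}

#' Concatenate modality feature matrices subject-wise
#'
#' @param parts list of `feature_matrix` objects with identical subject
#'   counts and ordering (checked via rownames when present).
#' @return A combined `feature_matrix`; provenance tags are preserved,
#'   so every output column maps back to its (modality, index).
#' @export
concat_modalities <- function(parts) {
  stopifnot(length(parts) >= 1)
  n <- nrow(parts[[1]])
  rn <- rownames(parts[[1]])
  for (p in parts) {
    if (nrow(p) != n) stop("subject counts differ between parts")
    if (!is.null(rn) && !is.null(rownames(p)) &&
        !identical(rownames(p), rn))
      stop("subject ordering differs between parts")
  }
  vals <- do.call(cbind, lapply(parts, unclass))
  ids <- do.call(rbind, lapply(parts, fm_ids))
  rownames(ids) <- NULL
  feature_matrix(vals, feature_ids = ids)
}

#' Stratified fold assignment with a remainder fold
#'
#' Each of the first `k - 1` folds receives `floor(n_g / k)` randomly
#' chosen subjects of group g; fold `k` receives every remaining
#' subject. For 135 males / 155 females and k = 10 this yields nine
#' folds of 13 males + 15 females and a last fold of 18 males +
#' 20 females.
#'
#' @param gender character vector (`"male"`/`"female"`), one entry per
#'   subject, in subject order.
#' @param k number of folds (>= 2; each group must have >= k members).
#' @param seed integer seed for the random assignment.
#' @return list of class `fold_spec`: `k`, `assignments` (integer fold
#'   per subject), `composition` (k x 2 matrix of male/female counts).
#' @export
make_folds <- function(gender, k = 10, seed = 1) {
  stopifnot(k >= 2)
  groups <- list(male = which(gender == "male"),
                 female = which(gender == "female"))
  for (g in groups)
    if (length(g) < k) stop("each group needs at least k subjects")
  set.seed(as.integer(seed))
  assignments <- integer(length(gender))
  for (g in groups) {
    per <- length(g) %/% k
    shuffled <- sample(g)
    fold <- rep(k, length(g))
    fold[seq_len(per * (k - 1))] <- rep(seq_len(k - 1), each = per)
    assignments[shuffled] <- fold
  }
  comp <- t(vapply(seq_len(k), function(f)
    c(male = sum(assignments == f & gender == "male"),
      female = sum(assignments == f & gender == "female")),
    numeric(2)))
  structure(list(k = k, assignments = assignments, composition = comp),
            class = "fold_spec")
}

#' Feature-count grid for embedded selection
#'
#' `(step, 2 step, ..., largest multiple below total, total)`. With
#' step 2,000 over 67,541 features this is 34 grid points; step 100
#' over 6,670 gives 67; step 2,000 over 141,752 gives 71.
#'
#' @param step positive increment.
#' @param total total feature count.
#' @return strictly increasing integer vector ending in `total`.
#' @export
make_feature_grid <- function(step, total) {
  stopifnot(step > 0, total > 0)
  if (step > total) return(as.integer(total))
  g <- seq(step, total, by = step)
  g <- g[g < total]
  as.integer(c(g, total))
}

# |weight| ranking, ties broken by ascending feature index.
rank_features <- function(w) order(-abs(w), seq_along(w))

svm_accuracy <- function(pred_sign, y_sign) mean(pred_sign == y_sign)

#' Cross-validated classification with embedded feature selection
#'
#' For every fold: a linear SVM is trained on the full training set,
#' features are ranked by descending |weight| (ties by ascending
#' index), and for each grid point k the classifier is retrained on the
#' top-k features and scored on the held-out fold. Nothing from the
#' test fold touches ranking or training. The overall accuracy per grid
#' point is the unweighted mean of fold accuracies; the best grid point
#' maximizes it (ties go to the smallest k). Sensitivity is the pooled
#' fraction of males classified male and specificity the pooled
#' fraction of females classified female; AUC comes from decision
#' values pooled across test folds at the best grid point (males
#' positive).
#'
#' @param X a [feature_matrix()] (or plain matrix).
#' @param y character labels `"male"`/`"female"`.
#' @param folds a [make_folds()] result.
#' @param grid feature-count grid from [make_feature_grid()]; defaults
#'   to the full feature set only (plain CV).
#' @param C SVM regularization constant.
#' @return list of class `cv_result`: `grid`, `fold_accuracy`
#'   (k x |grid|), `mean_accuracy`, `pooled_accuracy`, `best_grid_point`
#'   (index), `best_n_features`, `decision_values` (per subject, test
#'   fold, best grid point), `sensitivity`, `specificity`, `auc`,
#'   `roc`, `fold_spec`.
#' @export
cv_classify <- function(X, y, folds, grid = NULL, C = 1) {
  Xm <- unclass(X)
  n <- nrow(Xm)
  stopifnot(length(y) == n, length(folds$assignments) == n)
  if (is.null(grid)) grid <- ncol(Xm)
  ys <- ifelse(y == "male", 1, -1)
  k <- folds$k
  acc <- matrix(NA_real_, k, length(grid))
  dec <- matrix(NA_real_, n, length(grid))
  for (f in seq_len(k)) {
    tr <- folds$assignments != f
    te <- !tr
    full <- linear_svm(Xm[tr, , drop = FALSE], ys[tr], C = C)
    ranking <- rank_features(full$w)
    for (gi in seq_along(grid)) {
      if (grid[gi] == ncol(Xm)) {
        # full feature set: reuse the ranking fit (identical model)
        dv <- predict(full, Xm[te, , drop = FALSE])
      } else {
        top <- ranking[seq_len(grid[gi])]
        fit <- linear_svm(Xm[tr, top, drop = FALSE], ys[tr], C = C)
        dv <- predict(fit, Xm[te, top, drop = FALSE])
      }
      dec[te, gi] <- dv
      acc[f, gi] <- svm_accuracy(sign(dv), ys[te])
    }
  }
  mean_acc <- colMeans(acc)
  best <- which.max(mean_acc)
  dbest <- dec[, best]
  pred <- sign(dbest)
  sens <- mean(pred[ys == 1] == 1)
  spec <- mean(pred[ys == -1] == -1)
  roc <- roc_auc(dbest, y)
  structure(list(grid = grid, fold_accuracy = acc,
                 mean_accuracy = mean_acc,
                 pooled_accuracy = mean(pred == ys),
                 best_grid_point = best,
                 best_n_features = grid[best],
                 decision_values = dbest,
                 sensitivity = sens, specificity = spec,
                 auc = roc$auc, roc = roc$curve,
                 fold_spec = folds, C = C),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> best mean accuracy ",
      signif(100 * x$mean_accuracy[x$best_grid_point], 4), "% at ",
      x$best_n_features, " features (", length(x$grid),
      " grid points); sens ", signif(100 * x$sensitivity, 4),
      "%, spec ", signif(100 * x$specificity, 4), "%, AUC ",
      signif(x$auc, 4), "\n", sep = "")
  invisible(x)
}

#' ROC curve and AUC from pooled decision values
#'
#' Males are the positive class. The AUC equals the probability that a
#' randomly chosen male's decision value exceeds a randomly chosen
#' female's, with ties counting one half (the Wilcoxon/Mann-Whitney
#' identity).
#'
#' @param decision_values numeric vector, one per subject.
#' @param y labels `"male"`/`"female"` (or logical male indicator).
#' @return list with `auc` and `curve` (data.frame `fpr`, `tpr`
#'   monotone from (0,0) to (1,1)).
#' @export
roc_auc <- function(decision_values, y) {
  pos <- if (is.logical(y)) y else y == "male"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  npos <- sum(pos); nneg <- sum(!pos)
  r <- rank(decision_values)             # average ranks handle ties
  auc <- (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(decision_values, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  # collapse tied thresholds so the curve is a function of threshold
  last_of_tie <- c(diff(decision_values[ord]) != 0, TRUE)
  curve <- data.frame(fpr = c(0, fp[last_of_tie] / nneg),
                      tpr = c(0, tp[last_of_tie] / npos))
  list(auc = auc, curve = curve)
}

#' Permutation null for a cross-validated accuracy
#'
#' Repeats the embedded-selection CV `n_perm` times with the training
#' labels of every fold shuffled at random (test labels are untouched),
#' evaluating at the same grid point as the actual analysis. The
#' p-value is the fraction of null accuracies greater than or equal to
#' the actual accuracy, floored at `1 / n_perm`; the Bonferroni factor
#' for the grid search is reported alongside.
#'
#' @param X a [feature_matrix()] or matrix.
#' @param y labels `"male"`/`"female"`.
#' @param folds a [make_folds()] result.
#' @param n_features grid point (feature count) to evaluate, normally
#'   `cv$best_n_features`.
#' @param n_perm number of permutations (>= 1).
#' @param actual_accuracy observed mean CV accuracy to compare against.
#' @param seed integer seed.
#' @param bonferroni_factor number of grid evaluations searched (|grid|).
#' @param C SVM regularization constant.
#' @return list of class `permutation_null`: `n_perm`,
#'   `null_accuracies`, `p_value`, `p_bonferroni`, `bonferroni_factor`.
#' @export
permutation_test <- function(X, y, folds, n_features, n_perm = 2000,
                             actual_accuracy, seed = 1,
                             bonferroni_factor = 1, C = 1) {
  stopifnot(n_perm >= 1)
  Xm <- unclass(X)
  ys <- ifelse(y == "male", 1, -1)
  k <- folds$k
  set.seed(as.integer(seed))
  null_acc <- vapply(seq_len(n_perm), function(pe) {
    fold_acc <- vapply(seq_len(k), function(f) {
      tr <- which(folds$assignments != f)
      te <- which(folds$assignments == f)
      ysh <- ys[sample(tr)]              # shuffled training labels
      full <- linear_svm(Xm[tr, , drop = FALSE], ysh, C = C)
      if (n_features == ncol(Xm)) {
        dv <- predict(full, Xm[te, , drop = FALSE])
      } else {
        top <- rank_features(full$w)[seq_len(n_features)]
        fit <- linear_svm(Xm[tr, top, drop = FALSE], ysh, C = C)
        dv <- predict(fit, Xm[te, top, drop = FALSE])
      }
      svm_accuracy(sign(dv), ys[te])
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  p <- max(sum(null_acc >= actual_accuracy) / n_perm, 1 / n_perm)
  structure(list(n_perm = n_perm, null_accuracies = null_acc,
                 p_value = p,
                 p_bonferroni = min(p * bonferroni_factor, 1),
                 bonferroni_factor = bonferroni_factor),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("<permutation_null> ", x$n_perm, " permutations, null mean ",
      signif(mean(x$null_accuracies), 4), ", p ",
      if (x$p_value <= 1 / x$n_perm) paste0("< ", 1 / x$n_perm)
      else signif(x$p_value, 4),
      " (x", x$bonferroni_factor, " Bonferroni: ",
      signif(x$p_bonferroni, 4), ")\n", sep = "")
  invisible(x)
}
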