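test_that("residualize_features matches the least-squares oracle", {
  set.seed(51)
  n <- 30
  covs <- data.frame(age = rnorm(n), edu = rnorm(n))
  X <- feature_matrix(matrix(rnorm(n * 6), n), "gmv")
  R <- residualize_features(X, covs)
  for (j in c(1, 4)) {
    expect_equal(unclass(R)[, j],
                 as.vector(oracle_ls_residuals(unclass(X)[, j],
                                               as.matrix(covs))),
                 tolerance = 1e-10)
    for (k in 1:2)
      expect_lt(abs(sum(R[, j] * covs[[k]])),
                1e-8 * sqrt(sum(R[, j]^2) * sum(covs[[k]]^2)))
  }
  # column that is an exact linear function of covariates -> zeros
  X2 <- unclass(X); X2[, 2] <- 2 * covs$age - covs$edu + 5
  R2 <- residualize_features(feature_matrix(X2, "gmv"), covs)
  expect_equal(max(abs(R2[, 2])), 0, tolerance = 1e-10)
  # covariates orthogonal to a column -> only mean removal
  covs0 <- data.frame(a = rep(c(-1, 1), n / 2))
  x0 <- rep(c(1, 1, 3, 3), length.out = n) # orthogonal to covs0
  R3 <- residualize_features(feature_matrix(cbind(x0), "gmv"), covs0)
  expect_equal(as.vector(R3[, 1]), x0 - mean(x0), tolerance = 1e-10)
  expect_error(residualize_features(X, cbind(covs$age, covs$age)),
               "rank deficient")
})

test_that("znorm_per_subject uses the population-SD convention per row", {
  X <- feature_matrix(rbind(c(1, 2, 3), c(4, 4, 10)), "gmv")
  Z <- znorm_per_subject(X)
  expect_equal(as.vector(Z[1, ]), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-10)           # population SD: sqrt(2/3)
  expect_equal(Z[1, 2], 0)
  for (i in 1:2) {
    expect_equal(mean(Z[i, ]), 0, tolerance = 1e-10)
    expect_equal(sqrt(mean((Z[i, ] - mean(Z[i, ]))^2)), 1,
                 tolerance = 1e-10)
  }
  # already standardized row is unchanged
  r <- c(-1, 0, 1) * sqrt(3 / 2)
  Z2 <- znorm_per_subject(feature_matrix(rbind(r, r), "gmv"))
  expect_equal(as.vector(Z2[1, ]), r, tolerance = 1e-10)
  # zero-variance row rejected
  expect_error(znorm_per_subject(feature_matrix(rbind(c(1, 1, 1)),
                                                "gmv")),
               "zero feature variance")
  # normalization is per modality block
  ids <- data.frame(modality = rep(c("gmv", "fc"), c(3, 2)),
                    index = c(1:3, 1:2))
  Xm <- feature_matrix(rbind(c(1, 2, 3, 10, 20)), feature_ids = ids)
  Zm <- znorm_per_subject(Xm)
  expect_equal(mean(Zm[1, 1:3]), 0, tolerance = 1e-10)
  expect_equal(mean(Zm[1, 4:5]), 0, tolerance = 1e-10)
})

test_that("concat_modalities preserves counts and provenance tags", {
  a <- feature_matrix(matrix(1, 4, 3), "gmv")
  b <- feature_matrix(matrix(2, 4, 5), "reho")
  cc <- concat_modalities(list(a, b))
  expect_equal(ncol(cc), 8)
  ids <- attr(cc, "feature_ids")
  expect_equal(ids$modality, rep(c("gmv", "reho"), c(3, 5)))
  expect_equal(ids$index, c(1:3, 1:5))
  # single part is the identity
  one <- concat_modalities(list(a))
  expect_equal(unclass(one), unclass(a))
  expect_error(concat_modalities(list(a, feature_matrix(matrix(0, 3, 2),
                                                        "fc"))),
               "subject counts")
})

test_that("make_folds reproduces the remainder-fold composition", {
  gender <- rep(c("male", "female"), c(135, 155))
  fs <- make_folds(gender, k = 10, seed = 3)
  expect_equal(unname(fs$composition[1:9, 1]), rep(13, 9))
  expect_equal(unname(fs$composition[1:9, 2]), rep(15, 9))
  expect_equal(unname(fs$composition[10, ]), c(18, 20))
  expect_equal(colSums(fs$composition), c(male = 135, female = 155))
  # exact division
  fs2 <- make_folds(rep(c("male", "female"), c(20, 20)), 10, 1)
  expect_true(all(fs2$composition == 2))
  # partition property for random sizes
  set.seed(52)
  for (r in 1:5) {
    nm <- sample(12:40, 1); nf <- sample(12:40, 1)
    g <- sample(rep(c("male", "female"), c(nm, nf)))
    f <- make_folds(g, k = 5, seed = r)
    expect_equal(colSums(f$composition), c(male = nm, female = nf))
    expect_true(all(f$composition[1:4, 1] == nm %/% 5))
  }
  # determinism
  expect_identical(make_folds(gender, 10, 7), make_folds(gender, 10, 7))
  expect_error(make_folds(rep(c("male", "female"), c(5, 30)), 10),
               "at least k")
})

test_that("make_feature_grid reproduces the protocol grids", {
  expect_length(make_feature_grid(2000, 67541), 34)
  expect_length(make_feature_grid(100, 6670), 67)
  expect_length(make_feature_grid(2000, 141752), 71)
  g <- make_feature_grid(2000, 67541)
  expect_true(all(diff(g) > 0))
  expect_equal(g[length(g)], 67541)
  expect_equal(make_feature_grid(100, 50), 50L)  # step > total
  # exact multiple: last element is total, not duplicated
  expect_equal(make_feature_grid(5, 15), c(5L, 10L, 15L))
})

test_that("the combined feature count of the emulated protocol is 141,752", {
  parts <- list(feature_matrix(matrix(0, 2, 67541), "gmv"),
                feature_matrix(matrix(0, 2, 67541), "reho"),
                feature_matrix(matrix(0, 2, 6670), "fc"))
  expect_equal(ncol(concat_modalities(parts)), 141752)
})

test_that("linear_svm separates and satisfies dual feasibility", {
  set.seed(53)
  X <- rbind(matrix(rnorm(30 * 4, 2), 30), matrix(rnorm(30 * 4, -2), 30))
  y <- rep(c(1, -1), each = 30)
  fit <- linear_svm(X, y, C = 1)
  expect_equal(mean(sign(predict(fit, X)) == y), 1)
  expect_true(all(fit$alpha >= -1e-12 & fit$alpha <= 1 + 1e-12))
  # KKT: margin violations only where alpha is at the box bound
  marg <- y * predict(fit, X)
  expect_true(all(marg[fit$alpha < 1e-8] >= 1 - 1e-3))
  expect_true(all(abs(marg[fit$alpha > 1e-8 & fit$alpha < 1 - 1e-8] - 1)
                  < 1e-3))
  # determinism
  fit2 <- linear_svm(X, y, C = 1)
  expect_identical(fit$w, fit2$w)
  expect_error(linear_svm(X, rep(1, 60)), "both classes")
})

test_that("cv_classify attains high accuracy on separable classes and
           chance on shuffled labels", {
  dat <- sep_features(n_per = 40, p = 50, seed = 54)
  folds <- make_folds(dat$y, k = 10, seed = 1)
  grid <- make_feature_grid(10, 50)
  cv <- cv_classify(dat$X, dat$y, folds, grid)
  expect_gte(cv$mean_accuracy[cv$best_grid_point], 0.95)
  expect_equal(cv$best_n_features, grid[cv$best_grid_point])
  expect_true(all(cv$fold_accuracy >= 0 & cv$fold_accuracy <= 1))
  # shuffled labels -> chance
  set.seed(55)
  ysh <- sample(dat$y)
  cvs <- cv_classify(dat$X, ysh, make_folds(ysh, 10, 1),
                     grid = 50L)
  expect_gte(cvs$mean_accuracy[1], 0.35)
  expect_lte(cvs$mean_accuracy[1], 0.65)
  # grid = total only equals plain CV without selection
  cvp <- cv_classify(dat$X, dat$y, folds, grid = 50L)
  expect_length(cvp$mean_accuracy, 1)
})

test_that("fold results are deterministic and leakage-free", {
  dat <- sep_features(n_per = 20, p = 30, seed = 56)
  folds <- make_folds(dat$y, k = 5, seed = 2)
  grid <- make_feature_grid(10, 30)
  cv1 <- cv_classify(dat$X, dat$y, folds, grid)
  cv2 <- cv_classify(dat$X, dat$y, folds, grid)
  expect_identical(cv1$fold_accuracy, cv2$fold_accuracy)
  # corrupt one subject's features: folds not containing that subject
  # as test data must be bit-identical (ranking/training never sees
  # test subjects of other folds... the subject is in training for
  # them, so corrupt a subject and check ITS fold's models unaffected
  # for the other direction: accuracies of folds where the corrupted
  # subject is in the TEST set change only via its own prediction).
  sub <- 1
  f_of_sub <- folds$assignments[sub]
  Xc <- unclass(dat$X)
  Xc[sub, ] <- rnorm(ncol(Xc)) * 100
  cv3 <- cv_classify(feature_matrix(Xc, "gmv"), dat$y, folds, grid)
  # folds that trained WITHOUT subject `sub` (i.e. sub in their test
  # set) used identical training data; their other test subjects keep
  # identical decision values
  te <- which(folds$assignments == f_of_sub & seq_along(dat$y) != sub)
  expect_equal(cv1$decision_values[te], cv3$decision_values[te],
               tolerance = 1e-10)
})

test_that("roc_auc equals the pairwise-comparison oracle exactly", {
  set.seed(57)
  for (r in 1:10) {
    n <- sample(6:20, 1)
    y <- sample(c("male", "female"), n, replace = TRUE)
    if (length(unique(y)) < 2) y <- c("male", "female", y[-(1:2)])
    d <- sample(seq(-2, 2, 0.5), n, replace = TRUE)  # ties likely
    expect_equal(roc_auc(d, y)$auc, oracle_auc(d, y == "male"))
  }
  # perfect separation and all-ties limits
  expect_equal(roc_auc(c(3, 4, 1, 2),
                       c("male", "male", "female", "female"))$auc, 1)
  expect_equal(roc_auc(rep(1, 6),
                       rep(c("male", "female"), 3))$auc, 0.5)
  # curve is monotone from (0,0) to (1,1)
  rc <- roc_auc(rnorm(30), rep(c("male", "female"), 15))$curve
  expect_equal(unlist(rc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(rc[nrow(rc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  expect_error(roc_auc(1:4, rep("male", 4)), "both classes")
})

test_that("permutation_test yields the floor p and a centered null", {
  dat <- sep_features(n_per = 12, p = 10, n_inf = 4, d_per = 4,
                      seed = 58)
  folds <- make_folds(dat$y, k = 4, seed = 3)
  cv <- cv_classify(dat$X, dat$y, folds, grid = 10L)
  actual <- cv$mean_accuracy[1]
  expect_gte(actual, 0.9)
  pe <- permutation_test(dat$X, dat$y, folds, n_features = 10L,
                         n_perm = 60, actual_accuracy = actual,
                         seed = 5, bonferroni_factor = 3)
  expect_length(pe$null_accuracies, 60)
  expect_gte(pe$p_value, 1 / 60)
  expect_equal(pe$p_bonferroni, min(3 * pe$p_value, 1))
  # actual = 0 can never beat the null -> p = 1
  pe0 <- permutation_test(dat$X, dat$y, folds, n_features = 10L,
                          n_perm = 30, actual_accuracy = 0, seed = 5)
  expect_equal(pe0$p_value, 1)
})

test_that("selection helps when informative features are planted", {
  # accuracy at the true feature count is not worse than using all
  # features, over replicates (monotonicity sanity)
  diffs <- numeric(20)
  for (r in seq_len(20)) {
    dat <- sep_features(n_per = 30, p = 60, n_inf = 10, d_per = 1.5,
                        seed = 600 + r)
    folds <- make_folds(dat$y, k = 5, seed = r)
    cv <- cv_classify(dat$X, dat$y, folds, grid = c(10L, 60L))
    diffs[r] <- cv$mean_accuracy[1] - cv$mean_accuracy[2]
  }
  expect_gte(mean(diffs), -0.02)
})
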