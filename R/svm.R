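# Linear support vector machine, solved in the dual by coordinate
# descent (the LIBLINEAR L1-loss algorithm). No R SVM implementation is
# available in the supported stack, and the classifier is the heart of
# the classification protocol, so it lives here. The bias is handled by
# an appended constant feature, the iteration order is fixed, and no
# randomness is used, so fits are bit-reproducible.

#' Fit a linear SVM (hinge loss, L2 regularization)
#'
#' Solves `min_w 0.5 ||w||^2 + C * sum_i max(0, 1 - y_i w.x_i)` via
#' dual coordinate descent with box constraints `0 <= alpha_i <= C`.
#' The intercept is obtained by augmenting each sample with a constant
#' feature of 1 (so it is weakly regularized, the standard LIBLINEAR
#' treatment).
#'
#' @param X n x p numeric matrix.
#' @param y labels in `{-1, +1}` (numeric) or a factor/character vector
#'   with exactly two levels, the FIRST sorted level coded -1.
#' @param C regularization constant (default 1, the conventional
#'   choice when none is specified).
#' @param max_passes maximum full passes over the data.
#' @param tol convergence tolerance on the maximal projected gradient.
#' @return list of class `linear_svm` with `w` (length p), `b`,
#'   `alpha`, `levels` (NULL for numeric y), `passes`.
#' @export
linear_svm <- function(X, y, C = 1, max_passes = 200, tol = 1e-4) {
  X <- as.matrix(X)
  lv <- NULL
  if (!is.numeric(y)) {
    lv <- sort(unique(as.character(y)))
    if (length(lv) != 2) stop("y must have exactly two classes")
    y <- ifelse(as.character(y) == lv[2], 1, -1)
  }
  if (!all(y %in% c(-1, 1))) stop("numeric y must be in {-1, +1}")
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- nrow(X); p <- ncol(X)
  # n << p in imaging MVPA: work with the (bias-augmented) Gram matrix
  # so each coordinate step is O(n); w is recovered once at the end.
  K <- tcrossprod(X) + 1                 # +1 = appended bias feature
  Qii <- diag(K)
  alpha <- numeric(n)
  f <- numeric(n)                        # f_i = sum_j alpha_j y_j K_ij
  passes <- 0L
  repeat {
    passes <- passes + 1L
    max_pg <- 0
    for (i in seq_len(n)) {
      G <- y[i] * f[i] - 1
      pg <- if (alpha[i] <= 0) min(G, 0)
            else if (alpha[i] >= C) max(G, 0)
            else G
      if (abs(pg) > max_pg) max_pg <- abs(pg)
      if (abs(pg) > 1e-12) {
        a_new <- min(max(alpha[i] - G / Qii[i], 0), C)
        if (a_new != alpha[i]) {
          f <- f + (a_new - alpha[i]) * y[i] * K[, i]
          alpha[i] <- a_new
        }
      }
    }
    if (max_pg < tol || passes >= max_passes) break
  }
  ay <- alpha * y
  w <- drop(crossprod(X, ay))
  structure(list(w = w, b = sum(ay), alpha = alpha,
                 C = C, levels = lv, passes = passes),
            class = "linear_svm")
}

#' Decision values of a fitted linear SVM
#'
#' @param object a `linear_svm`.
#' @param newdata n x p matrix.
#' @param type `"decision"` (signed margin) or `"class"`.
#' @param ... unused.
#' @return numeric decision values, or predicted labels.
#' @export
predict.linear_svm <- function(object, newdata,
                               type = c("decision", "class"), ...) {
  type <- match.arg(type)
  d <- as.matrix(newdata) %*% object$w + object$b
  d <- drop(d)
  if (type == "decision") return(d)
  if (is.null(object$levels)) return(ifelse(d >= 0, 1, -1))
  ifelse(d >= 0, object$levels[2], object$levels[1])
}
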