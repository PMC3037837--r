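#' Train a soft-margin linear SVM
#'
#' Solves the dual of the maximum-margin problem with an SMO solver
#' (maximal-violating-pair working-set selection).  The returned model
#' satisfies the stationarity identities of the Lagrangian: the weight
#' vector is the alpha-weighted combination of training samples,
#' \eqn{W = \sum_i \alpha_i y_i X_i}, and \eqn{\sum_i y_i \alpha_i = 0};
#' samples with \eqn{\alpha_i > 0} are the support vectors.
#'
#' @param X numeric matrix, samples in rows, features in columns.
#' @param y labels: +1/-1 (a 2-level factor is coerced, second level = +1).
#' @param C soft-margin cost (default 1).
#' @param eps SMO stopping tolerance on the KKT gap.
#' @return object of class `linear_svm`: `w`, `b`, `alpha`,
#'   `support` (indices with alpha > 0), plus the training call details.
#' @export
train_linear_svm <- function(X, y, C = 1, eps = 1e-10) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- ifelse(as.integer(y) == 2L, 1, -1)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1")
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (C <= 0) stop("C must be positive")
  K <- tcrossprod(X)
  fit <- .smo_solve(K, y, C, eps = eps)
  alpha <- fit$alpha
  alpha[alpha < 1e-12] <- 0          # clean numerically-zero multipliers
  w <- drop(crossprod(X, alpha * y))
  structure(list(w = w, b = fit$b, alpha = alpha,
                 support = which(alpha > 0), C = C,
                 iterations = fit$iterations, kkt_gap = fit$kkt_gap,
                 converged = fit$converged),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("linear_svm: %d features, %d support vectors, C=%g\n",
              length(x$w), length(x$support), x$C))
  invisible(x)
}

#' @rdname train_linear_svm
#' @param object a `linear_svm` model.
#' @param newdata samples-by-features matrix.
#' @param type `"class"` (+1/-1) or `"decision"` (raw scores).
#' @param ... unused.
#' @export
predict.linear_svm <- function(object, newdata, type = c("class", "decision"),
                               ...) {
  type <- match.arg(type)
  f <- drop(as.matrix(newdata) %*% object$w) + object$b
  if (type == "decision") f else ifelse(f >= 0, 1, -1)
}

# kernel-space SMO fit + prediction used by the RFE inner loops: avoids
# forming w for every candidate subset
svm_fit_kernel <- function(K, y, C, eps = 1e-8) {
  fit <- .smo_solve(K, y, C, eps = eps)
  list(coef = fit$alpha * y, b = fit$b)
}

svm_predict_kernel <- function(fit, K_test_train) {
  drop(K_test_train %*% fit$coef) + fit$b
}

#' Recursive feature elimination with a linear SVM
#'
#' Trains a linear SVM, ranks features by squared weight, removes the
#' lowest-ranked `step` features, and repeats on the survivors until none
#' remain.  Ties in squared weight are broken by original feature order:
#' the earlier feature survives longer.  `step = "auto"` removes the bottom
#' half while more than 100 features remain, then one at a time (the usual
#' speed-up for long gene lists).
#'
#' @param X samples-by-features matrix with column names.
#' @param y +1/-1 labels (or 2-level factor).
#' @param step features removed per round: positive integer, a fraction in
#'   (0,1) of the surviving features, or `"auto"`.
#' @param C soft-margin cost.
#' @return character vector of class `elimination_order`: feature names
#'   from first-eliminated to last-surviving (a permutation of the input
#'   features).
#' @export
rfe_ranking <- function(X, y, step = 1L, C = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (is.factor(y)) y <- ifelse(as.integer(y) == 2L, 1, -1)
  features <- colnames(X)
  remaining <- seq_along(features)
  eliminated <- integer()
  K <- tcrossprod(X)                 # downdated as features leave
  while (length(remaining) > 1L) {
    n_rem <- length(remaining)
    fit <- svm_fit_kernel(K, y, C)
    w <- drop(crossprod(X[, remaining, drop = FALSE], fit$coef))
    n_drop <- if (identical(step, "auto")) {
      if (n_rem > 100L) floor(n_rem / 2) else 1L
    } else if (is.numeric(step) && step > 0 && step < 1) {
      max(1L, floor(n_rem * step))
    } else {
      max(1L, as.integer(step))
    }
    n_drop <- min(n_drop, n_rem - 1L)
    # smallest w^2 leaves first; within ties the later original index leaves
    ord <- order(w^2, -remaining)
    drop_local <- ord[seq_len(n_drop)]
    drop_local <- drop_local[order(w[drop_local]^2, -remaining[drop_local])]
    for (d in remaining[drop_local]) {
      xf <- X[, d]
      K <- K - tcrossprod(xf)        # rank-1 Gram downdate
    }
    eliminated <- c(eliminated, remaining[drop_local])
    remaining <- remaining[-drop_local]
  }
  structure(features[c(eliminated, remaining)], class = "elimination_order")
}

#' Select the best nested subset from an elimination order
#'
#' The elimination order induces nested candidate subsets: for each size
#' *s*, the *s* last-eliminated (most important) features.  Every candidate
#' is scored by stratified internal cross-validation on the training data
#' only, and the smallest subset attaining the maximum mean accuracy is
#' returned (parsimony tie-break).
#'
#' @param order an `elimination_order` from [rfe_ranking()].
#' @param X,y training data (the same passed to [rfe_ranking()]).
#' @param inner_folds folds for the internal CV (default 5).
#' @param C soft-margin cost.
#' @param seed seed for the internal fold assignment.
#' @return character vector of selected feature names, with attribute
#'   `accuracy` (per-size mean internal-CV accuracy).
#' @export
select_best_subset <- function(order, X, y, inner_folds = 5L, C = 1,
                               seed = 1L) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- ifelse(as.integer(y) == 2L, 1, -1)
  n <- length(order)
  stopifnot(n >= 1L, all(order %in% colnames(X)))
  ranked <- rev(order)               # most important first
  folds <- make_folds(factor(y), folds = inner_folds, seed = seed)
  ns <- nrow(X)
  K <- matrix(0, ns, ns)
  acc <- numeric(n)
  for (s in seq_len(n)) {
    xf <- X[, ranked[s]]
    K <- K + tcrossprod(xf)          # incremental Gram for the size-s prefix
    correct <- 0L; total <- 0L
    for (f in seq_along(folds)) {
      test <- folds[[f]]; train <- setdiff(seq_len(ns), test)
      if (length(unique(y[train])) < 2L) next
      fit <- svm_fit_kernel(K[train, train, drop = FALSE], y[train], C)
      pred <- sign(svm_predict_kernel(fit, K[test, train, drop = FALSE]))
      pred[pred == 0] <- 1
      correct <- correct + sum(pred == y[test])
      total <- total + length(test)
    }
    acc[s] <- if (total > 0) correct / total else NA_real_
  }
  best <- which.max(acc)             # first max = smallest subset
  structure(ranked[seq_len(best)], accuracy = acc)
}
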