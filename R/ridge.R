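#' L2-regularized logistic regression (IRLS)
#'
#' Fits `logit P(y=1) = b0 + X beta` by iteratively reweighted least squares
#' with ridge penalty `lambda/2 * (||beta||^2 + b0^2)`. The intercept is
#' penalized together with the weights: the 2AFC designs this estimator is
#' used on are balanced and symmetric, so "no evidence-independent bias" is
#' the natural shrinkage target (see the methods vignette). Predictors are
#' used on their native scale (the generator emits z-scored features).
#'
#' @param X numeric matrix, n x p.
#' @param y logical or 0/1 vector of length n.
#' @param lambda non-negative ridge penalty.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient change.
#' @return list with `beta` (p), `intercept`, `lambda`, `converged`,
#'   `loglik` (unpenalized).
#' @export
ridge_logistic <- function(X, y, lambda, max_iter = 100L, tol = 1e-10) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), lambda >= 0, nrow(X) == length(y))
  n <- nrow(X); p <- ncol(X)
  Xt <- cbind(`(intercept)` = 1, X)
  pen <- diag(rep(lambda, p + 1L))
  b <- numeric(p + 1L)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.vector(Xt %*% b)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    # penalized IRLS normal equations
    H <- crossprod(Xt * w, Xt) + pen
    g <- crossprod(Xt, y - mu) - lambda * b
    step <- solve(H, g)
    b_new <- b + as.vector(step)
    if (max(abs(b_new - b)) < tol) {
      b <- b_new; converged <- TRUE; break
    }
    b <- b_new
  }
  eta <- as.vector(Xt %*% b)
  ll <- sum(y * eta - log1p(exp(eta)))
  list(beta = stats::setNames(b[-1L], colnames(X)), intercept = b[1L],
       lambda = lambda, converged = converged, loglik = ll)
}

#' Predicted P(y = 1) from a ridge logistic fit
#' @param fit a fit from [ridge_logistic()].
#' @param X predictor matrix.
#' @return vector of probabilities.
#' @export
predict_ridge <- function(fit, X) {
  stats::plogis(fit$intercept + as.vector(as.matrix(X) %*% fit$beta))
}

# default penalty grid (documented: log-spaced, shared by encoding and
# readout fits)
kc_lambda_grid <- function() 10^seq(-3, 3, length.out = 13)

# Stratified fold assignment: labels are split evenly over folds; when
# `groups` is given (encoding fits group by stimulus pair), whole groups are
# assigned to folds by size-greedy balancing after a seeded shuffle. A
# single label-independent shuffle drives the assignment, so flipping every
# label (interval antisymmetry) leaves the fold partition unchanged.
stratified_folds <- function(y, k, seed, groups = NULL) {
  n <- length(y)
  set.seed(seed)
  fold <- integer(n)
  if (is.null(groups)) {
    ord <- sample.int(n)
    for (cl in sort(unique(y))) {
      idx <- ord[y[ord] == cl]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    gs <- split(seq_len(n), groups)
    gs <- gs[sample(length(gs))]
    load <- numeric(k)
    for (g in gs) {
      f <- which.min(load)
      fold[g] <- f
      load[f] <- load[f] + length(g)
    }
  }
  fold
}

# mean held-out log-loss over an inner CV for each lambda in the grid;
# ties in the selection break toward the larger (more regularized) lambda
select_lambda <- function(X, y, lambdas, nfolds, seed) {
  y <- as.numeric(y)
  k <- min(nfolds, max(2L, min(table(y))))
  fold <- stratified_folds(y, k, seed)
  loss <- matrix(NA_real_, nrow = k, ncol = length(lambdas))
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) next
    for (j in seq_along(lambdas)) {
      fit <- ridge_logistic(X[tr, , drop = FALSE], y[tr], lambdas[j])
      p <- predict_ridge(fit, X[!tr, , drop = FALSE])
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      loss[f, j] <- -mean(y[!tr] * log(p) + (1 - y[!tr]) * log(1 - p))
    }
  }
  m <- colMeans(loss, na.rm = TRUE)
  best <- max(which(m <= min(m) + 1e-12))
  list(lambda = lambdas[best], cv_loss = m)
}

# Full nested-CV classifier fit shared by encoding and readout models:
# outer stratified k-fold (optionally grouped), inner penalty selection per
# outer training set, Heaviside prediction rule with the 0.5 tie resolved as
# the negative class (large_first).
cv_ridge_fit <- function(X, y, k = 10L, seed = 1L, lambdas = kc_lambda_grid(),
                         inner_folds = 5L, groups = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (length(unique(y)) < 2L) stop("both response classes must be present")
  k <- min(k, min(table(y)) * 2L, n)
  fold <- stratified_folds(y, k, seed, groups = groups)
  pred <- numeric(n)
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    sel <- select_lambda(X[tr, , drop = FALSE], y[tr], lambdas, inner_folds,
                         seed = seed + f)
    fit <- ridge_logistic(X[tr, , drop = FALSE], y[tr], sel$lambda)
    pred[!tr] <- predict_ridge(fit, X[!tr, , drop = FALSE])
    cls <- pred[!tr] > 0.5
    fold_acc[f] <- mean(cls == (y[!tr] == 1))
  }
  sel_all <- select_lambda(X, y, lambdas, inner_folds, seed = seed)
  final <- ridge_logistic(X, y, sel_all$lambda)
  acc <- mean((pred > 0.5) == (y == 1))
  list(beta = final$beta, intercept = final$intercept,
       lambda = sel_all$lambda, cv_accuracy = acc,
       fold_accuracy = fold_acc,
       cv_sem = stats::sd(fold_acc) / sqrt(length(fold_acc)),
       fold_assignments = fold, cv_prob = pred)
}
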