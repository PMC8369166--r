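## Regularized multi-task linear regression (RMTLR).
##
## Objective, for N samples, p features, q tasks:
##   (1/N) sum_i || y_i - beta0 - x_i beta ||_2^2
##     + lambda * sum_j ( (1-alpha) ||beta_j||_2 + alpha ||beta_j||_2^2 )
## where beta_j is the j-th feature row shared across tasks. The group-lasso
## term carries (1-alpha), the ridge term alpha; this is the reverse of the
## glmnet convention, so a `convention` flag maps between the two.

effective_alpha <- function(alpha, convention) {
  if (convention == "swapped") 1 - alpha else alpha
}

#' RMTLR objective value
#'
#' @param X samples x features matrix.
#' @param Y samples x tasks matrix.
#' @param beta features x tasks coefficient matrix.
#' @param beta0 per-task intercept vector.
#' @param lambda,alpha penalty strength and mix.
#' @param convention `"as_printed"` (group-lasso weighted by 1 - alpha,
#'   the default) or `"swapped"` (glmnet-style).
#' @return Scalar objective value.
#' @export
rmtlr_objective <- function(X, Y, beta, beta0, lambda, alpha,
                            convention = c("as_printed", "swapped")) {
  convention <- match.arg(convention)
  a <- effective_alpha(alpha, convention)
  R <- Y - matrix(beta0, nrow(Y), ncol(Y), byrow = TRUE) - X %*% beta
  row_norms <- sqrt(rowSums(beta^2))
  sum(R^2) / nrow(Y) +
    lambda * sum((1 - a) * row_norms + a * row_norms^2)
}

#' Smallest penalty that zeroes every coefficient row
#'
#' Computed from the data as the smallest lambda for which the groupwise
#' soft-threshold kills all feature rows at beta = 0. For alpha = 1 (pure
#' ridge under the printed convention) no finite lambda gives exact zeros;
#' the group weight is floored at 1e-3 to keep the path generator usable.
#'
#' @inheritParams rmtlr_objective
#' @return Scalar lambda_max.
#' @export
rmtlr_lambda_max <- function(X, Y, alpha = 0.5,
                             convention = c("as_printed", "swapped")) {
  convention <- match.arg(convention)
  a <- effective_alpha(alpha, convention)
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  C0 <- crossprod(Xc, Yc) / nrow(X) # p x q
  max(sqrt(rowSums((2 * C0)^2))) / max(1 - a, 1e-3)
}

#' Fit a regularized multi-task linear regression
#'
#' Minimizes the printed objective by block coordinate descent over feature
#' rows with groupwise soft-thresholding: with c_j the (doubled) per-task
#' partial-residual correlation of feature j, the row update is
#' `beta_j = c_j * (||c_j|| - lambda (1-alpha))_+ / (||c_j|| (d_j + 2 lambda alpha))`,
#' which for unit-norm features reduces to the
#' `(2||r_j|| - lambda(1-alpha))_+ / (2 + 2 lambda alpha)` form. The
#' intercept is handled by centering, so `beta0 = mean(Y) - mean(X) beta`.
#' Entire rows are zero or free: a feature is selected for all tasks or
#' none (group sparsity).
#'
#' @param X samples x features numeric matrix.
#' @param Y samples x tasks numeric matrix (a vector is treated as one task).
#' @param lambda penalty strength (>= 0).
#' @param alpha penalty mix in `[0, 1]`; under the default convention
#'   `1 - alpha` weighs the group-lasso term and `alpha` the ridge term.
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change per sweep.
#' @param max_iter maximum number of sweeps.
#' @param convention see [rmtlr_objective()].
#' @param beta_init optional warm-start coefficient matrix (p x q).
#' @return An object of class `rmtlr_model`.
#' @export
rmtlr_fit <- function(X, Y, lambda, alpha = 0.5, tol = 1e-6,
                      max_iter = 10000L,
                      convention = c("as_printed", "swapped"),
                      beta_init = NULL) {
  convention <- match.arg(convention)
  a <- effective_alpha(alpha, convention)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop2("rmtlr_fit: non-finite values in X or Y")
  if (nrow(X) != nrow(Y)) stop2("X and Y need the same number of samples")
  if (nrow(X) < 2L) stop2("rmtlr_fit needs at least 2 samples")
  if (lambda < 0 || alpha < 0 || alpha > 1) stop2("invalid lambda or alpha")
  N <- nrow(X); p <- ncol(X); q <- ncol(Y)
  xbar <- colMeans(X); ybar <- colMeans(Y)
  Xc <- sweep(X, 2L, xbar); Yc <- sweep(Y, 2L, ybar)
  G <- crossprod(Xc) / N       # p x p
  C0 <- crossprod(Xc, Yc) / N  # p x q
  d <- 2 * diag(G)
  B0 <- if (is.null(beta_init)) matrix(0, p, q) else unname(as.matrix(beta_init))
  res <- rmtlr_cd(G, C0, d, lambda, a, tol, as.integer(max_iter), B0)
  B <- res$B
  beta0 <- ybar - drop(crossprod(B, xbar))
  if (!res$converged) {
    obj <- rmtlr_objective(X, Y, B, beta0, lambda, alpha, convention)
    warn2(sprintf("rmtlr_fit: max_iter reached (last sweep delta %.3g, objective %.6g)",
                  res$delta, obj))
  }
  iter <- res$iter
  converged <- res$converged
  dimnames(B) <- list(colnames(X), colnames(Y))
  names(beta0) <- colnames(Y)
  structure(list(beta = B, beta0 = beta0, lambda = lambda, alpha = alpha,
                 convention = convention, n_train = N, p = p, q = q,
                 n_sweeps = iter, converged = converged,
                 standardization = NULL,
                 feature_names = colnames(X), task_names = colnames(Y)),
            class = "rmtlr_model")
}

#' @export
print.rmtlr_model <- function(x, ...) {
  cat(sprintf("<rmtlr_model> p=%d features, q=%d tasks, lambda=%.4g, alpha=%.3g, %d nonzero rows\n",
              x$p, x$q, x$lambda, x$alpha, sum(rowSums(x$beta != 0) > 0L)))
  invisible(x)
}

#' Predict from an RMTLR model
#'
#' Applies the stored feature standardizer (when present), computes
#' `beta0 + X beta`, and maps predictions back to the task scale using the
#' stored task standardization statistics (when present).
#'
#' @param model an `rmtlr_model`.
#' @param X_new samples x features matrix containing at least the model's
#'   features (matched by name when both are named).
#' @return samples x tasks prediction matrix.
#' @export
rmtlr_predict <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (!is.null(model$feature_names) && !is.null(colnames(X_new))) {
    missing <- setdiff(model$feature_names, colnames(X_new))
    if (length(missing))
      stop2("missing features in new data: ", paste(missing, collapse = ", "))
    X_new <- X_new[, model$feature_names, drop = FALSE]
  } else if (ncol(X_new) != model$p) {
    stop2("new data has ", ncol(X_new), " features; model expects ", model$p)
  }
  s <- model$standardization
  if (!is.null(s))
    X_new <- apply_standardizer(s$x, X_new)
  pred <- matrix(model$beta0, nrow(X_new), model$q, byrow = TRUE) +
    X_new %*% model$beta
  if (!is.null(s) && !is.null(s$y))
    pred <- sweep(sweep(pred, 2L, ifelse(s$y$sd > 0, s$y$sd, 1), `*`),
                  2L, s$y$mean, `+`)
  rownames(pred) <- rownames(X_new)
  pred
}

#' Tune RMTLR hyperparameters by k-fold cross-validation
#'
#' Builds, per alpha, a geometric lambda path from the data-derived
#' `lambda_max` down to `lambda_min_ratio * lambda_max`, and scores every
#' (lambda, alpha) pair by k-fold cross-validated mean squared error
#' averaged over tasks and folds (folds from a seeded shuffle). Ties are
#' broken toward the larger lambda (stronger regularization).
#'
#' @inheritParams rmtlr_fit
#' @param alpha_grid candidate alpha values.
#' @param n_lambda number of lambda values per alpha.
#' @param k number of folds (default 5).
#' @param seed fold-shuffle seed.
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max.
#' @return List with `lambda`, `alpha`, and the full `cv_error` table
#'   (one row per grid point).
#' @export
rmtlr_cv_tune <- function(X, Y, alpha_grid = 0.5, n_lambda = 20L, k = 5L,
                          seed = 1L, lambda_min_ratio = 0.01, tol = 1e-6,
                          max_iter = 10000L,
                          convention = c("as_printed", "swapped")) {
  convention <- match.arg(convention)
  X <- as.matrix(X); Y <- as.matrix(Y)
  N <- nrow(X)
  if (N < k) stop2("need at least k samples for k-fold cross-validation")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), N))
  grid <- do.call(rbind, lapply(alpha_grid, function(al) {
    lmax <- rmtlr_lambda_max(X, Y, al, convention)
    data.frame(alpha = al,
               lambda = exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                                length.out = n_lambda)))
  }))
  grid$cv_error <- NA_real_
  for (al in unique(grid$alpha)) {
    idx <- which(grid$alpha == al)
    lam_path <- grid$lambda[idx]
    err <- matrix(0, length(lam_path), k)
    for (f in seq_len(k)) {
      tr <- fold != f
      prev <- NULL # warm start along the decreasing lambda path
      for (li in seq_along(lam_path)) {
        fit <- rmtlr_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                         lambda = lam_path[li], alpha = al, tol = tol,
                         max_iter = max_iter, convention = convention,
                         beta_init = prev)
        prev <- fit$beta
        pred <- rmtlr_predict(fit, X[!tr, , drop = FALSE])
        err[li, f] <- mean((Y[!tr, , drop = FALSE] - pred)^2)
      }
    }
    grid$cv_error[idx] <- rowMeans(err)
  }
  best <- which.min(grid$cv_error) # first minimum = largest lambda at ties
  list(lambda = grid$lambda[best], alpha = grid$alpha[best], cv_error = grid)
}

## groupwise KKT residual: for zero rows 2||r_j|| - lambda(1-a) (should be
## <= tol), for active rows the norm of the stationarity residual
rmtlr_kkt <- function(X, Y, model) {
  a <- effective_alpha(model$alpha, model$convention)
  N <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X)); Yc <- sweep(Y, 2L, colMeans(Y))
  R <- Yc - Xc %*% model$beta
  Cj <- 2 * crossprod(Xc, R) / N # p x q
  row_norms <- sqrt(rowSums(model$beta^2))
  viol <- numeric(model$p)
  for (j in seq_len(model$p)) {
    if (row_norms[j] == 0) {
      viol[j] <- max(0, sqrt(sum(Cj[j, ]^2)) - model$lambda * (1 - a))
    } else {
      grad <- -Cj[j, ] + 2 * model$lambda * a * model$beta[j, ] +
        model$lambda * (1 - a) * model$beta[j, ] / row_norms[j]
      viol[j] <- sqrt(sum(grad^2))
    }
  }
  viol
}
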