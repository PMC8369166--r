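#' Gaussian kernel between two sample sets
#'
#' `K[i, j] = exp(-||x_i - x_j||^2 / (2 sigma^2))`.
#'
#' @param X1 samples x features matrix.
#' @param X2 samples x features matrix with the same features.
#' @param sigma kernel width (> 0); see [kernel_width_median()] for the
#'   default heuristic.
#' @return `nrow(X1)` x `nrow(X2)` kernel matrix.
#' @export
gaussian_kernel <- function(X1, X2, sigma) {
  if (sigma <= 0) stop2("gaussian_kernel: sigma must be > 0")
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X1) != ncol(X2)) stop2("gaussian_kernel: feature dimensions differ")
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Median-heuristic kernel width
#'
#' Median of the pairwise Euclidean distances between training samples, a
#' standard default when no width is given.
#'
#' @param X samples x features matrix.
#' @return Scalar width (falls back to 1 when the median is 0).
#' @export
kernel_width_median <- function(X) {
  d <- stats::dist(as.matrix(X))
  m <- stats::median(d)
  if (!is.finite(m) || m <= 0) 1 else m
}

bemkl_default_priors <- function() {
  list(alpha_lambda = 1, beta_lambda = 1, alpha_upsilon = 1, beta_upsilon = 1,
       alpha_gamma = 1, beta_gamma = 1, alpha_omega = 1, beta_omega = 1,
       alpha_epsilon = 1, beta_epsilon = 1)
}

check_kernels <- function(kernels, n = NULL) {
  if (!length(kernels)) stop2("need at least one kernel")
  for (m in seq_along(kernels)) {
    K <- kernels[[m]]
    if (!is.matrix(K) || nrow(K) != ncol(K))
      stop2("kernel ", m, " is not square")
    if (!is.null(n) && nrow(K) != n)
      stop2("kernel ", m, " has ", nrow(K), " rows; expected ", n)
    ev <- min(eigen((K + t(K)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values)
    if (ev < -1e-6)
      stop2(sprintf("kernel %d is not positive semidefinite (min eigenvalue %.3g)",
                    m, ev))
  }
  invisible(TRUE)
}

#' Fit a Bayesian multiple-kernel learning regression
#'
#' Multi-task variational Bayesian kernel regression:
#' `f(x) = a^T (sum_m e_m k_m(x)) + b`, with gamma priors on all
#' precisions, kernel weights `e` shared across tasks, and sample weights
#' `a` and bias `b` per task. Each kernel feeds an intermediate
#' representation `g_m = K_m a` whose noisy combination `e^T g + b`
#' regresses the task. The posterior is a fully factorized mean-field
#' approximation updated deterministically for `n_iter` iterations, so the
#' fit is reproducible given inputs and prior hyperparameters.
#'
#' @param kernels list of M training kernel matrices (N x N, PSD).
#' @param Y samples x tasks numeric matrix.
#' @param priors named list of gamma shape/rate hyperparameters
#'   (`alpha_lambda`, `beta_lambda`, `alpha_upsilon`, `beta_upsilon`,
#'   `alpha_gamma`, `beta_gamma`, `alpha_omega`, `beta_omega`,
#'   `alpha_epsilon`, `beta_epsilon`); defaults all 1.
#' @param n_iter number of variational update sweeps (default 200).
#' @return An object of class `bemkl_model` with posterior means/variances
#'   for all factors.
#' @export
bemkl_fit <- function(kernels, Y, priors = list(), n_iter = 200L) {
  Y <- as.matrix(Y)
  N <- nrow(Y); q <- ncol(Y); M <- length(kernels)
  kernels <- lapply(kernels, function(K) (as.matrix(K) + t(as.matrix(K))) / 2)
  check_kernels(kernels, N)
  pr <- utils::modifyList(bemkl_default_priors(), priors)
  KK_sum <- Reduce(`+`, lapply(kernels, function(K) K %*% K))

  ## state: weights start at 0, kernel-combination factors at 1
  mu_a <- matrix(0, N, q); var_a <- matrix(1, N, q)
  Sigma_a <- replicate(q, diag(N), simplify = FALSE)
  mu_G <- lapply(seq_len(q), function(t) matrix(Y[, t] / M, M, N, byrow = TRUE))
  Sigma_G <- replicate(q, diag(M), simplify = FALSE)
  mu_e <- rep(1, M); Sigma_e <- diag(M)
  b_mean <- rep(0, q); b_var <- rep(1, q)
  lambda_mean <- matrix(1, N, q)
  upsilon_mean <- rep(1, q); gamma_mean <- rep(1, q)
  eps_mean <- rep(1, q); omega_mean <- rep(1, M)

  for (it in seq_len(n_iter)) {
    GG <- vector("list", q)
    for (t in seq_len(q)) {
      y <- Y[, t]
      ## lambda (per-element precision of a)
      lambda_mean[, t] <- (pr$alpha_lambda + 0.5) /
        (pr$beta_lambda + 0.5 * (mu_a[, t]^2 + var_a[, t]))
      ## a
      prec_a <- diag(lambda_mean[, t], N) + upsilon_mean[t] * KK_sum
      Sigma_a[[t]] <- chol2inv(chol(prec_a))
      kg <- Reduce(`+`, lapply(seq_len(M), function(m)
        kernels[[m]] %*% mu_G[[t]][m, ]))
      mu_a[, t] <- drop(Sigma_a[[t]] %*% (upsilon_mean[t] * kg))
      var_a[, t] <- diag(Sigma_a[[t]])
      Ka <- t(vapply(kernels, function(K) drop(K %*% mu_a[, t]), numeric(N)))
      ## upsilon (precision of the intermediate representations)
      tr_term <- sum(vapply(kernels, function(K)
        sum(K * (Sigma_a[[t]] %*% K)), numeric(1L)))
      ups_rate <- pr$beta_upsilon + 0.5 *
        (sum((mu_G[[t]] - Ka)^2) + N * sum(diag(Sigma_G[[t]])) + tr_term)
      upsilon_mean[t] <- (pr$alpha_upsilon + 0.5 * N * M) / ups_rate
      ## G
      EeeT <- tcrossprod(mu_e) + Sigma_e
      Sigma_G[[t]] <- chol2inv(chol(diag(upsilon_mean[t], M) +
                                      eps_mean[t] * EeeT))
      mu_G[[t]] <- Sigma_G[[t]] %*%
        (upsilon_mean[t] * Ka + eps_mean[t] * tcrossprod(mu_e, y - b_mean[t]))
      GG[[t]] <- tcrossprod(mu_G[[t]]) + N * Sigma_G[[t]]
      ## gamma and b (bias)
      gamma_mean[t] <- (pr$alpha_gamma + 0.5) /
        (pr$beta_gamma + 0.5 * (b_mean[t]^2 + b_var[t]))
      b_var[t] <- 1 / (gamma_mean[t] + N * eps_mean[t])
      fit_t <- drop(crossprod(mu_G[[t]], mu_e))
      b_mean[t] <- eps_mean[t] * sum(y - fit_t) * b_var[t]
      ## epsilon (output noise)
      eps_rate <- pr$beta_epsilon + 0.5 *
        (sum(y^2) - 2 * sum(y * (fit_t + b_mean[t])) +
           sum(EeeT * GG[[t]]) + 2 * b_mean[t] * sum(fit_t) +
           N * (b_mean[t]^2 + b_var[t]))
      eps_mean[t] <- (pr$alpha_epsilon + 0.5 * N) / max(eps_rate, 1e-12)
    }
    ## omega and e (shared kernel weights)
    omega_mean <- (pr$alpha_omega + 0.5) /
      (pr$beta_omega + 0.5 * (mu_e^2 + diag(Sigma_e)))
    prec_e <- diag(omega_mean, M) +
      Reduce(`+`, lapply(seq_len(q), function(t) eps_mean[t] * GG[[t]]))
    Sigma_e <- chol2inv(chol(prec_e))
    mu_e <- drop(Sigma_e %*%
                   Reduce(`+`, lapply(seq_len(q), function(t)
                     eps_mean[t] * (mu_G[[t]] %*% (Y[, t] - b_mean[t])))))
    state <- c(mu_a, mu_e, b_mean, eps_mean, upsilon_mean)
    if (any(!is.finite(state)))
      stop2("bemkl_fit: divergent (non-finite) update at iteration ", it)
  }
  dimnames(mu_a) <- list(rownames(Y), colnames(Y))
  structure(list(mu_a = mu_a, var_a = var_a, mu_e = mu_e, Sigma_e = Sigma_e,
                 b_mean = b_mean, b_var = b_var,
                 lambda_mean = lambda_mean, upsilon_mean = upsilon_mean,
                 gamma_mean = gamma_mean, omega_mean = omega_mean,
                 eps_mean = eps_mean, priors = pr, n_iter = n_iter,
                 n_train = N, n_kernels = M, q = q,
                 task_names = colnames(Y)),
            class = "bemkl_model")
}

#' @export
print.bemkl_model <- function(x, ...) {
  cat(sprintf("<bemkl_model> %d kernels, %d tasks, N=%d; kernel weights: %s\n",
              x$n_kernels, x$q, x$n_train,
              paste(sprintf("%.3f", x$mu_e), collapse = ", ")))
  invisible(x)
}

#' Predict from a BEMKL model
#'
#' Posterior predictive mean per task: the e-weighted combination of the
#' test-vs-train kernels applied to the task's sample weights, plus the
#' task bias.
#'
#' @param model a `bemkl_model`.
#' @param test_kernels list of M matrices (N_test x N_train), one per
#'   training kernel.
#' @return N_test x tasks prediction matrix.
#' @export
bemkl_predict <- function(model, test_kernels) {
  if (length(test_kernels) != model$n_kernels)
    stop2("expected ", model$n_kernels, " test kernels, got ",
          length(test_kernels))
  test_kernels <- lapply(test_kernels, as.matrix)
  for (m in seq_along(test_kernels))
    if (ncol(test_kernels[[m]]) != model$n_train)
      stop2("test kernel ", m, " has ", ncol(test_kernels[[m]]),
            " columns; expected ", model$n_train)
  Kc <- Reduce(`+`, Map(function(K, e) e * K, test_kernels,
                        as.list(model$mu_e)))
  pred <- Kc %*% model$mu_a +
    matrix(model$b_mean, nrow(Kc), model$q, byrow = TRUE)
  colnames(pred) <- model$task_names
  rownames(pred) <- rownames(test_kernels[[1L]])
  pred
}
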