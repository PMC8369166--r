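make_rmtlr_instance <- function(seed = 42, N = 100, p = 20, q = 5,
                                noise = 0.5, support = 5) {
  set.seed(seed)
  X <- matrix(rnorm(N * p), N, p, dimnames = list(NULL, paste0("f", 1:p)))
  B <- matrix(0, p, q)
  B[seq_len(support), ] <- rnorm(support * q)
  Y <- X %*% B + noise * matrix(rnorm(N * q), N, q)
  colnames(Y) <- paste0("t", 1:q)
  list(X = X, Y = Y, B = B)
}

test_that("standardizer maps train to zero mean / unit SD and test via train stats", {
  set.seed(1)
  tr <- matrix(rnorm(60, mean = 5, sd = 3), 20, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  tr[, 3] <- 7 # constant column
  s <- fit_standardizer(tr)
  ts <- apply_standardizer(s, tr)
  expect_equal(unname(colMeans(ts)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(ts[, 1:2], 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_true(all(ts[, 3] == 0) && s$constant["c"])
  te <- matrix(s$mean, 1, 3, byrow = TRUE, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(unname(apply_standardizer(s, te)[1, ]), c(0, 0, 0))
})

test_that("coordinate descent matches an independent proximal-gradient oracle", {
  inst <- make_rmtlr_instance(seed = 42, N = 100, p = 20, q = 5)
  fit <- rmtlr_fit(inst$X, inst$Y, lambda = 0.1, alpha = 0.5, tol = 1e-9)
  oracle <- prox_grad_rmtlr(inst$X, inst$Y, lambda = 0.1, alpha = 0.5)
  obj_cd <- rmtlr_objective(inst$X, inst$Y, fit$beta, fit$beta0, 0.1, 0.5)
  expect_lt(abs(obj_cd - oracle$objective) / oracle$objective, 1e-6)
  expect_equal(fit$beta, oracle$beta, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("lambda >= lambda_max shrinks everything; lambda = 0 is OLS", {
  inst <- make_rmtlr_instance(seed = 7, N = 60, p = 10, q = 3)
  lmax <- rmtlr_lambda_max(inst$X, inst$Y, alpha = 0.5)
  f1 <- rmtlr_fit(inst$X, inst$Y, lambda = lmax * (1 + 1e-8), alpha = 0.5)
  expect_true(all(f1$beta == 0))
  expect_equal(unname(f1$beta0), unname(colMeans(inst$Y)))
  f2 <- rmtlr_fit(inst$X, inst$Y, lambda = lmax * 0.99, alpha = 0.5)
  expect_gt(sum(f2$beta != 0), 0) # lambda_max is tight
  f0 <- rmtlr_fit(inst$X, inst$Y, lambda = 0, alpha = 0.5, tol = 1e-10)
  ols <- lm.fit(cbind(1, inst$X), inst$Y)$coefficients
  expect_lt(max(abs(f0$beta - ols[-1, ])), 1e-6)
  expect_lt(max(abs(f0$beta0 - ols[1, ])), 1e-6)
})

test_that("group sparsity is exact and KKT conditions hold at the solution", {
  inst <- make_rmtlr_instance(seed = 9)
  fit <- rmtlr_fit(inst$X, inst$Y, lambda = 0.3, alpha = 0.5, tol = 1e-9)
  row_nonzero <- rowSums(fit$beta != 0)
  expect_true(all(row_nonzero %in% c(0L, ncol(inst$Y)))) # all tasks or none
  expect_gt(sum(row_nonzero == 0), 0) # the penalty actually bites here
  expect_lt(max(tmemark:::rmtlr_kkt(inst$X, inst$Y, fit)), 1e-5)
})

test_that("the objective is non-increasing across sweeps", {
  inst <- make_rmtlr_instance(seed = 11, N = 50, p = 8, q = 2)
  objs <- vapply(1:12, function(it) {
    f <- suppressWarnings(rmtlr_fit(inst$X, inst$Y, 0.2, 0.5, tol = 0,
                                    max_iter = it))
    rmtlr_objective(inst$X, inst$Y, f$beta, f$beta0, 0.2, 0.5)
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("q = 1, alpha = 1 reduces to ridge regression (printed convention)", {
  inst <- make_rmtlr_instance(seed = 13, N = 80, p = 12, q = 1)
  lam <- 0.4
  fit <- rmtlr_fit(inst$X, inst$Y, lam, alpha = 1, tol = 1e-10)
  Xc <- scale(inst$X, scale = FALSE); Yc <- scale(inst$Y, scale = FALSE)
  ridge <- solve(crossprod(Xc) / nrow(Xc) + lam * diag(ncol(Xc)),
                 crossprod(Xc, Yc) / nrow(Xc))
  expect_lt(max(abs(fit$beta - ridge)), 1e-6)
})

test_that("the convention flag swaps the two penalty terms", {
  inst <- make_rmtlr_instance(seed = 15, N = 50, p = 8, q = 2)
  f1 <- rmtlr_fit(inst$X, inst$Y, 0.2, alpha = 0.3)
  f2 <- rmtlr_fit(inst$X, inst$Y, 0.2, alpha = 0.7, convention = "swapped")
  expect_equal(f1$beta, f2$beta)
})

test_that("prediction applies intercepts and errors on missing features", {
  inst <- make_rmtlr_instance(seed = 17, N = 40, p = 6, q = 2)
  f0 <- rmtlr_fit(inst$X, inst$Y, lambda = 1e6, alpha = 0.5) # all-zero beta
  pred <- rmtlr_predict(f0, inst$X)
  expect_equal(pred, matrix(f0$beta0, nrow(inst$X), 2, byrow = TRUE),
               ignore_attr = TRUE)
  # OLS residuals orthogonal to the design
  fo <- rmtlr_fit(inst$X, inst$Y, 0, 0.5, tol = 1e-10)
  res <- inst$Y - rmtlr_predict(fo, inst$X)
  expect_lt(max(abs(crossprod(inst$X, res))), 1e-6)
  # duplicate rows predict identically; missing features error
  X2 <- inst$X[c(1, 1, 2), ]
  p2 <- rmtlr_predict(fo, X2)
  expect_equal(p2[1, ], p2[2, ])
  expect_error(rmtlr_predict(fo, inst$X[, 1:3]), "missing features")
})

test_that("cross-validated tuning matches a brute-force CV loop", {
  inst <- make_rmtlr_instance(seed = 19, N = 60, p = 10, q = 3)
  tuned <- rmtlr_cv_tune(inst$X, inst$Y, alpha_grid = c(0.3, 0.7),
                         n_lambda = 5, k = 4, seed = 99)
  # independent loop: same folds, cold-started fits
  set.seed(99)
  fold <- sample(rep_len(1:4, nrow(inst$X)))
  for (i in seq_len(nrow(tuned$cv_error))) {
    al <- tuned$cv_error$alpha[i]; lam <- tuned$cv_error$lambda[i]
    errs <- vapply(1:4, function(f) {
      tr <- fold != f
      fit <- rmtlr_fit(inst$X[tr, ], inst$Y[tr, ], lam, al, tol = 1e-8)
      mean((inst$Y[!tr, ] - rmtlr_predict(fit, inst$X[!tr, ]))^2)
    }, numeric(1))
    expect_equal(tuned$cv_error$cv_error[i], mean(errs), tolerance = 1e-5)
  }
  expect_equal(tuned$cv_error$cv_error[which(
    tuned$cv_error$lambda == tuned$lambda &
      tuned$cv_error$alpha == tuned$alpha)],
    min(tuned$cv_error$cv_error))
  # a one-point grid is returned unchanged
  one <- rmtlr_cv_tune(inst$X, inst$Y, alpha_grid = 0.5, n_lambda = 1,
                       k = 3, seed = 1)
  expect_equal(one$alpha, 0.5)
  expect_equal(one$lambda, rmtlr_lambda_max(inst$X, inst$Y, 0.5))
})

test_that("pure-noise targets select almost nothing in most seeds", {
  # Minimum-CV-error selection on pure noise keeps a handful of features in
  # a minority of seeds (~20% at these sizes, measured over 100 seeds), so
  # the asserted property is the honest one: the median selection is empty
  # and a clear majority of seeds stay below 10% of p.
  p <- 30
  n_selected <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    X <- matrix(rnorm(200 * p), 200, p)
    Y <- matrix(rnorm(200 * 3), 200, 3)
    tuned <- rmtlr_cv_tune(X, Y, alpha_grid = 0.5, n_lambda = 20, k = 5,
                           seed = s)
    fit <- rmtlr_fit(X, Y, tuned$lambda, tuned$alpha)
    sum(rowSums(fit$beta != 0) > 0)
  }, numeric(1))
  expect_equal(median(n_selected), 0)
  expect_gte(sum(n_selected <= 0.1 * p), 12)
})

test_that("non-finite inputs are rejected", {
  inst <- make_rmtlr_instance(seed = 21, N = 20, p = 4, q = 2, support = 2)
  inst$X[1, 1] <- NA
  expect_error(rmtlr_fit(inst$X, inst$Y, 0.1), "non-finite")
})
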