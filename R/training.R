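#' Column standardizer learned from training data
#'
#' Stores per-column mean and standard deviation of the training matrix so
#' that test data can be standardized with training statistics only.
#' Constant columns are flagged and map to zero.
#'
#' @param train numeric matrix (samples x columns).
#' @return An object of class `standardizer`.
#' @export
fit_standardizer <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) == 0L) stop2("cannot fit a standardizer on an empty matrix")
  mu <- colMeans(train)
  sd <- apply(train, 2L, stats::sd)
  sd[is.na(sd)] <- 0
  structure(list(mean = mu, sd = sd, constant = sd == 0,
                 columns = colnames(train)),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param s a `standardizer` from [fit_standardizer()].
#' @param data matrix with the same columns as the training data.
#' @return The standardized matrix; constant training columns become 0.
#' @export
apply_standardizer <- function(s, data) {
  data <- as.matrix(data)
  if (!is.null(s$columns) && !is.null(colnames(data)))
    data <- data[, s$columns, drop = FALSE]
  out <- sweep(data, 2L, s$mean)
  out <- sweep(out, 2L, ifelse(s$constant, 1, s$sd), `/`)
  out[, s$constant] <- 0
  out
}

merge_views <- function(views) {
  if (inherits(views, "view_matrix")) views <- list(views)
  mats <- lapply(views, as.matrix)
  samp <- rownames(mats[[1L]])
  for (m in mats)
    if (!identical(rownames(m), samp))
      stop2("views must cover the same samples in the same order")
  nm <- names(views) %||% vapply(views, function(v)
    if (inherits(v, "view_matrix")) v$view_name else "view", character(1L))
  mats <- Map(function(m, n) {
    colnames(m) <- paste(n, colnames(m), sep = ".")
    m
  }, mats, nm)
  do.call(cbind, mats)
}

spearman_by_task <- function(pred, obs) {
  vapply(seq_len(ncol(obs)), function(t)
    suppressWarnings(stats::cor(pred[, t], obs[, t], method = "spearman")),
    numeric(1L))
}

#' Repeated randomized cross-validation training
#'
#' The core training protocol: `n_runs` times, randomly hold out
#' `test_frac` of the samples, standardize the training split (features
#' and tasks), standardize the held-out split with the training statistics,
#' tune hyperparameters on the training split (RMTLR, by inner k-fold CV)
#' or use the configured priors (BEMKL), fit, and record the held-out
#' Spearman correlation per task. Multiple views are concatenated
#' column-wise for RMTLR and mapped to one Gaussian kernel each for BEMKL.
#' Run seeds derive from the master seed with a counter scheme, so run r
#' is reproducible regardless of `n_runs`.
#'
#' @param views a `view_matrix` (or plain matrix) or named list of them.
#' @param tasks a [task_matrix()] or samples x tasks matrix.
#' @param learner `"rmtlr"` or `"bemkl"`.
#' @param n_runs number of randomized splits (default 100).
#' @param test_frac held-out fraction per run (default 0.2).
#' @param seed master seed.
#' @param alpha_grid,n_lambda,k_folds RMTLR tuning grid.
#' @param bemkl_priors,bemkl_iter BEMKL settings.
#' @param tol,max_iter RMTLR solver control.
#' @return An object of class `model_ensemble` holding the `n_runs` fitted
#'   models, split indices, standardizers, hyperparameters, and per-run
#'   held-out correlations.
#' @export
run_randomized_cv <- function(views, tasks, learner = c("rmtlr", "bemkl"),
                              n_runs = 100L, test_frac = 0.2, seed = 1L,
                              alpha_grid = 0.5, n_lambda = 10L, k_folds = 5L,
                              bemkl_priors = list(), bemkl_iter = 200L,
                              tol = 1e-6, max_iter = 10000L) {
  learner <- match.arg(learner)
  if (inherits(tasks, "task_matrix")) tasks <- tasks$values
  tasks <- as.matrix(tasks)
  if (inherits(views, "view_matrix") || is.matrix(views)) views <- list(views)
  view_names <- names(views) %||% vapply(views, function(v)
    if (inherits(v, "view_matrix")) v$view_name else "view", character(1L))
  names(views) <- view_names
  mats <- lapply(views, as.matrix)
  for (m in mats) {
    if (!identical(rownames(m), rownames(tasks)))
      stop2("view and task sample sets must be identical (same order)")
    if (anyNA(m)) stop2("views must not contain missing values")
  }
  N <- nrow(tasks)
  if (N < 10L) stop2("need at least 10 samples for randomized cross-validation")
  X_all <- merge_views(views)
  n_test <- max(1L, round(test_frac * N))

  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(derive_seed(seed, r))
    test_idx <- sort(sample.int(N, n_test))
    train_idx <- setdiff(seq_len(N), test_idx)
    Y_tr <- tasks[train_idx, , drop = FALSE]
    Y_te <- tasks[test_idx, , drop = FALSE]
    sy <- fit_standardizer(Y_tr)
    Y_trs <- apply_standardizer(sy, Y_tr)
    Y_tes <- apply_standardizer(sy, Y_te)
    if (learner == "rmtlr") {
      X_tr <- X_all[train_idx, , drop = FALSE]
      sx <- fit_standardizer(X_tr)
      X_trs <- apply_standardizer(sx, X_tr)
      X_tes <- apply_standardizer(sx, X_all[test_idx, , drop = FALSE])
      tuned <- rmtlr_cv_tune(X_trs, Y_trs, alpha_grid = alpha_grid,
                             n_lambda = n_lambda, k = k_folds,
                             seed = derive_seed(seed, r + n_runs),
                             tol = tol, max_iter = max_iter)
      fit <- rmtlr_fit(X_trs, Y_trs, lambda = tuned$lambda,
                       alpha = tuned$alpha, tol = tol, max_iter = max_iter)
      pred <- rmtlr_predict(fit, X_tes)
      runs[[r]] <- list(model = fit, train_idx = train_idx,
                        test_idx = test_idx,
                        standardizer_x = sx, standardizer_y = sy,
                        hyperparameters = tuned[c("lambda", "alpha")],
                        test_spearman = spearman_by_task(pred, Y_tes))
    } else {
      sxs <- lapply(mats, function(m) fit_standardizer(m[train_idx, , drop = FALSE]))
      Xtr <- Map(function(m, s) apply_standardizer(s, m[train_idx, , drop = FALSE]),
                 mats, sxs)
      Xte <- Map(function(m, s) apply_standardizer(s, m[test_idx, , drop = FALSE]),
                 mats, sxs)
      sigmas <- vapply(Xtr, kernel_width_median, numeric(1L))
      K_tr <- Map(function(x, s) gaussian_kernel(x, x, s), Xtr, as.list(sigmas))
      K_te <- Map(function(xte, xtr, s) gaussian_kernel(xte, xtr, s),
                  Xte, Xtr, as.list(sigmas))
      fit <- bemkl_fit(unname(K_tr), Y_trs, priors = bemkl_priors,
                       n_iter = bemkl_iter)
      pred <- bemkl_predict(fit, unname(K_te))
      runs[[r]] <- list(model = fit, test_idx = test_idx,
                        standardizer_x = sxs, standardizer_y = sy,
                        hyperparameters = list(sigma = sigmas,
                                               priors = fit$priors,
                                               n_iter = bemkl_iter),
                        train_idx = train_idx,
                        test_spearman = spearman_by_task(pred, Y_tes))
    }
  }
  structure(list(runs = runs, learner = learner, n_runs = n_runs,
                 test_frac = test_frac, seed = seed,
                 view_names = view_names,
                 feature_names = colnames(X_all),
                 task_names = colnames(tasks),
                 sample_ids = rownames(tasks),
                 view_features = lapply(mats, colnames),
                 view_provenance = lapply(views, function(v)
                   if (inherits(v, "view_matrix")) v$provenance else list()),
                 train_views = if (learner == "bemkl") mats),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("<model_ensemble> %s, %d runs, views: %s, %d tasks, N=%d\n",
              x$learner, x$n_runs, paste(x$view_names, collapse = "+"),
              length(x$task_names), length(x$sample_ids)))
  invisible(x)
}

#' Mean held-out performance of an ensemble
#'
#' @param ensemble a `model_ensemble`.
#' @return Named vector: mean test-set Spearman correlation per task
#'   across runs.
#' @export
ensemble_performance <- function(ensemble) {
  rho <- do.call(rbind, lapply(ensemble$runs, `[[`, "test_spearman"))
  colnames(rho) <- ensemble$task_names
  colMeans(rho, na.rm = TRUE)
}

## one-sided-agnostic test of run-weights against zero; the natural
## two-sample rank-sum against a degenerate all-zero sample reduces to a
## one-sample problem, so a signed-rank test is used (flagged in output)
weights_vs_zero_p <- function(w) {
  if (all(w == 0)) return(1)
  suppressWarnings(stats::wilcox.test(w, mu = 0, exact = FALSE)$p.value)
}

#' Extract robust biomarkers from an RMTLR ensemble
#'
#' For every feature and task the 100 run-weights are collected; the
#' per-task median summarizes a feature's selection (a nonzero median means
#' the feature was selected by the regularization in at least half of the
#' runs), and the reported `median_weight` is the median across tasks of
#' the per-task medians. A feature is `robust` when its `median_weight` is
#' nonzero. Per task, the run-weights are tested against zero
#' (signed-rank; see Details) and features significant in fewer than half
#' of the tasks are flagged `low_consistency`. The across-task variance of
#' the per-task medians is reported as a stability diagnostic.
#'
#' @param ensemble an RMTLR `model_ensemble`.
#' @param p_threshold significance threshold per task (default 0.05).
#' @return A data.frame of class `biomarker_table`, one row per feature.
#' @export
extract_biomarkers <- function(ensemble, p_threshold = 0.05) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  if (ensemble$learner != "rmtlr")
    stop2("biomarker extraction is defined for RMTLR ensembles")
  feats <- ensemble$feature_names
  task_names <- ensemble$task_names
  n_runs <- ensemble$n_runs
  q <- length(task_names)
  W <- array(0, dim = c(length(feats), q, n_runs),
             dimnames = list(feats, task_names, NULL))
  for (r in seq_len(n_runs))
    W[, , r] <- ensemble$runs[[r]]$model$beta[feats, task_names]
  per_task_median <- apply(W, c(1L, 2L), stats::median)
  pvals <- apply(W, c(1L, 2L), weights_vs_zero_p)
  median_weight <- apply(per_task_median, 1L, stats::median)
  n_sig <- rowSums(pvals < p_threshold)
  out <- data.frame(
    feature = feats,
    view = sub("\\..*$", "", feats),
    median_weight = median_weight,
    n_significant_tasks = n_sig,
    robust = median_weight != 0,
    low_consistency = n_sig < q / 2,
    across_task_variance = apply(per_task_median, 1L, stats::var),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "per_task_median") <- per_task_median
  attr(out, "per_task_p") <- pvals
  attr(out, "p_threshold") <- p_threshold
  class(out) <- c("biomarker_table", "data.frame")
  out
}

#' Cluster tasks by their biomarker weight profiles
#'
#' Hierarchical clustering (average linkage) of the tasks' feature-weight
#' vectors under the 1 - Pearson correlation distance, cut into `k`
#' clusters.
#'
#' @param weights features x tasks matrix of weights (e.g. the
#'   `per_task_median` attribute of a [extract_biomarkers()] table, or a
#'   `biomarker_table` itself).
#' @param k number of clusters (default 4).
#' @return Named integer vector of cluster memberships per task.
#' @export
cluster_tasks <- function(weights, k = 4L) {
  if (inherits(weights, "biomarker_table"))
    weights <- attr(weights, "per_task_median")
  weights <- as.matrix(weights)
  q <- ncol(weights)
  if (q < 2L) stop2("task clustering needs at least 2 tasks")
  if (k > q) stop2("k (", k, ") exceeds the number of tasks (", q, ")")
  C <- suppressWarnings(stats::cor(weights))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  stats::cutree(hc, k = k)
}
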