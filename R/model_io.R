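MODEL_FORMAT <- "tmemark_model_ensemble"
MODEL_VERSION <- "1"

ser_matrix <- function(m) {
  if (is.null(m)) return(NULL)
  list(rows = rownames(m), cols = colnames(m), values = unname(as.matrix(m)))
}

deser_matrix <- function(x) {
  if (is.null(x)) return(NULL)
  m <- do.call(rbind, lapply(x$values, function(r) as.numeric(unlist(r))))
  dimnames(m) <- list(unlist(x$rows), unlist(x$cols))
  m
}

ser_standardizer <- function(s) {
  list(mean = unname(s$mean), sd = unname(s$sd),
       constant = unname(s$constant), columns = s$columns)
}

deser_standardizer <- function(x) {
  if (is.null(x$mean) || is.null(x$sd))
    stop2("model file lacks standardization statistics")
  cols <- unlist(x$columns)
  structure(list(mean = stats::setNames(unlist(x$mean), cols),
                 sd = stats::setNames(unlist(x$sd), cols),
                 constant = stats::setNames(as.logical(unlist(x$constant)), cols),
                 columns = cols),
            class = "standardizer")
}

ser_model <- function(m) {
  if (inherits(m, "rmtlr_model")) {
    list(type = "rmtlr", beta = ser_matrix(m$beta), beta0 = unname(m$beta0),
         lambda = m$lambda, alpha = m$alpha, convention = m$convention,
         n_train = m$n_train, p = m$p, q = m$q, n_sweeps = m$n_sweeps,
         converged = m$converged,
         feature_names = m$feature_names, task_names = m$task_names)
  } else if (inherits(m, "bemkl_model")) {
    list(type = "bemkl", mu_a = ser_matrix(m$mu_a), var_a = ser_matrix(m$var_a),
         mu_e = m$mu_e, Sigma_e = ser_matrix(m$Sigma_e),
         b_mean = m$b_mean, b_var = m$b_var,
         lambda_mean = ser_matrix(m$lambda_mean),
         upsilon_mean = m$upsilon_mean, gamma_mean = m$gamma_mean,
         omega_mean = m$omega_mean, eps_mean = m$eps_mean,
         priors = m$priors, n_iter = m$n_iter, n_train = m$n_train,
         n_kernels = m$n_kernels, q = m$q, task_names = m$task_names)
  } else stop2("unknown model class")
}

deser_model <- function(x) {
  if (x$type == "rmtlr") {
    structure(list(beta = deser_matrix(x$beta),
                   beta0 = stats::setNames(unlist(x$beta0),
                                           unlist(x$task_names)),
                   lambda = x$lambda, alpha = x$alpha,
                   convention = x$convention, n_train = x$n_train,
                   p = x$p, q = x$q, n_sweeps = x$n_sweeps,
                   converged = x$converged, standardization = NULL,
                   feature_names = unlist(x$feature_names),
                   task_names = unlist(x$task_names)),
              class = "rmtlr_model")
  } else if (x$type == "bemkl") {
    structure(list(mu_a = deser_matrix(x$mu_a), var_a = deser_matrix(x$var_a),
                   mu_e = unlist(x$mu_e), Sigma_e = deser_matrix(x$Sigma_e),
                   b_mean = unlist(x$b_mean), b_var = unlist(x$b_var),
                   lambda_mean = deser_matrix(x$lambda_mean),
                   upsilon_mean = unlist(x$upsilon_mean),
                   gamma_mean = unlist(x$gamma_mean),
                   omega_mean = unlist(x$omega_mean),
                   eps_mean = unlist(x$eps_mean), priors = x$priors,
                   n_iter = x$n_iter, n_train = x$n_train,
                   n_kernels = x$n_kernels, q = x$q,
                   task_names = unlist(x$task_names)),
              class = "bemkl_model")
  } else stop2("unknown serialized model type: ", x$type)
}

#' Save a model ensemble as self-describing JSON
#'
#' Writes every run (model coefficients or posteriors, split indices,
#' standardization statistics, hyperparameters) plus the ensemble metadata
#' and seeds at full double precision, so the round-trip is bit-identical
#' for integers and well within 1e-12 for reals.
#'
#' @param ensemble a `model_ensemble` from [run_randomized_cv()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
save_model <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  runs <- lapply(ensemble$runs, function(r) {
    sx <- if (inherits(r$standardizer_x, "standardizer"))
      ser_standardizer(r$standardizer_x) else
        lapply(r$standardizer_x, ser_standardizer)
    list(model = ser_model(r$model), train_idx = r$train_idx,
         test_idx = r$test_idx, standardizer_x = sx,
         standardizer_x_per_view = !inherits(r$standardizer_x, "standardizer"),
         standardizer_y = ser_standardizer(r$standardizer_y),
         hyperparameters = r$hyperparameters,
         test_spearman = unname(r$test_spearman))
  })
  obj <- list(format = MODEL_FORMAT, version = MODEL_VERSION,
              learner = ensemble$learner, n_runs = ensemble$n_runs,
              test_frac = ensemble$test_frac, seed = ensemble$seed,
              view_names = ensemble$view_names,
              feature_names = ensemble$feature_names,
              task_names = ensemble$task_names,
              sample_ids = ensemble$sample_ids,
              view_features = ensemble$view_features,
              view_provenance = ensemble$view_provenance,
              train_views = lapply(ensemble$train_views, ser_matrix),
              runs = runs)
  json <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a model ensemble saved by [save_model()]
#'
#' @param path JSON file written by [save_model()].
#' @return The reconstructed `model_ensemble`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, MODEL_FORMAT))
    stop2("not a tmemark model file: ", path)
  if (!identical(obj$version, MODEL_VERSION))
    stop2("model file version '", obj$version,
          "' does not match supported version '", MODEL_VERSION, "'")
  runs <- lapply(obj$runs, function(r) {
    if (is.null(r$standardizer_y))
      stop2("model file lacks standardization statistics for a run")
    sx <- if (isTRUE(r$standardizer_x_per_view))
      lapply(r$standardizer_x, deser_standardizer) else
        deser_standardizer(r$standardizer_x)
    list(model = deser_model(r$model),
         train_idx = unlist(r$train_idx), test_idx = unlist(r$test_idx),
         standardizer_x = sx,
         standardizer_y = deser_standardizer(r$standardizer_y),
         hyperparameters = r$hyperparameters,
         test_spearman = unlist(r$test_spearman))
  })
  structure(list(runs = runs, learner = obj$learner, n_runs = obj$n_runs,
                 test_frac = obj$test_frac, seed = obj$seed,
                 view_names = unlist(obj$view_names),
                 feature_names = unlist(obj$feature_names),
                 task_names = unlist(obj$task_names),
                 sample_ids = unlist(obj$sample_ids),
                 view_features = lapply(obj$view_features, unlist),
                 view_provenance = obj$view_provenance,
                 train_views = lapply(obj$train_views, deser_matrix)),
            class = "model_ensemble")
}
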