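## Cohort prediction, responder evaluation, and TMB integration.

predict_ensemble_matrix <- function(ensemble, X_new) {
  X_new <- as.matrix(X_new)
  q <- length(ensemble$task_names)
  acc <- matrix(0, nrow(X_new), q,
                dimnames = list(rownames(X_new), ensemble$task_names))
  if (ensemble$learner == "rmtlr") {
    missing <- setdiff(ensemble$feature_names, colnames(X_new))
    if (length(missing))
      stop2("new cohort lacks trained features: ",
            paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ..." else "")
    X_new <- X_new[, ensemble$feature_names, drop = FALSE]
    for (run in ensemble$runs) {
      Xs <- apply_standardizer(run$standardizer_x, X_new)
      acc <- acc + rmtlr_predict(run$model, Xs)
    }
  } else {
    if (length(ensemble$view_names) != 1L)
      stop2("matrix-level BEMKL prediction expects a single-view ensemble")
    mat <- ensemble$train_views[[1L]]
    for (run in ensemble$runs) {
      s <- run$standardizer_x[[1L]]
      Xtr <- apply_standardizer(s, mat[run$train_idx, , drop = FALSE])
      Xte <- apply_standardizer(s, X_new)
      Kte <- gaussian_kernel(Xte, Xtr, run$hyperparameters$sigma[[1L]])
      acc <- acc + bemkl_predict(run$model, list(Kte))
    }
  }
  acc / ensemble$n_runs
}

derive_view_for_prediction <- function(ensemble, view_name, expr_new, priors,
                                       tpm_threshold = 10,
                                       exclude_genes = NULL) {
  prov <- ensemble$view_provenance[[view_name]] %||% list()
  if (view_name == "cellfrac")
    return(deconvolve_cell_fractions(expr_new, priors$cell_signature))
  if (view_name == "pathways")
    return(compute_pathway_activity(expr_new, priors$pathway_model,
                                    exclude_genes))
  if (view_name == "tfs")
    return(compute_tf_activity(expr_new, priors$regulons))
  db <- derive_tme_lr_pairs(priors$lr_database, tpm_threshold)
  if (view_name == "lrpairs") {
    v <- compute_lr_view(expr_new, db)
    want <- ensemble$view_features[[view_name]]
    groups <- prov$groups
    if (!is.null(groups)) { # map new cohort onto the trained (grouped) features
      vals <- vapply(want, function(f) {
        ids <- intersect(unlist(groups[[f]]) %||% f, colnames(v$values))
        if (!length(ids)) stop2("trained LR feature not derivable: ", f)
        v$values[, ids[[1L]]]
      }, numeric(nrow(v$values)))
      return(view_matrix(matrix(vals, nrow = nrow(v$values),
                                dimnames = list(rownames(v$values), want)),
                         "lrpairs", provenance = prov))
    }
    return(v)
  }
  if (view_name == "ccpairs") {
    freqs <- prov$frequencies
    if (is.null(freqs))
      stop2("no stored LR frequencies for the CC view; recompute them on ",
            "a reference cohort with lr_pair_frequencies()")
    return(compute_cc_view(expr_new, db,
                           reference_frequencies = unlist(freqs),
                           tpm_threshold = prov$tpm_threshold %||% tpm_threshold))
  }
  stop2("cannot derive view '", view_name, "' for prediction")
}

#' Predict immune response for a new cohort
#'
#' For each single-view ensemble, derives the view from the new cohort's
#' expression (reusing the stored LR frequencies and feature grouping),
#' averages the predictions of the ensemble's runs per task, and averages
#' across tasks to one score per view. The final ensemble score of a
#' patient is the arithmetic mean of the single-view scores.
#'
#' @param ensembles a `model_ensemble` or named list of single-view
#'   `model_ensemble`s.
#' @param expr_new a [gene_expr()] for the new cohort, or a named list of
#'   precomputed `view_matrix` objects.
#' @param priors the [prior_bundle()] used at training time (required when
#'   `expr_new` is an expression matrix).
#' @param tpm_threshold,exclude_genes view-derivation settings.
#' @return An object of class `prediction_result` with per-view per-task
#'   scores, per-view task-averaged scores, and the ensemble score.
#' @export
predict_cohort <- function(ensembles, expr_new, priors = NULL,
                           tpm_threshold = 10, exclude_genes = NULL) {
  if (inherits(ensembles, "model_ensemble")) ensembles <- list(ensembles)
  if (is.null(names(ensembles)))
    names(ensembles) <- vapply(ensembles, function(e)
      paste(e$view_names, collapse = "+"), character(1L))
  per_view_task <- list()
  for (nm in names(ensembles)) {
    ens <- ensembles[[nm]]
    if (inherits(expr_new, "gene_expr")) {
      if (is.null(priors)) stop2("priors are required to derive views")
      vm <- lapply(ens$view_names, function(v)
        derive_view_for_prediction(ens, v, expr_new, priors,
                                   tpm_threshold, exclude_genes))
      names(vm) <- ens$view_names
      X_new <- merge_views(vm)
    } else {
      X_new <- merge_views(expr_new[ens$view_names])
    }
    per_view_task[[nm]] <- predict_ensemble_matrix(ens, X_new)
  }
  per_view_score <- vapply(per_view_task, rowMeans,
                           numeric(nrow(per_view_task[[1L]])))
  if (is.null(dim(per_view_score)))
    per_view_score <- matrix(per_view_score, nrow = 1L,
                             dimnames = list(rownames(per_view_task[[1L]]),
                                             names(per_view_task)))
  task_names <- colnames(per_view_task[[1L]])
  ensemble_task <- Reduce(`+`, per_view_task) / length(per_view_task)
  structure(list(per_view_task = per_view_task,
                 per_view_score = per_view_score,
                 ensemble_task = ensemble_task,
                 ensemble_score = rowMeans(per_view_score),
                 views = names(ensembles), task_names = task_names),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %d samples, views: %s, %d tasks\n",
              length(x$ensemble_score), paste(x$views, collapse = ", "),
              length(x$task_names)))
  invisible(x)
}

as_binary_labels <- function(labels, positive = "R") {
  if (is.data.frame(labels)) labels <- stats::setNames(labels$label, labels$sample_id)
  u <- unique(labels)
  if (length(u) < 2L) stop2("labels contain a single class")
  if (length(u) > 2L) stop2("labels must be binary, got: ", paste(u, collapse = ", "))
  if (is.numeric(labels)) return(labels == max(labels))
  labels == positive
}

#' Area under the ROC curve (rank formulation)
#'
#' Mann-Whitney AUC with tie correction: average ranks of the scores are
#' used, so tied positive/negative pairs count one half.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (`"R"`/`"NR"`, logical, or 0/1); the
#'   `positive` class is scored as the one with higher expected scores.
#' @param positive positive-class label for character input.
#' @return Scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = "R") {
  pos <- as_binary_labels(labels, positive)
  if (length(scores) != length(pos)) stop2("scores and labels differ in length")
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return data.frame with columns `fpr` and `tpr`, threshold decreasing.
#' @export
roc_curve <- function(scores, labels, positive = "R") {
  pos <- as_binary_labels(labels, positive)
  ord <- order(scores, decreasing = TRUE)
  scr <- scores[ord]; p <- pos[ord]
  keep <- c(which(diff(scr) != 0), length(scr)) # threshold between distinct scores
  tpr <- cumsum(p)[keep] / sum(pos)
  fpr <- cumsum(!p)[keep] / sum(!pos)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Vertically averaged ROC curve
#'
#' Averages several ROC curves on a fixed false-positive-rate grid
#' (step-function interpolation), the construction behind a task-averaged
#' ROC display.
#'
#' @param curves list of data.frames from [roc_curve()].
#' @param grid FPR grid (default 101 points on `[0, 1]`).
#' @return data.frame with columns `fpr` and mean `tpr`.
#' @export
average_roc <- function(curves, grid = seq(0, 1, length.out = 101L)) {
  tprs <- vapply(curves, function(cv) {
    vapply(grid, function(f) max(0, cv$tpr[cv$fpr <= f]), numeric(1L))
  }, numeric(length(grid)))
  data.frame(fpr = grid, tpr = rowMeans(tprs))
}

#' Evaluate predictions against responder labels
#'
#' @param result a [predict_cohort()] result or a numeric score vector.
#' @param labels binary responder labels (data.frame from
#'   [map_response_labels()], or a vector aligned with the scores).
#' @param positive positive-class label.
#' @return List with per-task AUCs (mean and SD across tasks), per-view
#'   AUCs, the ensemble AUC, and the task-averaged ROC curve.
#' @export
evaluate_predictions <- function(result, labels, positive = "R") {
  if (is.numeric(result))
    return(list(ensemble_auc = roc_auc(result, labels, positive)))
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$label, labels$sample_id)[
      names(result$ensemble_score)]
  task_auc <- apply(result$ensemble_task, 2L, roc_auc, labels = labels,
                    positive = positive)
  view_auc <- apply(result$per_view_score, 2L, roc_auc, labels = labels,
                    positive = positive)
  curves <- lapply(seq_along(task_auc), function(t)
    roc_curve(result$ensemble_task[, t], labels, positive))
  list(task_auc = task_auc,
       task_auc_mean = mean(task_auc), task_auc_sd = stats::sd(task_auc),
       view_auc = view_auc,
       ensemble_auc = roc_auc(result$ensemble_score, labels, positive),
       mean_roc = average_roc(curves))
}

effect_size_r <- function(z, n) z / sqrt(n)

rank_sum_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n1 + n2 + 1) -
                            sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sig2 <= 0) return(0)
  (W - mu) / sqrt(sig2)
}

signed_rank_z <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(0)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sig2 <= 0) return(0)
  (V - mu) / sqrt(sig2)
}

#' Compare two groups with Wilcoxon tests and an effect size
#'
#' Unpaired data: two-sided (by default) Wilcoxon rank-sum test. Paired
#' data: Wilcoxon signed-rank test, one-sided by default. P-values are
#' exact for 25 or fewer observations (without ties), otherwise normal
#' approximation with continuity correction. The effect size is
#' r = Z / sqrt(n observations), with Z from the tie-corrected normal
#' approximation of the test statistic.
#'
#' @param values numeric observations (unpaired) or first member of each
#'   pair (paired).
#' @param groups two-level factor for unpaired data; for paired data the
#'   second member of each pair.
#' @param paired treat `values`/`groups` as paired measurements.
#' @param alternative test direction (defaults: two-sided unpaired,
#'   `"greater"` paired).
#' @return List with `p_value`, `effect_size`, `z`, `method`.
#' @export
compare_groups <- function(values, groups, paired = FALSE,
                           alternative = NULL) {
  if (paired) {
    alternative <- alternative %||% "greater"
    x <- values; y <- groups
    if (length(x) != length(y) || length(x) < 2L)
      stop2("paired comparison needs >= 2 pairs")
    if (all(x == y)) {
      warn2("all pairs tied; p = 1, effect size 0")
      return(list(p_value = 1, effect_size = 0, z = 0,
                  method = "wilcoxon_signed_rank"))
    }
    n <- length(x)
    p <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                             alternative = alternative,
                                             exact = n <= 25,
                                             correct = TRUE)$p.value)
    z <- signed_rank_z(x - y)
    return(list(p_value = p, effect_size = abs(effect_size_r(z, n)), z = z,
                method = "wilcoxon_signed_rank"))
  }
  alternative <- alternative %||% "two.sided"
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop2("groups must have exactly 2 levels")
  x <- values[g == levels(g)[1L]]
  y <- values[g == levels(g)[2L]]
  if (length(x) < 2L || length(y) < 2L)
    stop2("need >= 2 observations per group")
  if (length(unique(values)) == 1L) {
    warn2("all observations tied; p = 1, effect size 0")
    return(list(p_value = 1, effect_size = 0, z = 0,
                method = "wilcoxon_rank_sum"))
  }
  n <- length(values)
  p <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                           exact = n <= 25,
                                           correct = TRUE)$p.value)
  z <- rank_sum_z(x, y)
  list(p_value = p, effect_size = abs(effect_size_r(z, n)), z = z,
       method = "wilcoxon_rank_sum")
}

#' Classify tumor mutational burden into tertiles
#'
#' Values are split into thirds (lowest third `L`, middle `M`, upper `H`),
#' ties broken by stable sample order. Pre-supplied classes pass through
#' unchanged.
#'
#' @param tmb numeric TMB values (>= 3 of them) or a character vector of
#'   classes `L`/`M`/`H`.
#' @return Character vector of classes aligned with the input.
#' @export
tmb_classify <- function(tmb) {
  if (is.character(tmb) || is.factor(tmb)) {
    tmb <- as.character(tmb)
    if (!all(tmb %in% c("L", "M", "H")))
      stop2("TMB classes must be L, M, or H")
    return(tmb)
  }
  if (any(tmb < 0)) stop2("TMB values must be >= 0")
  n <- length(tmb)
  if (n < 3L) stop2("tertile classification needs >= 3 values")
  if (length(unique(tmb)) == 1L)
    warn2("all TMB values equal; tertiles assigned by stable sample order")
  sizes <- diff(round(seq(0, n, length.out = 4L)))
  cls_sorted <- rep(c("L", "M", "H"), times = sizes)
  out <- character(n)
  out[order(tmb)] <- cls_sorted # order() is stable: ties keep input order
  out
}

#' Penalty-based TMB integration
#'
#' `P = P_model + c * gamma` with `c = -1` for class `L`, `0` for `M`,
#' `+1` for `H`: low-TMB patients are penalized and high-TMB patients
#' boosted by a fixed amount.
#'
#' @param p_model per-patient prediction scores.
#' @param tmb_class classes from [tmb_classify()].
#' @param gamma penalty magnitude (>= 0).
#' @return Adjusted scores.
#' @export
integrate_tmb_penalty <- function(p_model, tmb_class, gamma) {
  if (gamma < 0) stop2("gamma must be >= 0")
  tmb_class <- tmb_classify(tmb_class)
  cc <- c(L = -1, M = 0, H = 1)[tmb_class]
  unname(p_model + cc * gamma)
}

#' Weighted-average TMB integration
#'
#' Min-max scales the model predictions to `[0, 1]` within the cohort,
#' maps TMB classes to `L = 0`, `M = 0.5`, `H = 1`, and returns
#' `(1 - eta) * P_scaled + eta * TMB`.
#'
#' @inheritParams integrate_tmb_penalty
#' @param eta TMB weight in `[0, 1]`.
#' @return Blended scores in `[0, 1]`.
#' @export
integrate_tmb_weighted <- function(p_model, tmb_class, eta) {
  if (eta < 0 || eta > 1) stop2("eta must be in [0, 1]")
  tmb_class <- tmb_classify(tmb_class)
  rng <- range(p_model)
  if (diff(rng) == 0) {
    warn2("constant predictions; scaled to 0.5 everywhere")
    p_scaled <- rep(0.5, length(p_model))
  } else {
    p_scaled <- (p_model - rng[1L]) / diff(rng)
  }
  tmb_val <- c(L = 0, M = 0.5, H = 1)[tmb_class]
  unname((1 - eta) * p_scaled + eta * tmb_val)
}

#' Map clinical response annotations to responder labels
#'
#' Default RECIST convention: complete and partial response are
#' responders, stable and progressive disease non-responders; the mapping
#' is configurable per dataset.
#'
#' @param clinical data.frame with sample ids and a response column.
#' @param column name of the annotation column (default `"response"`).
#' @param id_column name of the sample-id column (default `"sample_id"`).
#' @param mapping named character vector annotation -> `"R"`/`"NR"`.
#' @return data.frame of class `response_labels` with columns `sample_id`,
#'   `label`, `source`.
#' @export
map_response_labels <- function(clinical, column = "response",
                                id_column = "sample_id",
                                mapping = c(CR = "R", PR = "R",
                                            SD = "NR", PD = "NR")) {
  if (!column %in% names(clinical))
    stop2("annotation column '", column, "' not found")
  ann <- as.character(clinical[[column]])
  unmapped <- setdiff(unique(ann), names(mapping))
  if (length(unmapped))
    stop2("unmapped response annotation(s): ", paste(unmapped, collapse = ", "))
  out <- data.frame(sample_id = as.character(clinical[[id_column]]),
                    label = unname(mapping[ann]), source = ann,
                    stringsAsFactors = FALSE)
  class(out) <- c("response_labels", "data.frame")
  out
}
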