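## Unified pipeline entry point tying the modules into the two workflows:
## train on a reference cohort, predict on a new cohort.

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop2("config file not found: ", config)
    cfg <- yaml::read_yaml(config)
    cfg$.base_dir <- dirname(config)
  } else {
    cfg <- config
    cfg$.base_dir <- cfg$.base_dir %||% "."
  }
  cfg
}

resolve_path <- function(cfg, p) {
  if (is.null(p)) return(NULL)
  if (file.exists(p)) p else file.path(cfg$.base_dir, p)
}

provenance_sidecar <- function(cfg, path, extra = list()) {
  keep <- cfg[setdiff(names(cfg), ".base_dir")]
  prov <- c(list(config_hash = fnv1a_hash(jsonlite::toJSON(keep, auto_unbox = TRUE)),
                 seed = cfg$seed %||% 1L,
                 package_version = as.character(utils::packageVersion("tmemark")),
                 timestamped = FALSE), # deterministic outputs: no wall clock
            extra)
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA, null = "null")
}

pipeline_simulate <- function(cfg, out_dir) {
  seed <- cfg$seed %||% 1L
  priors <- make_priors(n_genes = cfg$n_genes %||% 2000L,
                        n_celltypes = cfg$n_celltypes %||% 10L,
                        n_pathways = cfg$n_pathways %||% 14L,
                        n_tfs = cfg$n_tfs %||% 30L,
                        n_lr_pairs = cfg$n_lr_pairs %||% 40L,
                        seed = seed)
  cohort <- make_cohort(priors, n_samples = cfg$n_samples %||% 300L,
                        noise_sd = cfg$noise_sd %||% 0.1,
                        seed = derive_seed(seed, 1L))
  labels <- make_icb_labels(cohort$truth,
                            effect_size = cfg$effect_size %||% 2,
                            prevalence = cfg$prevalence %||% 0.35,
                            seed = derive_seed(seed, 2L))
  write_priors(priors, file.path(out_dir, "priors"))
  write_expression(cohort$expr, file.path(out_dir, "expression.tsv"))
  utils::write.table(labels, file.path(out_dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(fractions = ser_matrix(truth$fractions),
         latent_immune = as.list(truth$latent_immune),
         params = truth$params),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  list(files = c("priors/priors.yaml", "expression.tsv", "labels.tsv",
                 "truth.json"))
}

pipeline_views <- function(cfg, out_dir) {
  expr <- load_expression(resolve_path(cfg, cfg$expr))
  priors <- load_priors(resolve_path(cfg, cfg$priors))
  which <- cfg$view %||% "all"
  if (identical(which, "all"))
    which <- c("cellfrac", "pathways", "tfs", "lrpairs", "ccpairs")
  views <- compute_views(expr, priors, which = which,
                         tpm_threshold = cfg$tpm_threshold %||% 10)
  for (nm in names(views)) {
    write_tsv(views[[nm]]$values, file.path(out_dir, paste0(nm, ".tsv")),
              row_label = "sample")
    jsonlite::write_json(
      c(list(view = nm, dropped = views[[nm]]$dropped),
        views[[nm]]$provenance),
      file.path(out_dir, paste0(nm, ".provenance.json")),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(files = paste0(names(views), ".tsv"))
}

pipeline_scores <- function(cfg, out_dir) {
  expr <- load_expression(resolve_path(cfg, cfg$expr))
  priors <- load_priors(resolve_path(cfg, cfg$priors))
  tasks <- compute_task_matrix(expr, priors$score_definitions)
  write_tsv(tasks$values, file.path(out_dir, "tasks.tsv"), row_label = "sample")
  list(files = "tasks.tsv")
}

load_view_dir <- function(cfg, view_names) {
  dir <- resolve_path(cfg, cfg$views_dir)
  out <- list()
  for (nm in view_names) {
    vals <- as.matrix(read_table_auto(file.path(dir, paste0(nm, ".tsv")),
                                      row_names = 1L))
    prov_path <- file.path(dir, paste0(nm, ".provenance.json"))
    prov <- if (file.exists(prov_path))
      jsonlite::fromJSON(prov_path, simplifyVector = FALSE) else list()
    out[[nm]] <- view_matrix(vals, if (nm %in% c("cellfrac", "pathways", "tfs",
                                                 "lrpairs", "ccpairs")) nm
                             else "external",
                             provenance = prov)
  }
  out
}

pipeline_train <- function(cfg, out_dir) {
  view_names <- unlist(cfg$train_views) %||% c("cellfrac", "pathways")
  views <- load_view_dir(cfg, view_names)
  tasks <- as.matrix(read_table_auto(resolve_path(cfg, cfg$tasks),
                                     row_names = 1L))
  ens <- run_randomized_cv(views, tasks,
                           learner = cfg$learner %||% "rmtlr",
                           n_runs = cfg$n_runs %||% 100L,
                           test_frac = cfg$test_frac %||% 0.2,
                           seed = cfg$seed %||% 1L,
                           alpha_grid = unlist(cfg$alpha_grid) %||% 0.5,
                           n_lambda = cfg$n_lambda %||% 10L)
  save_model(ens, file.path(out_dir, "model.json"))
  perf <- ensemble_performance(ens)
  utils::write.table(data.frame(task = names(perf), mean_test_spearman = perf),
                     file.path(out_dir, "performance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(files = c("model.json", "performance.tsv"))
}

pipeline_biomarkers <- function(cfg, out_dir) {
  ens <- load_model(resolve_path(cfg, cfg$model))
  bm <- extract_biomarkers(ens, p_threshold = cfg$p_threshold %||% 0.05)
  utils::write.table(bm, file.path(out_dir, "biomarkers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(files = "biomarkers.tsv")
}

pipeline_predict <- function(cfg, out_dir) {
  ens <- load_model(resolve_path(cfg, cfg$model))
  expr <- load_expression(resolve_path(cfg, cfg$expr))
  priors <- load_priors(resolve_path(cfg, cfg$priors))
  pred <- predict_cohort(ens, expr, priors,
                         tpm_threshold = cfg$tpm_threshold %||% 10)
  out <- cbind(ensemble_score = pred$ensemble_score, pred$ensemble_task)
  write_tsv(out, file.path(out_dir, "predictions.tsv"), row_label = "sample")
  files <- "predictions.tsv"
  if (!is.null(cfg$labels)) {
    lab <- read_table_auto(resolve_path(cfg, cfg$labels))
    labels <- stats::setNames(lab$label, lab$sample_id)[
      names(pred$ensemble_score)]
    if (!is.null(cfg$tmb)) {
      tmb <- read_table_auto(resolve_path(cfg, cfg$tmb))
      cls <- tmb_classify(stats::setNames(tmb$tmb, tmb$sample_id)[
        names(pred$ensemble_score)])
      blended <- integrate_tmb_weighted(pred$ensemble_score, cls,
                                        eta = cfg$eta %||% 0.5)
      ev <- list(ensemble_auc = roc_auc(pred$ensemble_score, labels),
                 tmb_blended_auc = roc_auc(blended, labels))
    } else {
      ev <- evaluate_predictions(pred, labels)
      ev$mean_roc <- NULL
    }
    jsonlite::write_json(ev, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "evaluation.json")
  }
  list(files = files)
}

#' Run one pipeline command
#'
#' Commands: `simulate` (synthetic priors + cohort + labels), `views`
#' (derive TME views), `scores` (task matrix), `train` (randomized-CV
#' ensemble), `biomarkers`, `predict`. Outputs are deterministic given the
#' config and seed; every run writes a provenance JSON (config hash, seed,
#' package version) and partial outputs are removed on failure.
#'
#' @param config path to a YAML config or an equivalent named list.
#' @param command one of `"simulate"`, `"views"`, `"scores"`, `"train"`,
#'   `"biomarkers"`, `"predict"`.
#' @param out_dir output directory (created; taken from the config's
#'   `out` entry when missing).
#' @return Invisibly, the list of files written.
#' @export
run_pipeline <- function(config, command, out_dir = NULL) {
  commands <- c(simulate = pipeline_simulate, views = pipeline_views,
                scores = pipeline_scores, train = pipeline_train,
                biomarkers = pipeline_biomarkers, predict = pipeline_predict)
  if (length(command) != 1L || !command %in% names(commands))
    stop2("unknown command '", paste(command, collapse = " "),
          "'; use one of: ", paste(names(commands), collapse = ", "))
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg$out %||% stop2("no output directory configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- tryCatch(commands[[command]](cfg, out_dir), error = function(e) {
    e
  })
  if (inherits(res, "error")) {
    for (f in list.files(out_dir, full.names = TRUE)) unlink(f, recursive = TRUE)
    stop2("pipeline command '", command, "' failed: ", conditionMessage(res))
  }
  provenance_sidecar(cfg, file.path(out_dir, paste0(command, ".provenance.json")),
                     extra = list(command = command, files = res$files))
  invisible(res$files)
}
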