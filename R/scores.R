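#' Samples x tasks matrix of immune-response proxy scores
#'
#' @param values numeric matrix, samples x tasks, no missing values,
#'   unique task names.
#' @return An object of class `task_matrix`.
#' @export
task_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop2("task matrix needs sample rownames and task colnames")
  if (anyDuplicated(colnames(values))) stop2("duplicate task names")
  if (any(!is.finite(values))) stop2("task matrix must not contain missing values")
  structure(list(values = values), class = "task_matrix")
}

#' @export
print.task_matrix <- function(x, ...) {
  cat(sprintf("<task_matrix> %d samples x %d tasks\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
as.matrix.task_matrix <- function(x, ...) x$values

transform_expr <- function(expr, transform) {
  switch(transform,
         tpm = expr$tpm,
         log2_tpm1p = log2(expr$tpm + 1),
         identity = expr$tpm,
         stop2("unknown expression transform: ", transform))
}

present_genes <- function(expr, genes, what) {
  present <- intersect(genes, rownames(expr$tpm))
  if (length(present) == 0L)
    stop2(what, ": none of the genes are present in the expression matrix")
  if (length(present) < length(genes))
    message(sprintf("%s: %d of %d genes absent, ignored",
                    what, length(genes) - length(present), length(genes)))
  present
}

#' Geometric-mean score
#'
#' Geometric mean of (TPM + pseudocount) over the present genes; with
#' GZMA and PRF1 this is the classical cytolytic-activity (CYT) score.
#'
#' @param expr a [gene_expr()].
#' @param genes gene symbols.
#' @param pseudocount added before taking logs (default 0.01).
#' @return Named numeric vector, one score per sample.
#' @export
score_geometric_mean <- function(expr, genes, pseudocount = 0.01) {
  g <- present_genes(expr, genes, "geometric_mean")
  exp(colMeans(log(expr$tpm[g, , drop = FALSE] + pseudocount)))
}

#' (Rank-normalized) weighted-mean score
#'
#' Transforms expression (default log2(TPM+1)), optionally rank-normalizes
#' each gene across samples to `[0, 1]` (average ranks, mapped by
#' (rank - 1)/(n - 1)), and returns the weighted mean
#' sum(w_g x_g) / sum(w_g) per sample.
#'
#' @param expr a [gene_expr()].
#' @param genes gene symbols.
#' @param weights optional weights matched to `genes` (default all 1).
#' @param transform `"log2_tpm1p"` (default), `"tpm"` or `"identity"`.
#' @param rank_normalize rank-normalize genes across samples first.
#' @return Named numeric vector, one score per sample.
#' @export
score_weighted_mean <- function(expr, genes, weights = NULL,
                                transform = "log2_tpm1p",
                                rank_normalize = FALSE) {
  g <- present_genes(expr, genes, "weighted_mean")
  w <- if (is.null(weights)) rep(1, length(g)) else
    weights[match(g, genes)]
  E <- transform_expr(expr, transform)[g, , drop = FALSE]
  if (rank_normalize) {
    n <- ncol(E)
    E <- t(apply(E, 1L, function(x)
      if (n == 1L) 0.5 else (rank(x, ties.method = "average") - 1) / (n - 1)))
    if (length(g) == 1L) E <- matrix(E, nrow = 1L,
                                     dimnames = list(g, colnames(expr$tpm)))
  }
  drop(crossprod(E, w) / sum(w))[colnames(expr$tpm)]
}

#' Gene-pair logic score
#'
#' Counts, per sample, the gene pairs (g1, g2) for which expression of g1
#' strictly exceeds that of g2 (the IMPRES / MSI-status construction).
#' Pairs with either gene absent are skipped with a warning. The score is
#' invariant to any strictly monotone per-sample transform.
#'
#' @param expr a [gene_expr()].
#' @param gene_pairs data.frame with columns `g1` and `g2`.
#' @return Named integer vector, one count per sample.
#' @export
score_pair_logic <- function(expr, gene_pairs) {
  stopifnot(all(c("g1", "g2") %in% names(gene_pairs)))
  ok <- gene_pairs$g1 %in% rownames(expr$tpm) &
    gene_pairs$g2 %in% rownames(expr$tpm)
  if (!any(ok)) stop2("pair_logic: no evaluable gene pairs")
  if (any(!ok))
    warn2("pair_logic: skipped ", sum(!ok), " pair(s) with absent genes")
  gp <- gene_pairs[ok, , drop = FALSE]
  hits <- expr$tpm[gp$g1, , drop = FALSE] > expr$tpm[gp$g2, , drop = FALSE]
  colSums(hits)
}

#' First-principal-component score with sign anchoring
#'
#' Scores samples by the first principal component of the (gene-centered)
#' expression submatrix. Because a PC's sign is arbitrary, the sign is
#' flipped when the Pearson correlation with the mean of the supplied
#' anchor scores is negative; a zero correlation keeps the computed sign
#' with a warning.
#'
#' @param expr a [gene_expr()].
#' @param genes gene symbols (>= 2 present).
#' @param anchor_scores optional numeric matrix/vector of anchor task
#'   scores (samples in rows).
#' @param transform expression transform before the PCA.
#' @return Named numeric vector, one score per sample.
#' @export
score_pc1 <- function(expr, genes, anchor_scores = NULL,
                      transform = "log2_tpm1p") {
  g <- present_genes(expr, genes, "pc1")
  if (length(g) < 2L) stop2("pc1 needs at least 2 present genes")
  E <- transform_expr(expr, transform)[g, , drop = FALSE]
  if (ncol(E) < 3L) stop2("pc1 needs at least 3 samples")
  X <- sweep(t(E), 2L, rowMeans(E)) # samples x genes, gene-centered
  if (all(abs(X) < .Machine$double.eps))
    stop2("pc1: zero-variance expression submatrix")
  sv <- svd(X, nu = 1L, nv = 0L)
  score <- drop(sv$u[, 1L] * sv$d[1L])
  names(score) <- colnames(E)
  if (!is.null(anchor_scores)) {
    anchor <- rowMeans(as.matrix(anchor_scores))
    if (!is.null(names(anchor))) anchor <- anchor[names(score)]
    r <- suppressWarnings(stats::cor(score, anchor))
    if (is.na(r) || r == 0) {
      warn2("pc1: anchor correlation undefined or zero; sign kept as computed")
    } else if (r < 0) {
      score <- -score
    }
  }
  score
}

#' Evaluate a list of score definitions into a task matrix
#'
#' Dispatches each [score_definition()] by its form. `pc1` definitions are
#' evaluated last so their `sign_anchor` can reference already-computed
#' tasks. Definitions whose genes are entirely absent are dropped with a
#' warning. Columns are returned unstandardized; standardization happens
#' inside model training.
#'
#' @param expr a [gene_expr()].
#' @param score_definitions list of [score_definition()] objects.
#' @return A [task_matrix()].
#' @export
compute_task_matrix <- function(expr, score_definitions) {
  if (length(score_definitions) == 0L) stop2("empty score definition list")
  nm <- vapply(score_definitions, function(d) d$name, character(1L))
  if (anyDuplicated(nm)) stop2("duplicate score definition names")
  ord <- order(vapply(score_definitions, function(d) d$form == "pc1", logical(1L)))
  defs <- score_definitions[ord]
  cols <- list()
  for (d in defs) {
    val <- tryCatch(switch(d$form,
      geometric_mean = score_geometric_mean(expr, d$genes, d$pseudocount),
      weighted_mean = score_weighted_mean(expr, d$genes, d$weights, d$transform),
      rank_normalized_mean = score_weighted_mean(expr, d$genes, d$weights,
                                                 d$transform,
                                                 rank_normalize = TRUE),
      pair_logic = score_pair_logic(expr, d$gene_pairs),
      pc1 = {
        anchors <- intersect(d$sign_anchor %||% character(), names(cols))
        anchor_m <- if (length(anchors)) do.call(cbind, cols[anchors])
        score_pc1(expr, d$genes, anchor_scores = anchor_m, transform = d$transform)
      }),
      error = function(e) {
        warn2("score '", d$name, "' dropped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(val)) cols[[d$name]] <- val
  }
  if (length(cols) == 0L) stop2("no computable score definitions")
  task_matrix(do.call(cbind, cols)[, nm[nm %in% names(cols)], drop = FALSE])
}

#' Select the mutually correlated task subset
#'
#' For each cohort, computes each task's median Pearson correlation with
#' all other tasks; across cohorts, takes the median of these medians and
#' keeps tasks whose value exceeds the threshold. Constant task columns
#' have undefined correlations, which are treated as 0 with a warning.
#'
#' @param tasks a [task_matrix()] or a list of them (one per cohort).
#' @param threshold keep tasks with median-of-medians correlation strictly
#'   above this value (default 0.4).
#' @return Character vector of selected task names; the full score table
#'   is attached as attribute `"medians"`.
#' @export
select_tasks <- function(tasks, threshold = 0.4) {
  if (inherits(tasks, "task_matrix")) tasks <- list(tasks)
  task_names <- colnames(tasks[[1L]]$values)
  if (length(task_names) < 3L) stop2("task selection needs at least 3 tasks")
  per_cohort <- sapply(tasks, function(tm) {
    V <- tm$values[, task_names, drop = FALSE]
    const <- col_pop_sd(V) == 0
    if (any(const))
      warn2("constant task column(s), correlations treated as 0: ",
            paste(task_names[const], collapse = ", "))
    C <- suppressWarnings(stats::cor(V))
    C[!is.finite(C)] <- 0
    diag(C) <- NA
    apply(C, 2L, stats::median, na.rm = TRUE)
  })
  per_cohort <- matrix(per_cohort, nrow = length(task_names),
                       dimnames = list(task_names, NULL))
  med <- apply(per_cohort, 1L, stats::median)
  structure(task_names[med > threshold], medians = med)
}
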