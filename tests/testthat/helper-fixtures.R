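## Shared fixtures and independent oracles for the test suite.

## tiny expression object from a genes x samples matrix (dimnames optional)
tiny_expr <- function(m, genes = NULL, samples = NULL) {
  m <- as.matrix(m)
  rownames(m) <- genes %||% rownames(m) %||% sprintf("G%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% colnames(m) %||% sprintf("S%02d", seq_len(ncol(m)))
  gene_expr(m)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## toy LR database: three pairs (one a two-gene ligand complex) across two
## aggregated TME types plus a pan-cancer type
toy_lr_db <- function() {
  genes <- c("L1", "R1", "L2", "R2", "L3A", "L3B", "R3")
  ctx <- matrix(0, 5, length(genes),
                dimnames = list(c("Tc_1", "Tc_2", "Fib_1", "Fib_2", "Pancancer"),
                                genes))
  ctx["Tc_1", c("L1", "L2")] <- 50
  ctx["Fib_1", c("R1", "R2")] <- 50
  ctx["Tc_2", c("L3A", "L3B")] <- 50
  ctx["Tc_2", "R3"] <- 50 # autocrine for the complex pair
  pairs <- data.frame(pair_id = c("P1", "P2", "P3"),
                      ligand_genes = c("L1", "L2", "L3A;L3B"),
                      receptor_genes = c("R1", "R2", "R3"),
                      stringsAsFactors = FALSE)
  lr_database(pairs, ctx,
              aggregation_map = c(Tc_1 = "Tcell", Tc_2 = "Tcell",
                                  Fib_1 = "Fibroblast", Fib_2 = "Fibroblast",
                                  Pancancer = "Pancancer"),
              aggregated_types = c("Tcell", "Fibroblast", "Pancancer"))
}

## independent proximal-gradient minimizer of the printed RMTLR objective
prox_grad_rmtlr <- function(X, Y, lambda, alpha, n_iter = 20000L) {
  N <- nrow(X)
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  L <- 2 * svd(Xc, nu = 0, nv = 0)$d[1]^2 / N + 2 * lambda * alpha
  B <- matrix(0, ncol(X), ncol(Y))
  for (it in seq_len(n_iter)) {
    Gr <- -2 * crossprod(Xc, Yc - Xc %*% B) / N + 2 * lambda * alpha * B
    Bn <- B - Gr / L
    rn <- sqrt(rowSums(Bn^2))
    sc <- pmax(0, 1 - (lambda * (1 - alpha) / L) / pmax(rn, 1e-300))
    B <- Bn * sc
  }
  beta0 <- colMeans(Y) - drop(crossprod(B, colMeans(X)))
  list(beta = B, beta0 = beta0,
       objective = rmtlr_objective(X, Y, B, beta0, lambda, alpha))
}

## brute-force AUC: count positive/negative pairs, ties worth one half
auc_pair_counting <- function(scores, pos) {
  s_pos <- scores[pos]; s_neg <- scores[!pos]
  tot <- 0
  for (a in s_pos) for (b in s_neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(s_pos) * length(s_neg))
}

## construct a minimal rmtlr ensemble from a features x tasks x runs array
fake_rmtlr_ensemble <- function(W) {
  feats <- dimnames(W)[[1]]; tasks <- dimnames(W)[[2]]
  runs <- lapply(seq_len(dim(W)[3]), function(r)
    list(model = structure(list(beta = W[, , r, drop = TRUE]),
                           class = "rmtlr_model")))
  structure(list(runs = runs, learner = "rmtlr", n_runs = dim(W)[3],
                 feature_names = feats, task_names = tasks,
                 view_names = "external", sample_ids = character()),
            class = "model_ensemble")
}
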