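#' Samples x features view matrix
#'
#' Container for one of the five TME views (or an external feature matrix
#' such as proteomics). Features containing any missing value are dropped
#' at construction and recorded, mirroring the rule used for protein data.
#'
#' @param values numeric matrix, samples x features, with dimnames.
#' @param view_name one of `"cellfrac"`, `"pathways"`, `"tfs"`,
#'   `"lrpairs"`, `"ccpairs"`, `"external"`.
#' @param provenance free-form list recorded alongside the values
#'   (thresholds, frequencies, dropped features).
#' @return An object of class `view_matrix`.
#' @export
view_matrix <- function(values, view_name, provenance = list()) {
  valid <- c("cellfrac", "pathways", "tfs", "lrpairs", "ccpairs", "external")
  if (!view_name %in% valid) stop2("unknown view name: ", view_name)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || (ncol(values) > 0L && is.null(colnames(values))))
    stop2("view matrix needs sample rownames and feature colnames")
  if (anyDuplicated(colnames(values))) stop2("duplicate feature ids in view")
  has_na <- colSums(!is.finite(values)) > 0L
  dropped <- colnames(values)[has_na]
  if (length(dropped)) {
    message(sprintf("view '%s': dropped %d feature(s) with missing values",
                    view_name, length(dropped)))
    values <- values[, !has_na, drop = FALSE]
  }
  structure(list(view_name = view_name, values = values,
                 dropped = dropped, provenance = provenance),
            class = "view_matrix")
}

#' @export
print.view_matrix <- function(x, ...) {
  cat(sprintf("<view_matrix:%s> %d samples x %d features\n",
              x$view_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
as.matrix.view_matrix <- function(x, ...) x$values

#' @export
dim.view_matrix <- function(x) dim(x$values)

## Lawson-Hanson active-set non-negative least squares: min ||Ax - b||, x >= 0.
## The entering test uses a gradient-scale tolerance; feasibility checks on
## the coefficients themselves use a relative machine-precision guard, so
## genuinely tiny positive solutions are kept.
nnls_solve <- function(A, b) {
  p <- ncol(A)
  w_tol <- 10 * .Machine$double.eps * p * max(1, abs(crossprod(A, b)))
  x <- numeric(p)
  passive <- logical(p)
  w <- drop(crossprod(A, b))
  outer_it <- 0L
  while (any(!passive & w > w_tol) && outer_it < 50L * p) {
    outer_it <- outer_it + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    inner_it <- 0L
    repeat {
      inner_it <- inner_it + 1L
      idx <- which(passive)
      s <- numeric(p)
      coef <- drop(qr.coef(qr(A[, idx, drop = FALSE]), b))
      coef[is.na(coef)] <- 0
      s[idx] <- coef
      if (all(s[idx] > 0) || inner_it > p + 1L) { x <- s; break }
      neg <- idx[s[idx] <= 0]
      alpha <- min(x[neg] / pmax(x[neg] - s[neg], .Machine$double.xmin))
      x <- x + alpha * (s - x)
      zero_guard <- 1e-12 * max(x, 1e-300)
      passive <- passive & x > zero_guard
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  pmax(x, 0)
}

#' Estimate immune-cell fractions by deconvolution
#'
#' Solves, per sample, a non-negative least-squares mixture of the TPM
#' profile on the cell-type signature columns over the signature genes.
#' Fractions are rescaled only when their sum exceeds 1, `Other` is defined
#' as exactly 1 minus the total immune fraction, and the non-regulatory CD4
#' column is reported as CD4 + Treg (with Treg kept as its own column),
#' giving 11 features for the canonical cell-type list.
#'
#' @param expr a [gene_expr()].
#' @param signature genes x cell-types non-negative matrix (defaults to
#'   `priors$cell_signature` when a bundle is supplied).
#' @return A `view_matrix` with `view_name = "cellfrac"`.
#' @export
deconvolve_cell_fractions <- function(expr, signature) {
  if (inherits(signature, "prior_bundle")) signature <- signature$cell_signature
  signature <- as.matrix(signature)
  if (any(signature < 0)) stop2("cell signature must be non-negative")
  genes <- intersect(rownames(expr$tpm), rownames(signature))
  if (length(genes) == 0L) stop2("no overlap between expression and signature genes")
  A <- signature[genes, , drop = FALSE]
  Y <- expr$tpm[genes, , drop = FALSE]
  zero <- colSums(Y) == 0
  if (any(zero))
    stop2("all-zero expression over signature genes for sample(s): ",
          paste(colnames(Y)[zero], collapse = ", "))
  fr <- t(apply(Y, 2L, function(b) nnls_solve(A, b)))
  colnames(fr) <- colnames(signature)
  tot <- rowSums(fr)
  over <- tot > 1
  fr[over, ] <- fr[over, , drop = FALSE] / tot[over]
  other <- pmax(0, 1 - rowSums(fr))
  if (all(c("CD4", "Treg") %in% colnames(fr)))
    fr[, "CD4"] <- fr[, "CD4"] + fr[, "Treg"]
  out <- cbind(fr, Other = other)
  view_matrix(out, "cellfrac",
              provenance = list(n_signature_genes = length(genes)))
}

#' Pathway activity as weighted sums of z-scored expression
#'
#' Expression is put on the log2(TPM+1) scale, genes listed in
#' `exclude_genes` are removed from the pathway model (to avoid circularity
#' with genes used by the immune-response scores), each remaining model
#' gene is z-scored across samples (population SD; constant genes map to
#' 0), and each pathway score is the weight-weighted sum of gene z-scores.
#'
#' @param expr a [gene_expr()].
#' @param pathway_model genes x pathways weight matrix (or a
#'   [prior_bundle()]).
#' @param exclude_genes genes removed from the model before scoring.
#' @return A `view_matrix` with `view_name = "pathways"`.
#' @export
compute_pathway_activity <- function(expr, pathway_model, exclude_genes = NULL) {
  if (inherits(pathway_model, "prior_bundle"))
    pathway_model <- pathway_model$pathway_model
  W <- as.matrix(pathway_model)
  W <- W[!rownames(W) %in% exclude_genes, , drop = FALSE]
  genes <- intersect(rownames(W), rownames(expr$tpm))
  empty <- colnames(W)[colSums(W[genes, , drop = FALSE] != 0) == 0L]
  if (length(empty))
    warn2("pathway(s) with no surviving signature genes dropped: ",
          paste(empty, collapse = ", "))
  W <- W[genes, setdiff(colnames(W), empty), drop = FALSE]
  if (ncol(W) == 0L || length(genes) == 0L) {
    vals <- matrix(0, ncol(expr$tpm), 0,
                   dimnames = list(colnames(expr$tpm), character()))
    return(view_matrix(vals, "pathways",
                       provenance = list(dropped_pathways = empty)))
  }
  E <- log2(expr$tpm[genes, , drop = FALSE] + 1)
  mu <- rowMeans(E)
  sd <- sqrt(rowMeans((E - mu)^2))
  Z <- (E - mu) / ifelse(sd > 0, sd, 1)
  Z[sd == 0, ] <- 0
  scores <- t(Z) %*% W
  view_matrix(scores, "pathways",
              provenance = list(n_model_genes = length(genes),
                                n_excluded = length(exclude_genes),
                                dropped_pathways = empty))
}

#' Transcription-factor activity as a rank-based enrichment score
#'
#' Regulons are filtered to the requested confidence grades; each retained
#' TF needs at least `min_targets` targets present in the expression
#' matrix. Per sample, expression is rank-transformed across genes
#' (average ranks for ties), mapped to quantiles q = (rank - 0.5)/n and
#' then to normal scores z = qnorm(q); the normalized enrichment score of
#' a TF is sum(mor_t * z_t) / sqrt(n_targets) over its present targets.
#'
#' @param expr a [gene_expr()].
#' @param regulons regulon data.frame (or a [prior_bundle()]).
#' @param confidence_keep confidence grades retained (default A and B).
#' @param min_targets minimum present targets per TF.
#' @return A `view_matrix` with `view_name = "tfs"`.
#' @export
compute_tf_activity <- function(expr, regulons, confidence_keep = c("A", "B"),
                                min_targets = 5L) {
  if (inherits(regulons, "prior_bundle")) regulons <- regulons$regulons
  reg <- regulons[regulons$confidence %in% confidence_keep, , drop = FALSE]
  if (nrow(reg) == 0L) stop2("no regulons left after confidence filter")
  reg <- reg[reg$target %in% rownames(expr$tpm), , drop = FALSE]
  n_tgt <- table(reg$tf)
  drop_tf <- names(n_tgt)[n_tgt < min_targets]
  if (length(drop_tf))
    warn2("TF(s) with fewer than ", min_targets, " present targets dropped: ",
          paste(drop_tf, collapse = ", "))
  reg <- reg[!reg$tf %in% drop_tf, , drop = FALSE]
  if (nrow(reg) == 0L) stop2("no TF regulons with enough present targets")
  n <- nrow(expr$tpm)
  Zs <- apply(expr$tpm, 2L, function(x) {
    q <- (rank(x, ties.method = "average") - 0.5) / n
    stats::qnorm(q)
  })
  rownames(Zs) <- rownames(expr$tpm)
  tfs <- unique(reg$tf)
  nes <- sapply(tfs, function(tf) {
    r <- reg[reg$tf == tf, ]
    colSums(Zs[r$target, , drop = FALSE] * r$mor) / sqrt(nrow(r))
  })
  if (is.null(dim(nes))) nes <- matrix(nes, nrow = 1L,
                                       dimnames = list(colnames(expr$tpm), tfs))
  view_matrix(nes, "tfs",
              provenance = list(confidence_keep = confidence_keep,
                                min_targets = min_targets,
                                dropped_tfs = drop_tf))
}

pair_genes <- function(db) Map(function(l, r) unique(c(l, r)),
                               db$pairs$ligand_genes, db$pairs$receptor_genes)

## per-pair logical: all constituent genes present in the prior table
genes_in_prior <- function(db) {
  cols <- colnames(db$celltype_expression)
  vapply(pair_genes(db), function(g) all(g %in% cols), logical(1L))
}

#' Filter an LR database to pairs expressible in the TME
#'
#' Keeps a pair iff (a) every ligand and receptor gene reaches
#' `tpm_threshold` in at least one cell type of the prior expression table
#' and (b) at least one ordered (sender, receiver) cell-type combination
#' exists (autocrine allowed) in which all ligand genes pass in the sender
#' and all receptor genes pass in the receiver. Ligands/receptors expressed
#' but never paired are removed implicitly by the pair filter.
#'
#' @param db an [lr_database()].
#' @param tpm_threshold TPM expression cutoff (default 10).
#' @return The filtered [lr_database()].
#' @export
derive_tme_lr_pairs <- function(db, tpm_threshold = 10) {
  stopifnot(inherits(db, "lr_database"))
  ctx <- db$celltype_expression
  pass <- ctx >= tpm_threshold
  keep <- vapply(seq_len(nrow(db$pairs)), function(i) {
    lig <- db$pairs$ligand_genes[[i]]
    rec <- db$pairs$receptor_genes[[i]]
    if (!all(c(lig, rec) %in% colnames(ctx))) return(FALSE)
    if (!all(colSums(pass[, c(lig, rec), drop = FALSE]) > 0L)) return(FALSE)
    send_ok <- rowSums(pass[, lig, drop = FALSE]) == length(lig)
    recv_ok <- rowSums(pass[, rec, drop = FALSE]) == length(rec)
    any(send_ok) && any(recv_ok) # ordered pairs incl. sender == receiver
  }, logical(1L))
  if (!any(keep)) warn2("no LR pairs survive the TME expression filter")
  out <- db
  out$pairs <- db$pairs[keep, , drop = FALSE]
  attr(out, "tpm_threshold") <- tpm_threshold
  out
}

#' Patient-level LR pair weights
#'
#' The weight of an LR pair in a sample is the minimum of log2(TPM+1) over
#' all constituent genes (ligand and receptor, including complex members):
#' the interaction is only as strong as its least-expressed component.
#' Genes absent from the expression matrix count as unexpressed (weight 0,
#' with a warning).
#'
#' @param expr a [gene_expr()].
#' @param db a (typically [derive_tme_lr_pairs()]-filtered) [lr_database()].
#' @return A `view_matrix` with `view_name = "lrpairs"`.
#' @export
compute_lr_view <- function(expr, db) {
  stopifnot(inherits(db, "lr_database"))
  if (nrow(db$pairs) == 0L) stop2("empty LR database")
  L <- log2(expr$tpm + 1)
  pg <- pair_genes(db)
  missing <- setdiff(unique(unlist(pg)), rownames(L))
  if (length(missing))
    warn2("LR gene(s) absent from expression treated as unexpressed: ",
          paste(utils::head(missing, 5L), collapse = ", "),
          if (length(missing) > 5L) ", ..." else "")
  vals <- vapply(pg, function(g) {
    present <- intersect(g, rownames(L))
    if (length(present) < length(g)) return(numeric(ncol(L)))
    apply(L[present, , drop = FALSE], 2L, min)
  }, numeric(ncol(L)))
  if (is.null(dim(vals)))
    vals <- matrix(vals, nrow = 1L)
  dimnames(vals) <- list(colnames(expr$tpm), db$pairs$pair_id)
  view_matrix(vals, "lrpairs",
              provenance = list(n_pairs = nrow(db$pairs),
                                missing_genes = missing))
}

#' Group LR features with identical weight profiles
#'
#' Pairs sharing their limiting gene get identical weights in every sample;
#' such duplicate columns are merged into a single feature whose name joins
#' the constituent pair ids with `"_"` in lexicographic order.
#'
#' @param view an `"lrpairs"` `view_matrix`.
#' @return The grouped `view_matrix`.
#' @export
group_lr_features <- function(view) {
  stopifnot(inherits(view, "view_matrix"), view$view_name == "lrpairs")
  V <- view$values
  if (ncol(V) <= 1L) return(view)
  key <- apply(V, 2L, function(col) paste(col, collapse = "\r"))
  groups <- split(colnames(V), key)
  merged_names <- vapply(groups, function(g)
    paste(sort(g), collapse = "_"), character(1L))
  first_col <- vapply(groups, function(g) g[[1L]], character(1L))
  ord <- order(match(first_col, colnames(V)))
  out <- V[, unname(first_col[ord]), drop = FALSE]
  colnames(out) <- unname(merged_names[ord])
  view_matrix(out, "lrpairs",
              provenance = c(view$provenance,
                             list(n_before_grouping = ncol(V),
                                  n_after_grouping = ncol(out),
                                  groups = stats::setNames(groups[ord],
                                                           merged_names[ord]))))
}

## static assignment of pairs to ordered aggregated (sender, receiver) types
assign_cc_pairs <- function(db, tpm_threshold) {
  ctx <- db$celltype_expression
  pass <- ctx >= tpm_threshold
  agg <- db$aggregation_map
  lapply(seq_len(nrow(db$pairs)), function(i) {
    lig <- db$pairs$ligand_genes[[i]]
    rec <- db$pairs$receptor_genes[[i]]
    if (!all(c(lig, rec) %in% colnames(ctx))) return(character())
    senders <- rownames(ctx)[rowSums(pass[, lig, drop = FALSE]) == length(lig)]
    receivers <- rownames(ctx)[rowSums(pass[, rec, drop = FALSE]) == length(rec)]
    s_agg <- unique(agg[senders]); r_agg <- unique(agg[receivers])
    s_agg <- s_agg[!is.na(s_agg)]; r_agg <- r_agg[!is.na(r_agg)]
    if (!length(s_agg) || !length(r_agg)) return(character())
    as.vector(outer(s_agg, r_agg, function(s, r) paste0(s, "->", r)))
  })
}

## per-sample pair activity in a bulk profile: all genes >= threshold TPM
patient_active <- function(expr, db, tpm_threshold) {
  tpm <- expr$tpm
  pg <- pair_genes(db)
  act <- vapply(pg, function(g) {
    if (!all(g %in% rownames(tpm))) return(logical(ncol(tpm)))
    colSums(tpm[g, , drop = FALSE] >= tpm_threshold) == length(g)
  }, logical(ncol(tpm)))
  if (is.null(dim(act))) act <- matrix(act, nrow = 1L)
  dimnames(act) <- list(colnames(tpm), db$pairs$pair_id)
  act
}

#' Reference-cohort frequency of LR pair activity
#'
#' Fraction of reference samples in which each pair is active (all
#' constituent genes at or above `tpm_threshold` TPM in the bulk profile).
#'
#' @param reference_expr a [gene_expr()] for the reference cohort.
#' @param db an [lr_database()].
#' @param tpm_threshold TPM activity cutoff.
#' @return Named numeric vector of frequencies in `[0, 1]` per pair id.
#' @export
lr_pair_frequencies <- function(reference_expr, db, tpm_threshold = 10) {
  colMeans(patient_active(reference_expr, db, tpm_threshold))
}

#' Cell-cell communication scores
#'
#' Every LR pair is statically assigned to the ordered aggregated
#' (sender -> receiver) cell-type pairs in which the prior expression table
#' passes the TPM threshold for ligand (sender) and receptor (receiver),
#' autocrine included. A pair is active in a patient when all its genes
#' reach the threshold in the bulk profile. The score of a CC pair is the
#' sum of 1/frequency over its assigned, patient-active LR pairs, where the
#' frequency is the fraction of reference-cohort samples in which the pair
#' is active; rarer interactions therefore weigh more. Pairs never active
#' in the reference (frequency 0) are excluded. One feature per ordered
#' pair of aggregated cell types (13 types -> 169 features for the
#' canonical list).
#'
#' @param expr a [gene_expr()] for the cohort being scored.
#' @param db a filtered [lr_database()].
#' @param reference_frequencies named per-pair frequencies, or `NULL` to
#'   compute them from `reference_expr`.
#' @param reference_expr optional reference cohort used when frequencies
#'   are not supplied.
#' @param tpm_threshold TPM activity cutoff (default 10).
#' @return A `view_matrix` with `view_name = "ccpairs"`; the frequencies
#'   used are stored in its `provenance`.
#' @export
compute_cc_view <- function(expr, db, reference_frequencies = NULL,
                            reference_expr = NULL, tpm_threshold = 10) {
  stopifnot(inherits(db, "lr_database"))
  if (length(db$aggregation_map) == 0L)
    stop2("CC scoring needs an aggregation map for the prior cell types")
  if (is.null(reference_frequencies)) {
    if (is.null(reference_expr))
      stop2("supply reference_frequencies or a reference cohort ",
            "(reference_expr) to compute them from")
    reference_frequencies <- lr_pair_frequencies(reference_expr, db, tpm_threshold)
  }
  f <- reference_frequencies[db$pairs$pair_id]
  f[is.na(f)] <- 0
  assign <- assign_cc_pairs(db, tpm_threshold)
  act <- patient_active(expr, db, tpm_threshold)
  types <- db$aggregated_types
  feats <- as.vector(t(outer(types, types, function(s, r) paste0(s, "->", r))))
  scores <- matrix(0, nrow(act), length(feats),
                   dimnames = list(rownames(act), feats))
  for (i in seq_along(assign)) {
    cc <- intersect(assign[[i]], feats)
    if (length(cc) == 0L || f[i] <= 0) next
    scores[, cc] <- scores[, cc] + act[, i] / f[i]
  }
  view_matrix(scores, "ccpairs",
              provenance = list(tpm_threshold = tpm_threshold,
                                frequencies = as.list(f)))
}

#' Compute all requested TME views
#'
#' Convenience wrapper deriving any subset of the five views from one
#' expression matrix and a prior bundle.
#'
#' @param expr a [gene_expr()].
#' @param priors a [prior_bundle()].
#' @param which views to compute (default all five).
#' @param exclude_genes genes removed from the pathway model.
#' @param tpm_threshold TPM cutoff for the LR/CC machinery.
#' @param cc_frequencies stored reference frequencies for the CC view; when
#'   `NULL` the cohort itself is used as the reference.
#' @param group_lr merge identical LR feature columns (default TRUE).
#' @return Named list of `view_matrix` objects.
#' @export
compute_views <- function(expr, priors,
                          which = c("cellfrac", "pathways", "tfs",
                                    "lrpairs", "ccpairs"),
                          exclude_genes = NULL, tpm_threshold = 10,
                          cc_frequencies = NULL, group_lr = TRUE) {
  stopifnot(inherits(priors, "prior_bundle"))
  out <- list()
  need_db <- any(c("lrpairs", "ccpairs") %in% which)
  if (need_db)
    db <- derive_tme_lr_pairs(priors$lr_database, tpm_threshold)
  if ("cellfrac" %in% which)
    out$cellfrac <- deconvolve_cell_fractions(expr, priors$cell_signature)
  if ("pathways" %in% which)
    out$pathways <- compute_pathway_activity(expr, priors$pathway_model,
                                             exclude_genes)
  if ("tfs" %in% which)
    out$tfs <- compute_tf_activity(expr, priors$regulons)
  if ("lrpairs" %in% which) {
    v <- compute_lr_view(expr, db)
    out$lrpairs <- if (group_lr) group_lr_features(v) else v
  }
  if ("ccpairs" %in% which)
    out$ccpairs <- compute_cc_view(expr, db,
                                   reference_frequencies = cc_frequencies,
                                   reference_expr = if (is.null(cc_frequencies)) expr,
                                   tpm_threshold = tpm_threshold)
  out
}
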