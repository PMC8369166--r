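## Seeded generators of prior knowledge, expression cohorts, and responder
## labels with the statistical structure the pipeline assumes, so every
## stage is testable without external cohorts.

SYNTH_AGG_TYPES <- c("Bcell", "Tcell", "NKcell", "Myeloid", "Dendritic",
                     "Mast", "Fibroblast", "Endothelial", "Adipocyte",
                     "Pericyte", "MonoMac", "Granulocyte")

rdirichlet1 <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              n, length(alpha), byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic prior-knowledge bundle
#'
#' Builds a cell signature with disjoint high-expression marker blocks per
#' cell type, a block-sparse pathway weight matrix, regulons with disjoint
#' targets (confidence A/B), an LR database whose cell-type expression
#' table makes every pair pass the 10 TPM filter for at least one
#' (sender, receiver) combination, and a default set of immune-response
#' score definitions anchored to the immune marker blocks.
#'
#' @param n_genes total gene universe (default 2000).
#' @param n_celltypes number of immune cell types (10 gives the canonical
#'   names).
#' @param n_pathways number of pathways (14 gives the canonical names).
#' @param n_tfs number of transcription factors.
#' @param n_lr_pairs number of ligand-receptor pairs.
#' @param seed RNG seed; the same seed yields an identical bundle.
#' @param markers_per_type,genes_per_pathway,targets_per_tf block sizes.
#' @return A [prior_bundle()]; block allocations are attached as attribute
#'   `"blocks"` for recovery tests.
#' @export
make_priors <- function(n_genes = 2000L, n_celltypes = 10L, n_pathways = 14L,
                        n_tfs = 30L, n_lr_pairs = 40L, seed = 1L,
                        markers_per_type = 30L, genes_per_pathway = 20L,
                        targets_per_tf = 8L) {
  stopifnot(n_genes > 0, n_celltypes > 0, n_pathways > 0, n_tfs > 0,
            n_lr_pairs > 0)
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  need <- n_celltypes * markers_per_type + n_pathways * genes_per_pathway +
    n_tfs * targets_per_tf + n_lr_pairs * 3L + 50L
  if (n_genes < need)
    stop2("infeasible sizes: need at least ", need, " genes for disjoint blocks")
  pool <- genes
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  cts <- if (n_celltypes == 10L) CANONICAL_CELL_TYPES else
    sprintf("CT%02d", seq_len(n_celltypes))
  marker_blocks <- stats::setNames(
    lapply(seq_len(n_celltypes), function(i) take(markers_per_type)), cts)
  sig <- matrix(0, n_genes, n_celltypes, dimnames = list(genes, cts))
  for (ct in cts)
    sig[marker_blocks[[ct]], ct] <- stats::runif(markers_per_type, 500, 2000)
  sig <- sweep(sig, 2L, colSums(sig), `/`) * 1e6 # TPM-scale profiles

  pws <- if (n_pathways == 14L) CANONICAL_PATHWAYS else
    sprintf("PW%02d", seq_len(n_pathways))
  pw_blocks <- stats::setNames(
    lapply(seq_len(n_pathways), function(i) take(genes_per_pathway)), pws)
  pw <- matrix(0, n_genes, n_pathways, dimnames = list(genes, pws))
  for (p in pws)
    pw[pw_blocks[[p]], p] <- stats::runif(genes_per_pathway, 0.5, 1.5) *
      sample(c(1, -1), genes_per_pathway, replace = TRUE, prob = c(0.8, 0.2))

  tf_names <- sprintf("TF%02d", seq_len(n_tfs))
  tf_blocks <- stats::setNames(
    lapply(seq_len(n_tfs), function(i) take(targets_per_tf)), tf_names)
  regulons <- do.call(rbind, lapply(tf_names, function(tf)
    data.frame(tf = tf, target = tf_blocks[[tf]],
               mor = sample(c(1, -1), targets_per_tf, replace = TRUE,
                            prob = c(0.75, 0.25)),
               confidence = sample(c("A", "B"), targets_per_tf, replace = TRUE),
               stringsAsFactors = FALSE)))

  ## LR database: 24 fine TME cell types in 12 aggregated types + pan-cancer
  fine <- c(paste0(rep(SYNTH_AGG_TYPES, each = 2L), c("_1", "_2")), "Pancancer")
  aggmap <- stats::setNames(c(rep(SYNTH_AGG_TYPES, each = 2L), "Pancancer"), fine)
  agg_types <- c(SYNTH_AGG_TYPES, "Pancancer")
  complex_lig <- stats::runif(n_lr_pairs) < 0.1
  lig_genes <- lapply(seq_len(n_lr_pairs), function(i)
    take(if (complex_lig[i]) 2L else 1L))
  rec_genes <- lapply(seq_len(n_lr_pairs), function(i) take(1L))
  lr_genes <- unlist(c(lig_genes, rec_genes))
  ctx <- matrix(stats::runif(length(fine) * length(lr_genes), 0, 2),
                length(fine), length(lr_genes),
                dimnames = list(fine, lr_genes))
  senders <- sample(fine, n_lr_pairs, replace = TRUE)
  receivers <- sample(fine, n_lr_pairs, replace = TRUE)
  for (i in seq_len(n_lr_pairs)) {
    ctx[senders[i], lig_genes[[i]]] <- stats::runif(length(lig_genes[[i]]), 40, 80)
    ctx[receivers[i], rec_genes[[i]]] <- stats::runif(1L, 40, 80)
  }
  pairs <- data.frame(
    pair_id = sprintf("LR%03d", seq_len(n_lr_pairs)),
    ligand_genes = vapply(lig_genes, paste, character(1L), collapse = ";"),
    receptor_genes = vapply(rec_genes, paste, character(1L), collapse = ";"),
    stringsAsFactors = FALSE)
  db <- lr_database(pairs, ctx, aggmap, agg_types)

  housekeeping <- take(10L)
  cd8 <- marker_blocks[[if ("CD8" %in% cts) "CD8" else cts[[1L]]]]
  nk <- marker_blocks[[if ("NK" %in% cts) "NK" else cts[[min(2L, n_celltypes)]]]]
  bmk <- marker_blocks[[if ("B" %in% cts) "B" else cts[[min(3L, n_celltypes)]]]]
  defs <- list(
    score_definition("CYT", "geometric_mean", genes = cd8[1:2]),
    score_definition("IFNg", "weighted_mean", genes = c(cd8[3:6], nk[1:4])),
    score_definition("TLS", "weighted_mean", genes = bmk[1:8]),
    score_definition("Ayers_expIS", "rank_normalized_mean",
                     genes = c(cd8[7:10], nk[5:8], bmk[9:10])),
    score_definition("IMPRES", "pair_logic",
                     gene_pairs = data.frame(g1 = c(cd8[11:13], nk[9:11]),
                                             g2 = housekeeping[1:6])),
    score_definition("Chemokines", "pc1",
                     genes = c(cd8[14:17], nk[12:15], bmk[11:14]),
                     sign_anchor = c("CYT", "IFNg")))
  bundle <- prior_bundle(sig, pw, regulons, db, defs)
  attr(bundle, "blocks") <- list(markers = marker_blocks, pathways = pw_blocks,
                                 tf_targets = tf_blocks,
                                 lr_ligands = lig_genes, lr_receptors = rec_genes,
                                 housekeeping = housekeeping,
                                 lr_senders = senders, lr_receivers = receivers)
  bundle
}

#' Generate a synthetic bulk expression cohort with known ground truth
#'
#' Cell fractions are drawn from a Dirichlet over the immune cell types
#' plus an "other" (tumor-like) component; the bulk TPM profile is the
#' signature mixture plus a flat other-cell profile covering non-marker
#' genes (so noiseless mixtures are exactly recoverable). Pathway and TF
#' structure is spiked by scaling block genes with per-sample activities
#' on the log2 scale, LR pair genes are toggled between an active and an
#' inactive expression level per sample, multiplicative lognormal noise is
#' applied, and every sample is renormalized to 1e6.
#'
#' @param priors a bundle from [make_priors()].
#' @param n_samples cohort size (default 300).
#' @param dirichlet_alpha concentration over (immune types..., other);
#'   default `c(rep(0.5, K), 5)`, i.e. a tumor-dominated mixture.
#' @param noise_sd lognormal noise SD on the log scale (default 0.1).
#' @param seed RNG seed.
#' @param spike_gain log2-scale gain of the pathway/TF spiking.
#' @param lr_contrast multipliers applied to LR pair genes in samples where
#'   the pair is (active, inactive); `c(1, 1)` disables LR modulation.
#' @return List with `expr` (a [gene_expr()]) and `truth` (a
#'   `synthetic_truth` list: fractions, activities, LR states, latent
#'   immune activity, parameters).
#' @export
make_cohort <- function(priors, n_samples = 300L, dirichlet_alpha = NULL,
                        noise_sd = 0.1, seed = 1L, spike_gain = 1,
                        lr_contrast = c(4, 0.25)) {
  blocks <- attr(priors, "blocks")
  if (is.null(blocks)) stop2("priors must come from make_priors()")
  set.seed(seed)
  sig <- priors$cell_signature
  genes <- rownames(sig)
  cts <- colnames(sig)
  K <- length(cts)
  alpha <- dirichlet_alpha %||% c(rep(0.5, K), 5)
  if (length(alpha) != K + 1L)
    stop2("dirichlet_alpha needs ", K + 1L, " components (immune types + other)")
  fr <- rdirichlet1(n_samples, alpha)
  colnames(fr) <- c(cts, "Other")
  samples <- sprintf("S%04d", seq_len(n_samples))
  rownames(fr) <- samples

  ## other-cell profile: zero on markers, modest on LR genes (so bulk LR
  ## activity is tunable), flat on the remaining background genes
  other <- stats::setNames(numeric(length(genes)), genes)
  marker_genes <- unlist(blocks$markers)
  lr_genes <- unlist(c(blocks$lr_ligands, blocks$lr_receptors))
  bg <- setdiff(genes, marker_genes)
  other[bg] <- 1e6 / length(bg)
  other[lr_genes] <- 10 # base TPM; per-sample multipliers move it across 10
  other <- other / sum(other) * 1e6 # a proper TPM profile

  bulk <- sig %*% t(fr[, cts, drop = FALSE]) +
    outer(other, fr[, "Other"])

  pw_act <- matrix(stats::rnorm(n_samples * length(blocks$pathways)),
                   n_samples, length(blocks$pathways),
                   dimnames = list(samples, names(blocks$pathways)))
  for (p in names(blocks$pathways)) {
    g <- blocks$pathways[[p]]
    sgn <- sign(priors$pathway_model[g, p])
    bulk[g, ] <- bulk[g, ] * 2^(spike_gain * outer(sgn, pw_act[, p]))
  }
  tf_act <- matrix(stats::rnorm(n_samples * length(blocks$tf_targets)),
                   n_samples, length(blocks$tf_targets),
                   dimnames = list(samples, names(blocks$tf_targets)))
  for (tf in names(blocks$tf_targets)) {
    g <- blocks$tf_targets[[tf]]
    mor <- priors$regulons$mor[match(g, priors$regulons$target)]
    bulk[g, ] <- bulk[g, ] * 2^(spike_gain * outer(mor, tf_act[, tf]))
  }
  n_pairs <- length(blocks$lr_ligands)
  lr_active <- matrix(stats::runif(n_samples * n_pairs) < 0.5,
                      n_samples, n_pairs,
                      dimnames = list(samples, priors$lr_database$pairs$pair_id))
  for (i in seq_len(n_pairs)) {
    g <- c(blocks$lr_ligands[[i]], blocks$lr_receptors[[i]])
    bulk[g, ] <- bulk[g, ] * rep(ifelse(lr_active[, i], lr_contrast[1L],
                                        lr_contrast[2L]), each = length(g))
  }
  if (noise_sd > 0)
    bulk <- bulk * exp(matrix(stats::rnorm(length(bulk), 0, noise_sd),
                              nrow(bulk)))
  bulk <- sweep(bulk, 2L, colSums(bulk), `/`) * 1e6
  colnames(bulk) <- samples

  cd8_col <- if ("CD8" %in% cts) "CD8" else cts[[1L]]
  z <- function(x) (x - mean(x)) / max(pop_sd(x), .Machine$double.eps)
  latent <- z(0.8 * z(fr[, cd8_col]) +
                0.4 * z(rowMeans(pw_act[, 1:min(2L, ncol(pw_act)), drop = FALSE])))
  truth <- structure(list(fractions = fr, pathway_activity = pw_act,
                          tf_activity = tf_act, lr_active = lr_active,
                          latent_immune = stats::setNames(latent, samples),
                          params = list(n_samples = n_samples, alpha = alpha,
                                        noise_sd = noise_sd, seed = seed,
                                        spike_gain = spike_gain,
                                        lr_contrast = lr_contrast)),
                     class = "synthetic_truth")
  list(expr = gene_expr(bulk), truth = truth)
}

#' Generate responder labels from a latent immune-activity variable
#'
#' Responder probability is `plogis(intercept + effect_size * z)` with `z`
#' the standardized latent immune activity; the intercept is solved so the
#' expected prevalence matches the target.
#'
#' @param truth a `synthetic_truth` from [make_cohort()].
#' @param effect_size log-odds per SD of latent immune activity
#'   (default 2).
#' @param prevalence target responder fraction in (0, 1) (default 0.35).
#' @param seed RNG seed for the label draw.
#' @return A `response_labels` data.frame; the responder probabilities are
#'   attached as attribute `"probability"`.
#' @export
make_icb_labels <- function(truth, effect_size = 2, prevalence = 0.35,
                            seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (prevalence <= 0 || prevalence >= 1)
    stop2("prevalence must be inside (0, 1)")
  z <- truth$latent_immune
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + effect_size * z)) -
                         prevalence, c(-50, 50))$root
  pr <- stats::plogis(b0 + effect_size * z)
  set.seed(seed)
  lab <- ifelse(stats::runif(length(z)) < pr, "R", "NR")
  out <- data.frame(sample_id = names(z), label = lab,
                    source = "synthetic", stringsAsFactors = FALSE)
  class(out) <- c("response_labels", "data.frame")
  attr(out, "probability") <- pr
  attr(out, "intercept") <- b0
  out
}

#' Write a prior bundle to plain-text files plus a YAML config
#'
#' Serializes every component of a [prior_bundle()] as TSV (and the score
#' definitions as YAML) into a directory and writes the `priors.yaml`
#' config that [load_priors()] can read back.
#'
#' @param priors a [prior_bundle()].
#' @param dir output directory (created if needed).
#' @return Path of the written YAML config, invisibly.
#' @export
write_priors <- function(priors, dir) {
  stopifnot(inherits(priors, "prior_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(priors$cell_signature, file.path(dir, "cell_signature.tsv"), "gene")
  write_tsv(priors$pathway_model, file.path(dir, "pathway_model.tsv"), "gene")
  utils::write.table(priors$regulons, file.path(dir, "regulons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  db <- priors$lr_database
  pairs <- data.frame(pair_id = db$pairs$pair_id,
                      ligand_genes = vapply(db$pairs$ligand_genes, paste,
                                            character(1L), collapse = ";"),
                      receptor_genes = vapply(db$pairs$receptor_genes, paste,
                                              character(1L), collapse = ";"))
  utils::write.table(pairs, file.path(dir, "lr_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(db$celltype_expression,
            file.path(dir, "lr_celltype_expression.tsv"), "cell_type")
  utils::write.table(data.frame(cell_type = names(db$aggregation_map),
                                aggregated = unname(db$aggregation_map)),
                     file.path(dir, "lr_aggregation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sd_cfg <- lapply(priors$score_definitions, function(d) {
    out <- list(name = d$name, form = d$form)
    if (!is.null(d$genes)) out$genes <- as.list(d$genes)
    if (!is.null(d$weights)) out$weights <- as.list(d$weights)
    if (!is.null(d$gene_pairs))
      out$gene_pairs <- lapply(seq_len(nrow(d$gene_pairs)), function(i)
        list(d$gene_pairs$g1[i], d$gene_pairs$g2[i]))
    out$transform <- d$transform
    out$pseudocount <- d$pseudocount
    if (!is.null(d$sign_anchor)) out$sign_anchor <- as.list(d$sign_anchor)
    out
  })
  yaml::write_yaml(sd_cfg, file.path(dir, "score_definitions.yaml"))
  cfg <- list(cell_signature = "cell_signature.tsv",
              pathway_model = "pathway_model.tsv",
              regulons = "regulons.tsv",
              lr_pairs = "lr_pairs.tsv",
              lr_celltype_expression = "lr_celltype_expression.tsv",
              lr_aggregation = "lr_aggregation.tsv",
              aggregated_types = as.list(db$aggregated_types),
              score_definitions = "score_definitions.yaml")
  path <- file.path(dir, "priors.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}
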