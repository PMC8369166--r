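## Canonical feature vocabularies. The immune-cell list mirrors the ten
## deconvolution cell types; "CD4" is reported as the sum of non-regulatory
## CD4 T cells and Tregs while Tregs stay a separate column, plus "Other"
## (1 - total immune content), giving 11 cell-fraction features.
CANONICAL_CELL_TYPES <- c("B", "CD4", "CD8", "DC", "M1", "M2",
                          "Monocyte", "Neutrophil", "NK", "Treg")

CANONICAL_PATHWAYS <- c("Androgen", "EGFR", "Estrogen", "Hypoxia", "JAK-STAT",
                        "MAPK", "NFkB", "p53", "PI3K", "TGFb", "TNFa",
                        "Trail", "VEGF", "WNT")

#' Ligand-receptor pair database
#'
#' A set of ligand-receptor (LR) pairs, a cell-type x gene TPM expression
#' table used as prior knowledge of who can express what, and a map from
#' fine cell types to aggregated cell types used for cell-cell (CC)
#' communication scoring. Multi-gene complexes are encoded as
#' `";"`-separated gene lists.
#'
#' @param pairs data.frame with columns `pair_id`, `ligand_genes`,
#'   `receptor_genes` (gene symbols, `";"`-joined for complexes).
#' @param celltype_expression numeric matrix, cell types x genes, TPM scale.
#' @param aggregation_map named character vector: fine cell type ->
#'   aggregated cell type.
#' @param aggregated_types ordered character vector of aggregated cell types
#'   (the TME-aggregated types plus one pan-cancer type).
#' @return An object of class `lr_database`.
#' @export
lr_database <- function(pairs, celltype_expression, aggregation_map,
                        aggregated_types) {
  stopifnot(is.data.frame(pairs),
            all(c("pair_id", "ligand_genes", "receptor_genes") %in% names(pairs)))
  if (anyDuplicated(pairs$pair_id)) stop2("duplicate pair_id in LR database")
  lig <- strsplit(as.character(pairs$ligand_genes), ";", fixed = TRUE)
  rec <- strsplit(as.character(pairs$receptor_genes), ";", fixed = TRUE)
  if (any(lengths(lig) == 0L) || any(lengths(rec) == 0L) ||
      any(vapply(c(lig, rec), function(g) any(g == ""), logical(1L))))
    stop2("LR pair with empty ligand or receptor gene set")
  celltype_expression <- as.matrix(celltype_expression)
  if (length(aggregation_map)) {
    missing_ct <- setdiff(names(aggregation_map), rownames(celltype_expression))
    if (length(missing_ct))
      stop2("aggregation_map cell types absent from celltype_expression: ",
            paste(missing_ct, collapse = ", "))
  }
  if (anyDuplicated(aggregated_types)) stop2("duplicate aggregated cell types")
  all_genes <- unique(unlist(c(lig, rec)))
  absent <- setdiff(all_genes, colnames(celltype_expression))
  if (length(absent))
    warn2("LR genes absent from celltype_expression (pairs kept but inert ",
          "for CC assignment): ", paste(utils::head(absent, 5L), collapse = ", "),
          if (length(absent) > 5L) ", ..." else "")
  structure(list(pairs = data.frame(pair_id = as.character(pairs$pair_id),
                                    ligand_genes = I(lig), receptor_genes = I(rec),
                                    stringsAsFactors = FALSE),
                 celltype_expression = celltype_expression,
                 aggregation_map = aggregation_map,
                 aggregated_types = as.character(aggregated_types)),
            class = "lr_database")
}

#' @export
print.lr_database <- function(x, ...) {
  cat(sprintf("<lr_database> %d pairs, %d cell types, %d aggregated types\n",
              nrow(x$pairs), nrow(x$celltype_expression),
              length(x$aggregated_types)))
  invisible(x)
}

#' Immune-response score definition
#'
#' Describes one transcriptome-based proxy score of immune response in a
#' form the generic score engine can evaluate: a geometric mean over genes
#' (e.g. cytolytic activity over GZMA/PRF1), a (rank-normalized) weighted
#' mean, a count of satisfied gene-pair inequalities, or the first
#' principal component of a gene set with its sign anchored to correlated
#' tasks.
#'
#' @param name unique score name.
#' @param form one of `"geometric_mean"`, `"weighted_mean"`,
#'   `"rank_normalized_mean"`, `"pair_logic"`, `"pc1"`.
#' @param genes character vector of gene symbols (all forms except
#'   `pair_logic`).
#' @param weights optional numeric weights matched to `genes`.
#' @param gene_pairs data.frame with columns `g1`, `g2` (`pair_logic` only).
#' @param transform expression transform: `"log2_tpm1p"` (default for
#'   mean-type scores), `"tpm"`, or `"identity"`.
#' @param pseudocount added to TPM inside geometric means.
#' @param sign_anchor character vector of task names whose mean fixes the
#'   PC1 sign.
#' @return An object of class `score_definition`.
#' @export
score_definition <- function(name, form, genes = NULL, weights = NULL,
                             gene_pairs = NULL, transform = NULL,
                             pseudocount = 0.01, sign_anchor = NULL) {
  forms <- c("geometric_mean", "weighted_mean", "rank_normalized_mean",
             "pair_logic", "pc1")
  if (!form %in% forms) stop2("unknown score form: ", form)
  if (form == "pair_logic") {
    if (is.null(gene_pairs) || nrow(gene_pairs) == 0L)
      stop2("pair_logic score '", name, "' needs non-empty gene_pairs")
  } else if (is.null(genes) || length(genes) == 0L) {
    stop2("score '", name, "' needs a non-empty gene list")
  }
  if (!is.null(weights) && length(weights) != length(genes))
    stop2("weights length must match genes for score '", name, "'")
  transform <- transform %||% if (form == "geometric_mean") "tpm" else "log2_tpm1p"
  structure(list(name = name, form = form, genes = genes, weights = weights,
                 gene_pairs = gene_pairs, transform = transform,
                 pseudocount = pseudocount, sign_anchor = sign_anchor),
            class = "score_definition")
}

#' Prior-knowledge bundle
#'
#' Collects the prior knowledge the five TME views and the response scores
#' are built from: a cell-type signature matrix for deconvolution, a
#' pathway gene-weight matrix, transcription-factor regulons, an LR
#' database, and immune-response score definitions.
#'
#' @param cell_signature numeric genes x cell-types matrix, TPM scale, >= 0.
#' @param pathway_model numeric genes x pathways weight matrix.
#' @param regulons data.frame with columns `tf`, `target`,
#'   `mor` (-1 or +1), `confidence` (A-E).
#' @param lr_database an [lr_database()] object.
#' @param score_definitions list of [score_definition()] objects.
#' @return An object of class `prior_bundle`.
#' @export
prior_bundle <- function(cell_signature, pathway_model, regulons,
                         lr_database, score_definitions = list()) {
  cell_signature <- as.matrix(cell_signature)
  if (anyDuplicated(colnames(cell_signature))) stop2("duplicate cell-type names")
  if (any(cell_signature < 0)) stop2("cell signature must be non-negative")
  pathway_model <- as.matrix(pathway_model)
  if (anyDuplicated(colnames(pathway_model))) stop2("duplicate pathway names")
  stopifnot(is.data.frame(regulons),
            all(c("tf", "target", "mor", "confidence") %in% names(regulons)))
  if (!all(regulons$mor %in% c(-1, 1))) stop2("regulon mor must be -1 or +1")
  if (!all(regulons$confidence %in% LETTERS[1:5]))
    stop2("regulon confidence must be one of A-E")
  if (nrow(regulons) == 0L) stop2("empty regulon table")
  stopifnot(inherits(lr_database, "lr_database"))
  nm <- vapply(score_definitions, function(d) d$name, character(1L))
  if (anyDuplicated(nm)) stop2("duplicate score definition names")
  structure(list(cell_signature = cell_signature, pathway_model = pathway_model,
                 regulons = regulons, lr_database = lr_database,
                 score_definitions = score_definitions),
            class = "prior_bundle")
}

#' @export
print.prior_bundle <- function(x, ...) {
  cat(sprintf(paste0("<prior_bundle> signature %d genes x %d cell types; ",
                     "%d pathways; %d regulon edges (%d TFs); %d LR pairs; ",
                     "%d score definitions\n"),
              nrow(x$cell_signature), ncol(x$cell_signature),
              ncol(x$pathway_model), nrow(x$regulons),
              length(unique(x$regulons$tf)), nrow(x$lr_database$pairs),
              length(x$score_definitions)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (tab-separated: name, description, genes...).
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("cannot read GMT file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop2("malformed GMT line (need name, description, >=1 gene)")
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L))
  sets
}

score_definition_from_config <- function(cfg, base_dir = ".") {
  genes <- cfg$genes
  if (!is.null(cfg$gmt)) {
    sets <- read_gmt(file.path(base_dir, cfg$gmt))
    genes <- sets[[cfg$gmt_set %||% 1L]]
  }
  gp <- NULL
  if (!is.null(cfg$gene_pairs))
    gp <- data.frame(g1 = vapply(cfg$gene_pairs, `[[`, character(1L), 1L),
                     g2 = vapply(cfg$gene_pairs, `[[`, character(1L), 2L),
                     stringsAsFactors = FALSE)
  score_definition(name = cfg$name, form = cfg$form, genes = unlist(genes),
                   weights = unlist(cfg$weights), gene_pairs = gp,
                   transform = cfg$transform,
                   pseudocount = cfg$pseudocount %||% 0.01,
                   sign_anchor = unlist(cfg$sign_anchor))
}

#' Load a prior-knowledge bundle from a YAML config
#'
#' The config names the path of each component (relative paths resolve
#' against the config's directory): `cell_signature` (TSV, genes x cell
#' types), `pathway_model` (TSV, genes x pathways), `regulons` (TSV with
#' columns tf/target/mor/confidence), `lr_pairs` (TSV with `";"`-joined
#' complex members), `lr_celltype_expression` (TSV, cell types x genes),
#' `lr_aggregation` (TSV, columns cell_type/aggregated), optional
#' `aggregated_types`, and `score_definitions` (inline list or a YAML
#' file; GMT accepted for gene lists).
#'
#' Regulons of every confidence grade are retained at load time; the
#' confidence filter is applied downstream when TF activities are computed.
#'
#' @param config path to the YAML configuration file.
#' @return A [prior_bundle()].
#' @export
load_priors <- function(config) {
  if (!file.exists(config)) stop2("cannot read priors config: ", config)
  cfg <- yaml::read_yaml(config)
  base_dir <- dirname(config)
  need <- c("cell_signature", "pathway_model", "regulons", "lr_pairs",
            "lr_celltype_expression", "lr_aggregation")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop2("priors config missing component(s): ", paste(miss, collapse = ", "))
  p <- function(x) if (file.exists(x)) x else file.path(base_dir, x)

  sig <- as.matrix(read_table_auto(p(cfg$cell_signature), row_names = 1L))
  pw <- as.matrix(read_table_auto(p(cfg$pathway_model), row_names = 1L))
  reg <- read_table_auto(p(cfg$regulons))
  pairs <- read_table_auto(p(cfg$lr_pairs))
  ctx <- as.matrix(read_table_auto(p(cfg$lr_celltype_expression), row_names = 1L))
  aggdf <- read_table_auto(p(cfg$lr_aggregation))
  if (!all(c("cell_type", "aggregated") %in% names(aggdf)))
    stop2("lr_aggregation table needs columns cell_type, aggregated")
  aggmap <- stats::setNames(as.character(aggdf$aggregated),
                            as.character(aggdf$cell_type))
  agg_types <- unlist(cfg$aggregated_types) %||% unique(unname(aggmap))
  db <- lr_database(pairs, ctx, aggmap, agg_types)

  defs <- list()
  if (!is.null(cfg$score_definitions)) {
    sd_cfg <- cfg$score_definitions
    if (is.character(sd_cfg)) sd_cfg <- yaml::read_yaml(p(sd_cfg))
    defs <- lapply(sd_cfg, score_definition_from_config, base_dir = base_dir)
  }
  prior_bundle(sig, pw, reg, db, defs)
}

#' Report gene overlap between an expression matrix and prior components
#'
#' @param expr a [gene_expr()].
#' @param priors a [prior_bundle()].
#' @return data.frame with one row per component: genes in the prior, genes
#'   shared with `expr`, and the shared fraction.
#' @export
prior_gene_overlap <- function(expr, priors) {
  gx <- rownames(expr$tpm)
  comp <- list(
    cell_signature = rownames(priors$cell_signature),
    pathway_model = rownames(priors$pathway_model),
    regulon_targets = unique(priors$regulons$target),
    lr_genes = unique(unlist(c(priors$lr_database$pairs$ligand_genes,
                               priors$lr_database$pairs$receptor_genes))))
  do.call(rbind, lapply(names(comp), function(nm) {
    g <- comp[[nm]]
    data.frame(component = nm, n_genes = length(g),
               n_shared = length(intersect(g, gx)),
               fraction = length(intersect(g, gx)) / max(1L, length(g)))
  }))
}
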