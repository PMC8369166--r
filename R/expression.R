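#' Gene expression container
#'
#' Holds a genes x samples expression matrix on the TPM scale, with an
#' optional matched matrix of raw counts. Gene identifiers are HGNC symbols
#' and must be unique; [load_expression()] enforces this by averaging rows
#' that share a symbol.
#'
#' @param tpm numeric matrix, genes x samples, non-negative, with unique
#'   rownames (gene symbols) and colnames (sample ids).
#' @param counts optional numeric matrix with identical dimnames.
#' @return An object of class `gene_expr`.
#' @export
gene_expr <- function(tpm, counts = NULL) {
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm)) || is.null(colnames(tpm)))
    stop2("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(tpm))) stop2("duplicate gene symbols in expression matrix")
  if (anyDuplicated(colnames(tpm))) stop2("duplicate sample ids in expression matrix")
  if (any(!is.finite(tpm)) || any(tpm < 0)) stop2("TPM values must be finite and >= 0")
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (!identical(dimnames(counts), dimnames(tpm)))
      stop2("counts and tpm must share gene and sample axes")
    if (any(!is.finite(counts)) || any(counts < 0)) stop2("counts must be finite and >= 0")
  }
  structure(list(tpm = tpm, counts = counts), class = "gene_expr")
}

#' @export
print.gene_expr <- function(x, ...) {
  cat(sprintf("<gene_expr> %d genes x %d samples (TPM%s)\n",
              nrow(x$tpm), ncol(x$tpm),
              if (is.null(x$counts)) "" else " + counts"))
  invisible(x)
}

#' @export
dim.gene_expr <- function(x) dim(x$tpm)

## HGNC symbol validity: non-empty, not the literal "NA", restricted charset.
## Deliberately offline -- no live HGNC lookup.
valid_hgnc <- function(sym) {
  !is.na(sym) & sym != "" & sym != "NA" & grepl("^[A-Za-z0-9@_.-]+$", sym)
}

collapse_symbols <- function(mat, sym) {
  keep <- valid_hgnc(sym)
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message(sprintf("load_expression: dropped %d rows with invalid gene symbols", n_drop))
  mat <- mat[keep, , drop = FALSE]
  sym <- sym[keep]
  if (nrow(mat) == 0L) stop2("no rows left after gene-symbol cleanup")
  if (anyDuplicated(sym)) {
    sums <- rowsum(mat, group = sym, reorder = FALSE)
    n <- as.vector(table(factor(sym, levels = rownames(sums))))
    mat <- sums / n
    message(sprintf("load_expression: averaged %d rows into %d shared symbols",
                    sum(n[n > 1L]), sum(n > 1L)))
  } else {
    rownames(mat) <- sym
  }
  mat
}

#' Load a bulk expression matrix
#'
#' Reads a delimited genes x samples table (first column gene symbols, header
#' row sample ids), removes rows with invalid HGNC symbols, averages rows
#' sharing a symbol, and optionally converts scaled abundance estimates
#' (which sum to 1 per sample) to TPM by multiplying by 1e6.
#'
#' @param path path to the TPM (or scaled-abundance) table.
#' @param format `"auto"` infers the delimiter from the file extension
#'   (`.csv` -> comma, otherwise tab).
#' @param counts_path optional path to a matching counts table.
#' @param scaled_to_tpm if `TRUE`, multiply the main table by 1,000,000.
#' @param transpose if `TRUE`, the file is samples x genes and is transposed
#'   after reading.
#' @return A [gene_expr()] object.
#' @export
load_expression <- function(path, format = c("auto", "tsv", "csv"),
                            counts_path = NULL, scaled_to_tpm = FALSE,
                            transpose = FALSE) {
  format <- match.arg(format)
  sep <- switch(format, auto = NULL, tsv = "\t", csv = ",")
  read_one <- function(p) {
    df <- read_table_auto(p, sep = sep)
    if (ncol(df) < 2L) stop2("expression table needs a symbol column plus >= 1 sample: ", p)
    sym <- as.character(df[[1L]])
    mat <- as.matrix(df[, -1L, drop = FALSE])
    if (transpose) { # samples x genes on disk
      mat <- t(mat); colnames(mat) <- sym; sym <- rownames(mat)
    }
    num <- suppressWarnings(array(as.numeric(mat), dim(mat), dimnames(mat)))
    bad <- which(!is.finite(num), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop2(sprintf("non-numeric value in %s at row %d, column %d",
                    p, bad[1L, 1L], bad[1L, 2L] + 1L))
    mat <- num
    collapse_symbols(mat, sym)
  }
  tpm <- read_one(path)
  if (scaled_to_tpm) tpm <- tpm * 1e6
  counts <- NULL
  if (!is.null(counts_path)) {
    counts <- read_one(counts_path)
    shared_g <- intersect(rownames(tpm), rownames(counts))
    shared_s <- intersect(colnames(tpm), colnames(counts))
    tpm <- tpm[shared_g, shared_s, drop = FALSE]
    counts <- counts[shared_g, shared_s, drop = FALSE]
  }
  gene_expr(tpm, counts)
}

#' Write a gene_expr TPM matrix to TSV
#' @param expr a [gene_expr()] object.
#' @param path output file.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "gene_expr"))
  write_tsv(expr$tpm, path, row_label = "gene")
}
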