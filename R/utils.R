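`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
stop2 <- function(...) stop(..., call. = FALSE)

#' @keywords internal
warn2 <- function(...) warning(..., call. = FALSE)

## population standard deviation (n denominator); returns 0 for constant input
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0L) return(0)
  sqrt(sum((x - mean(x))^2) / n)
}

col_pop_sd <- function(m) {
  mu <- colMeans(m)
  sqrt(colMeans(sweep(m, 2L, mu)^2))
}

## FNV-1a over a character scalar, used for provenance hashes (hex string)
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n")) %% 256
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

## derive a per-run seed from a master seed with a counter so that changing
## n_runs never reshuffles earlier runs; kept below 2^31
derive_seed <- function(master, counter) {
  as.integer((as.double(master) %% 2^20) * 1021 + counter * 7919) %% .Machine$integer.max
}

is_binary_labels <- function(x) length(unique(x)) == 2L

read_table_auto <- function(path, sep = NULL, header = TRUE, row_names = NULL) {
  if (!file.exists(path)) stop2("cannot read file: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  utils::read.table(path, sep = sep, header = header, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "",
                    row.names = row_names)
}

write_tsv <- function(x, path, row_label = "id") {
  df <- data.frame(check.names = FALSE, row.names = NULL,
                   stats::setNames(list(rownames(x)), row_label),
                   as.data.frame(x, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
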