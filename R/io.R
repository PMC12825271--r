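# shared TSV helpers: square matrices with region ids as header row/column

write_matrix_tsv <- function(M, path) {
  ids <- rownames(M)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(M)))
  df <- data.frame(region = ids, M, check.names = FALSE)
  colnames(df) <- c("region", ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(M), ids)) {
    stop("matrix TSV header does not match its region column: ", path)
  }
  dimnames(M) <- list(ids, ids)
  M
}
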