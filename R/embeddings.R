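# Input representation contract: one-hot (D = 4) by default, or an adapter
# for precomputed pretrained language-model embeddings (D = 640, one L x 640
# matrix per sequence). The model's projection layer accepts either width.

ONE_HOT_ORDER <- c("A", "C", "G", "U")

#' One-hot embed an RNA sequence
#'
#' Row i is the unit basis vector of residue i in A, C, G, U order; 'N'
#' becomes the uniform vector (0.25 each); padding rows are zero with pad
#' mask FALSE.
#'
#' @param seq an \linkS4class{RnaSequence}.
#' @param pad_to padded row count (>= sequence length; default no padding).
#' @return an \linkS4class{EmbeddingMatrix} with D = 4.
#' @export
oneHotEmbed <- function(seq, pad_to = NULL) {
  L <- seqLength(seq)
  Lp <- if (is.null(pad_to)) L else as.integer(pad_to)
  if (Lp < L) stop(sprintf("pad_to (%d) must be >= sequence length (%d)", Lp, L))
  v <- matrix(0, Lp, 4L, dimnames = list(NULL, ONE_HOT_ORDER))
  chars <- strsplit(residues(seq), "")[[1L]]
  for (k in seq_len(L)) {
    if (chars[k] == "N") v[k, ] <- 0.25
    else v[k, match(chars[k], ONE_HOT_ORDER)] <- 1
  }
  EmbeddingMatrix(v, padMask = seq_len(Lp) <= L)
}

#' Load a cached pretrained embedding matrix
#'
#' Reads one per-residue embedding matrix (whitespace-delimited text, one
#' row per residue, 640 columns — the pretrained RNA language-model output
#' contract) and validates its shape. The pretrained model itself is never
#' invoked; only its file-based output interface is honored.
#'
#' @param path text file holding an L x 640 numeric matrix; lines starting
#'   with '#' are ignored.
#' @param expected_L expected residue count.
#' @param expected_D expected embedding width (default 640).
#' @return an \linkS4class{EmbeddingMatrix} with D = \code{expected_D}.
#' @export
loadCachedEmbedding <- function(path, expected_L, expected_D = 640L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  v <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (nrow(v) != expected_L)
    stop(sprintf("embedding row count mismatch: found %d, expected L=%d",
                 nrow(v), expected_L))
  if (ncol(v) != expected_D)
    stop(sprintf("embedding width mismatch: found %d, expected D=%d",
                 ncol(v), expected_D))
  EmbeddingMatrix(v)
}

#' @param emb an \linkS4class{EmbeddingMatrix} to write.
#' @rdname loadCachedEmbedding
#' @export
writeCachedEmbedding <- function(emb, path) {
  v <- emb@values[emb@padMask, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# L=%d D=%d", nrow(v), ncol(v)), con)
  utils::write.table(format(v, digits = 8, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
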