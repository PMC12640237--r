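# Readers/writers for FASTA, dot-bracket, CT, BPSEQ and probability
# matrices. Internal coordinates are 0-based; CT/BPSEQ are 1-based on disk
# and converted at this boundary only.

DB_OPEN  <- c("(", "[", "{", "<")
DB_CLOSE <- c(")", "]", "}", ">")

#' Read RNA sequences from a FASTA file
#'
#' Sequences are uppercased and T is mapped to U; any residue outside
#' A/C/G/U/N is an error naming the offending character. Record order is
#' preserved.
#'
#' @param path FASTA file path.
#' @return list of \linkS4class{RnaSequence}.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop(sprintf("empty FASTA file: %s", path))
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop(sprintf("malformed FASTA: line %d does not start a record ('>')",
                 nonblank[1L]))
  out <- list()
  id <- NULL; buf <- character(0); startLine <- NA_integer_
  flush <- function() {
    if (is.null(id)) return()
    if (length(buf) == 0L)
      stop(sprintf("malformed FASTA: empty record '%s' at line %d",
                   id, startLine))
    out[[length(out) + 1L]] <<- RnaSequence(id, paste(buf, collapse = ""))
  }
  for (k in nonblank) {
    ln <- trimws(lines[k])
    if (startsWith(ln, ">")) {
      flush()
      id <- trimws(sub("^>", "", ln))
      if (!nzchar(id))
        stop(sprintf("malformed FASTA: empty header at line %d", k))
      id <- strsplit(id, "\\s+")[[1L]][1L]
      buf <- character(0); startLine <- k
    } else {
      buf <- c(buf, ln)
    }
  }
  flush()
  out
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs list of \linkS4class{RnaSequence} (or a single one).
#' @param path output path.
#' @param width line wrap width.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
  if (is(seqs, "RnaSequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", seqId(s)), con)
    res <- residues(s)
    starts <- seq(1L, nchar(res), by = width)
    writeLines(substring(res, starts, pmin(starts + width - 1L, nchar(res))), con)
  }
  invisible(path)
}

#' Parse dot-bracket notation
#'
#' Supports four bracket tiers \code{() [] {} <>}; distinct tiers may cross,
#' encoding pseudoknots. Each tier is matched with its own stack.
#'
#' @param db dot-bracket string over \code{. ( ) [ ] { } < >}.
#' @return a \linkS4class{SecondaryStructure}.
#' @export
parseDotBracket <- function(db) {
  chars <- strsplit(db, "")[[1L]]
  L <- length(chars)
  if (L == 0L) stop("empty dot-bracket string")
  allowed <- c(".", DB_OPEN, DB_CLOSE)
  bad <- which(!chars %in% allowed)
  if (length(bad) > 0L)
    stop(sprintf("invalid dot-bracket character '%s' at position %d",
                 chars[bad[1L]], bad[1L] - 1L))
  pairs <- list()
  for (tier in seq_along(DB_OPEN)) {
    stack <- integer(0)
    for (k in seq_len(L)) {
      if (chars[k] == DB_OPEN[tier]) {
        stack <- c(stack, k)
      } else if (chars[k] == DB_CLOSE[tier]) {
        if (length(stack) == 0L)
          stop(sprintf("unbalanced tier %d ('%s%s'): unmatched '%s' at position %d",
                       tier, DB_OPEN[tier], DB_CLOSE[tier], DB_CLOSE[tier], k - 1L))
        i <- stack[length(stack)]
        stack <- stack[-length(stack)]
        pairs[[length(pairs) + 1L]] <- c(i - 1L, k - 1L)
      }
    }
    if (length(stack) > 0L)
      stop(sprintf("unbalanced tier %d ('%s%s'): unmatched '%s' at position %d",
                   tier, DB_OPEN[tier], DB_CLOSE[tier], DB_OPEN[tier],
                   stack[length(stack)] - 1L))
  }
  SecondaryStructure(L, do.call(rbind, pairs))
}

#' Write a structure in dot-bracket notation
#'
#' Pairs are assigned greedily to the lowest bracket tier on which they do
#' not cross an already-placed pair, so nested structures use plain
#' parentheses and pseudoknots spill into \code{[] {} <>}.
#'
#' @param s a \linkS4class{SecondaryStructure}.
#' @return dot-bracket string; \code{parseDotBracket} of the result
#'   recovers the same pair set.
#' @export
writeDotBracket <- function(s) {
  L <- seqLength(s)
  chars <- rep(".", L)
  p <- basePairs(s)
  if (nrow(p) > 0L) {
    tiers <- vector("list", length(DB_OPEN))
    for (r in seq_len(nrow(p))) {
      i <- p[r, 1L]; j <- p[r, 2L]
      placed <- FALSE
      for (tier in seq_along(DB_OPEN)) {
        crosses <- FALSE
        tp <- tiers[[tier]]
        if (!is.null(tp) && nrow(tp) > 0L) {
          k <- tp[, 1L]; l <- tp[, 2L]
          crosses <- any((i < k & k < j & j < l) | (k < i & i < l & l < j))
        }
        if (!crosses) {
          tiers[[tier]] <- rbind(tp, c(i, j))
          chars[i + 1L] <- DB_OPEN[tier]
          chars[j + 1L] <- DB_CLOSE[tier]
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("structure requires more than %d bracket tiers",
                     length(DB_OPEN)))
    }
  }
  paste(chars, collapse = "")
}

#' Read/write CT files
#'
#' CT is 1-based and six-column: index, base, predecessor, successor,
#' partner (0 = unpaired), index again. The header line carries the length
#' and a title. Reciprocal partner entries are validated.
#'
#' @param path CT file path.
#' @return list with elements \code{sequence} (\linkS4class{RnaSequence})
#'   and \code{structure} (\linkS4class{SecondaryStructure}).
#' @export
readCt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop(sprintf("malformed CT file: %s", path))
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  L <- suppressWarnings(as.integer(hdr[1L]))
  if (is.na(L) || L < 1L) stop("malformed CT header: first field must be the length")
  title <- if (length(hdr) > 1L) paste(hdr[-1L], collapse = " ") else "ct"
  if (length(lines) - 1L != L)
    stop(sprintf("CT row count %d does not match header length %d",
                 length(lines) - 1L, L))
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  base <- vapply(rows, `[`, character(1), 2L)
  partner <- as.integer(vapply(rows, `[`, character(1), 5L))
  structureFromPartners(L, partner, base, title)
}

#' @param x list with \code{sequence} and \code{structure} (as returned by
#'   \code{readCt}), or a \linkS4class{SecondaryStructure} plus \code{seq}.
#' @rdname readCt
#' @export
writeCt <- function(x, path) {
  s <- x$structure; rna <- x$sequence
  L <- seqLength(s)
  partner <- partnerVector(s)
  base <- strsplit(residues(rna), "")[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %s", L, seqId(rna)), con)
  idx <- seq_len(L)
  writeLines(sprintf("%d %s %d %d %d %d", idx, base, idx - 1L,
                     ifelse(idx == L, 0L, idx + 1L), partner, idx), con)
  invisible(path)
}

#' Read/write BPSEQ files
#'
#' BPSEQ is 1-based and three-column: index, base, partner (0 = unpaired).
#' Lines starting with '#' are ignored. Reciprocal partner entries are
#' validated.
#'
#' @param path BPSEQ file path.
#' @param id identifier given to the sequence read from a BPSEQ file.
#' @return as \code{\link{readCt}}.
#' @export
readBpseq <- function(path, id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop(sprintf("empty BPSEQ file: %s", path))
  rows <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(rows) < 3L)) stop("malformed BPSEQ: expected 3 columns")
  idx <- as.integer(vapply(rows, `[`, character(1), 1L))
  if (!identical(idx, seq_along(idx)))
    stop("malformed BPSEQ: indices must run 1..L")
  base <- vapply(rows, `[`, character(1), 2L)
  partner <- as.integer(vapply(rows, `[`, character(1), 3L))
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  structureFromPartners(length(idx), partner, base, id)
}

#' @rdname readBpseq
#' @export
writeBpseq <- function(x, path) {
  s <- x$structure; rna <- x$sequence
  L <- seqLength(s)
  partner <- partnerVector(s)
  base <- strsplit(residues(rna), "")[[1L]]
  writeLines(sprintf("%d %s %d", seq_len(L), base, partner), path)
  invisible(path)
}

# shared: build (sequence, structure) from a 1-based partner vector
structureFromPartners <- function(L, partner, base, id) {
  if (any(is.na(partner)) || any(partner < 0L) || any(partner > L))
    stop("partner indices must lie in [0, L]")
  idx <- seq_len(L)
  paired <- which(partner > 0L)
  for (i in paired) {
    j <- partner[i]
    if (partner[j] != i)
      stop(sprintf(
        "inconsistent reciprocal partners: position %d pairs %d but %d pairs %d",
        i, j, j, partner[j]))
    if (j == i) stop(sprintf("self-pair at position %d", i))
  }
  sel <- paired[partner[paired] > paired]
  pairs <- if (length(sel)) cbind(sel - 1L, partner[sel] - 1L) else NULL
  list(sequence = RnaSequence(id, paste(base, collapse = "")),
       structure = SecondaryStructure(L, pairs))
}

partnerVector <- function(s) {
  partner <- integer(seqLength(s))
  p <- basePairs(s)
  if (nrow(p) > 0L) {
    partner[p[, 1L] + 1L] <- p[, 2L] + 1L
    partner[p[, 2L] + 1L] <- p[, 1L] + 1L
  }
  partner
}

#' Read/write probability matrices as whitespace-delimited text
#'
#' One row per line; a leading comment line records L and the channel.
#'
#' @param m a \linkS4class{PairProbabilityMatrix}; \code{path} a file path.
#' @param path file path.
#' @return the matrix (read) or \code{path} invisibly (write).
#' @export
writeProbabilityMatrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- probValues(m)
  writeLines(sprintf("# L=%d channel=%s", nrow(v), channel(m)), con)
  utils::write.table(format(v, digits = 10, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeProbabilityMatrix
#' @export
readProbabilityMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop(sprintf("empty matrix file: %s", path))
  ch <- "foreground"
  if (startsWith(lines[1L], "#")) {
    mch <- regmatches(lines[1L], regexec("channel=(\\w+)", lines[1L]))[[1L]]
    if (length(mch) == 2L) ch <- mch[2L]
    lines <- lines[-1L]
  }
  v <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  PairProbabilityMatrix(v, channel = ch)
}
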