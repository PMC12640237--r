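#' @import methods
NULL

RNA_ALPHABET <- c("A", "C", "G", "U", "N")

#' RnaSequence: an RNA sequence with an identifier
#'
#' Holds one RNA sequence over the alphabet A/C/G/U/N. Constructors normalize
#' case and map DNA-style T to U; any other character is rejected.
#'
#' @slot id character(1) sequence identifier.
#' @slot residues character(1) residue string over {A,C,G,U,N}.
#'
#' @examples
#' s <- RnaSequence("ex1", "acgt")
#' residues(s)   # "ACGU"
#' seqLength(s)  # 4
#' @export
setClass("RnaSequence",
  representation(id = "character", residues = "character"))

setValidity("RnaSequence", function(object) {
  if (length(object@id) != 1L) return("'id' must be a single string")
  if (length(object@residues) != 1L) return("'residues' must be a single string")
  if (nchar(object@residues) < 1L) return("sequence must have length >= 1")
  chars <- strsplit(object@residues, "")[[1]]
  bad <- setdiff(unique(chars), RNA_ALPHABET)
  if (length(bad) > 0L)
    return(sprintf("invalid residue character(s): %s", paste(bad, collapse = ", ")))
  TRUE
})

#' @param id character(1) identifier.
#' @param residues character(1) residue string; lowercase and 'T' are
#'   normalized, anything outside A/C/G/U/N/T is an error.
#' @rdname RnaSequence-class
#' @export
RnaSequence <- function(id, residues) {
  res <- normalizeResidues(residues)
  new("RnaSequence", id = as.character(id), residues = res)
}

normalizeResidues <- function(residues) {
  res <- chartr("t", "u", toupper(as.character(residues)))
  res <- chartr("T", "U", res)
  chars <- strsplit(res, "")[[1]]
  bad <- setdiff(unique(chars), RNA_ALPHABET)
  if (length(bad) > 0L)
    stop(sprintf("invalid residue character(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  res
}

#' SecondaryStructure: a set of base pairs
#'
#' A secondary structure over a sequence of length L is a matching on
#' positions 0..L-1: a set of pairs (i, j), i < j, in which no position
#' occurs twice. Crossing pairs (pseudoknots) are permitted; no nesting
#' constraint is imposed by the class.
#'
#' @slot L integer(1) sequence length.
#' @slot pairs integer matrix with two columns (i, j), 0-based, i < j,
#'   rows sorted by (i, j).
#'
#' @examples
#' ss <- SecondaryStructure(6, rbind(c(0, 5), c(1, 4)))
#' nPairs(ss)
#' writeDotBracket(ss)  # "((..))"
#' @export
setClass("SecondaryStructure",
  representation(L = "integer", pairs = "matrix"))

setValidity("SecondaryStructure", function(object) {
  if (length(object@L) != 1L || is.na(object@L) || object@L < 1L)
    return("'L' must be a positive integer")
  p <- object@pairs
  if (!is.numeric(p) || ncol(p) != 2L)
    return("'pairs' must be a two-column integer matrix")
  if (nrow(p) == 0L) return(TRUE)
  if (any(p < 0L) || any(p >= object@L))
    return("pair indices must lie in [0, L)")
  if (any(p[, 1L] >= p[, 2L]))
    return("each pair must satisfy i < j (no self-pairs)")
  idx <- c(p[, 1L], p[, 2L])
  if (anyDuplicated(idx))
    return("matching property violated: an index occurs in more than one pair")
  TRUE
})

#' @param L integer(1) sequence length.
#' @param pairs two-column matrix (or NULL for no pairs) of 0-based (i, j).
#' @rdname SecondaryStructure-class
#' @export
SecondaryStructure <- function(L, pairs = NULL) {
  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0L) ||
      length(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    # canonical order: i < j within a pair, rows sorted by (i, j)
    swap <- pairs[, 1L] > pairs[, 2L]
    if (any(swap)) pairs[swap, ] <- pairs[swap, c(2L, 1L)]
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  }
  storage.mode(pairs) <- "integer"
  new("SecondaryStructure", L = as.integer(L), pairs = pairs)
}

#' PairProbabilityMatrix: symmetric L x L pairing probabilities
#'
#' Model output for one sequence and one channel: entry (i, j) is the
#' probability that positions i and j pair. Symmetric, zero diagonal,
#' entries in [0, 1]. Two channels exist: "foreground" (the pairing
#' signal) and "background" (the null contrast used by the log-odds
#' score).
#'
#' @slot values numeric L x L matrix.
#' @slot channel character(1), "foreground" or "background".
#' @export
setClass("PairProbabilityMatrix",
  representation(values = "matrix", channel = "character"))

setValidity("PairProbabilityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (!object@channel %in% c("foreground", "background"))
    return("channel must be 'foreground' or 'background'")
  if (any(v < 0 | v > 1)) return("entries must lie in [0, 1]")
  if (any(abs(diag(v)) > 0)) return("diagonal must be zero")
  if (max(abs(v - t(v))) > 1e-8) return("matrix must be symmetric")
  TRUE
})

#' @param values numeric square matrix in [0,1], symmetric, zero diagonal.
#' @param channel "foreground" or "background".
#' @rdname PairProbabilityMatrix-class
#' @export
PairProbabilityMatrix <- function(values, channel = "foreground") {
  new("PairProbabilityMatrix", values = as.matrix(values), channel = channel)
}

#' TargetMatrix: binary supervision matrix with a validity mask
#'
#' The reconstruction target for one (possibly padded) sequence: a binary
#' symmetric matrix marking true base pairs, plus a logical mask that is
#' TRUE exactly on the valid (non-padded) submatrix.
#'
#' @slot values numeric L x L matrix of 0/1.
#' @slot mask logical L x L matrix.
#' @export
setClass("TargetMatrix",
  representation(values = "matrix", mask = "matrix"))

setValidity("TargetMatrix", function(object) {
  v <- object@values; m <- object@mask
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (!identical(dim(v), dim(m))) return("mask shape must equal values shape")
  if (!all(v %in% c(0, 1))) return("values must be binary")
  if (any(diag(v) != 0)) return("diagonal must be zero")
  if (max(abs(v - t(v))) > 0) return("matrix must be symmetric")
  TRUE
})

#' @param values binary symmetric matrix.
#' @param mask logical matrix (default all TRUE).
#' @rdname TargetMatrix-class
#' @export
TargetMatrix <- function(values, mask = NULL) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  new("TargetMatrix", values = values, mask = mask)
}

#' EmbeddingMatrix: per-residue input representation
#'
#' Rows are residues (possibly padded), columns are embedding channels:
#' D = 4 for one-hot input, D = 640 for the pretrained language-model
#' adapter. Padding rows are all-zero with pad mask FALSE.
#'
#' @slot values numeric L_pad x D matrix.
#' @slot padMask logical vector, TRUE for real residues.
#' @export
setClass("EmbeddingMatrix",
  representation(values = "matrix", padMask = "logical"))

setValidity("EmbeddingMatrix", function(object) {
  if (nrow(object@values) != length(object@padMask))
    return("padMask length must equal row count")
  if (any(!object@padMask)) {
    padRows <- object@values[!object@padMask, , drop = FALSE]
    if (any(padRows != 0)) return("masked-out rows must be all-zero")
  }
  TRUE
})

#' @param values numeric matrix.
#' @param padMask logical vector (default all TRUE).
#' @rdname EmbeddingMatrix-class
#' @export
EmbeddingMatrix <- function(values, padMask = NULL) {
  values <- as.matrix(values)
  if (is.null(padMask)) padMask <- rep(TRUE, nrow(values))
  new("EmbeddingMatrix", values = values, padMask = padMask)
}

#' StructureEnsemble: K sampled structures for one sequence
#'
#' @slot structures list of SecondaryStructure objects of equal length L.
#' @slot seed integer(1) seed provenance of the sampling run.
#' @export
setClass("StructureEnsemble",
  representation(structures = "list", seed = "integer"))

setValidity("StructureEnsemble", function(object) {
  if (length(object@structures) < 1L) return("ensemble needs K >= 1 structures")
  if (!all(vapply(object@structures, is, logical(1), "SecondaryStructure")))
    return("all members must be SecondaryStructure objects")
  Ls <- vapply(object@structures, function(s) s@L, integer(1))
  if (length(unique(Ls)) != 1L) return("all members must share one length L")
  TRUE
})

#' @param structures list of SecondaryStructure objects.
#' @param seed integer seed used to draw them (provenance only).
#' @rdname StructureEnsemble-class
#' @export
StructureEnsemble <- function(structures, seed = NA_integer_) {
  new("StructureEnsemble", structures = structures, seed = as.integer(seed))
}

#' TvaeModel: transformer variational autoencoder for base pairing
#'
#' Container for the model configuration, the parameter list (plain numeric
#' matrices/vectors), and a training-step counter. Create with
#' \code{\link{tvaeModel}}.
#'
#' @slot config list, see \code{\link{modelConfig}}.
#' @slot params named list of parameter arrays.
#' @slot step integer(1) training steps taken.
#' @export
setClass("TvaeModel",
  representation(config = "list", params = "list", step = "integer"))
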