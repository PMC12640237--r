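#' Detect crossing (pseudoknotted) pairs
#'
#' Two pairs (i, j) and (k, l) cross when i < k < j < l. A structure with at
#' least one crossing pair is pseudoknotted and cannot be written on a single
#' bracket tier.
#'
#' @param s a \linkS4class{SecondaryStructure}.
#' @return logical(1).
#' @export
hasCrossing <- function(s) {
  p <- basePairs(s)
  n <- nrow(p)
  if (n < 2L) return(FALSE)
  for (a in seq_len(n - 1L)) {
    i <- p[a, 1L]; j <- p[a, 2L]
    k <- p[(a + 1L):n, 1L]; l <- p[(a + 1L):n, 2L]
    if (any((i < k & k < j & j < l) | (k < i & i < l & l < j))) return(TRUE)
  }
  FALSE
}

#' Convert a structure to a binary target matrix
#'
#' @param s a \linkS4class{SecondaryStructure}.
#' @param pad_to optional padded size (>= L); padding is masked out.
#' @return a \linkS4class{TargetMatrix} with 1 at (i, j) and (j, i) for every
#'   pair, 0 elsewhere, and a mask covering the valid L x L block.
#' @export
structureToMatrix <- function(s, pad_to = NULL) {
  L <- seqLength(s)
  Lp <- if (is.null(pad_to)) L else as.integer(pad_to)
  if (Lp < L) stop("pad_to must be >= L")
  v <- matrix(0, Lp, Lp)
  p <- basePairs(s)
  if (nrow(p) > 0L) {
    v[cbind(p[, 1L] + 1L, p[, 2L] + 1L)] <- 1
    v[cbind(p[, 2L] + 1L, p[, 1L] + 1L)] <- 1
  }
  m <- matrix(FALSE, Lp, Lp)
  m[seq_len(L), seq_len(L)] <- TRUE
  TargetMatrix(v, m)
}

#' Recover a structure from a binary pairing matrix
#'
#' Inverse of \code{\link{structureToMatrix}} on the unmasked block.
#'
#' @param tm a \linkS4class{TargetMatrix}.
#' @return a \linkS4class{SecondaryStructure}.
#' @export
matrixToStructure <- function(tm) {
  valid <- which(apply(tm@mask, 1L, any))
  L <- length(valid)
  v <- tm@values[valid, valid, drop = FALSE]
  idx <- which(v == 1 & upper.tri(v), arr.ind = TRUE)
  SecondaryStructure(L, cbind(idx[, 1L] - 1L, idx[, 2L] - 1L))
}

#' Base-pair distance between two structures
#'
#' The cardinality of the symmetric difference of the two pair sets: the
#' number of pairs present in exactly one structure. A true metric on
#' structures of one sequence (zero iff equal, symmetric, triangle
#' inequality).
#'
#' @param a,b \linkS4class{SecondaryStructure} objects of equal length.
#' @return nonnegative integer.
#' @export
basePairDistance <- function(a, b) {
  if (seqLength(a) != seqLength(b))
    stop(sprintf("length mismatch: %d vs %d", seqLength(a), seqLength(b)))
  ka <- pairKeys(a); kb <- pairKeys(b)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

pairKeys <- function(s) {
  p <- basePairs(s)
  if (nrow(p) == 0L) return(integer(0))
  p[, 1L] * s@L + p[, 2L]
}

#' Compare a predicted structure with a reference
#'
#' Exact pair matching (no shift tolerance): a predicted pair counts as a
#' true positive only when the identical (i, j) occurs in the reference.
#' Precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2 * precision * recall / (precision + recall). Empty denominators
#' give 0, except that two empty structures compare as perfect agreement
#' (all three metrics 1).
#'
#' @param pred,ref \linkS4class{SecondaryStructure} objects of equal length.
#' @return list with tp, fp, fn, precision, recall, f1.
#' @export
evaluateStructure <- function(pred, ref) {
  if (seqLength(pred) != seqLength(ref))
    stop(sprintf("length mismatch: %d vs %d", seqLength(pred), seqLength(ref)))
  kp <- pairKeys(pred); kr <- pairKeys(ref)
  tp <- length(intersect(kp, kr))
  fp <- length(kp) - tp
  fn <- length(kr) - tp
  if (length(kp) == 0L && length(kr) == 0L) {
    prec <- rec <- f1 <- 1
  } else {
    prec <- if (tp + fp > 0L) tp / (tp + fp) else 0
    rec  <- if (tp + fn > 0L) tp / (tp + fn) else 0
    f1   <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1)
}
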