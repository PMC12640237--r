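# Discretization of probability matrices into base pairs: a log-odds
# score contrasting the foreground channel against a background channel,
# candidate enumeration under Watson-Crick/wobble and minimum-loop
# constraints, and a greedy maximum-weight matching pass (sort once,
# accept a pair when both ends are free), O(n^2 log n) in the sort.
# An exhaustive maximum-weight matching oracle is included for testing.

#' Biological pairing constraints
#'
#' @param allowed_pairs character vector of residue couples accepted as
#'   pairs (default Watson-Crick + G-U wobble, both orientations).
#' @param min_loop minimum unpaired residues between partners (default 3,
#'   i.e. j - i >= 4): the steric hairpin-loop minimum.
#' @param allow_crossing permit crossing pairs (pseudoknots) in the
#'   greedy assignment (default TRUE).
#' @param phi score penalty discouraging weak or spurious pairings; acts
#'   as the acceptance threshold since only positive scores become
#'   candidates.
#' @param epsilon probability clamp keeping the log-odds finite.
#' @return list of class \code{pairingConstraints}.
#' @export
pairingConstraints <- function(allowed_pairs = c("AU", "UA", "GC", "CG",
                                                 "GU", "UG"),
                               min_loop = 3L, allow_crossing = TRUE,
                               phi = 0, epsilon = 1e-6) {
  stopifnot(min_loop >= 0L, epsilon > 0, epsilon < 0.5)
  structure(list(allowed_pairs = allowed_pairs,
                 min_loop = as.integer(min_loop),
                 allow_crossing = allow_crossing,
                 phi = phi, epsilon = epsilon),
            class = "pairingConstraints")
}

#' Log-odds score matrix
#'
#' S_ij = log(P_fg/P_bg) + log((1 - P_bg)/(1 - P_fg)) - phi, natural
#' logarithm, with both channels clamped into [epsilon, 1 - epsilon]
#' first. Equal channels give S = -phi everywhere; the score contrasts
#' pair-on odds against pair-off odds.
#'
#' @param fg,bg \linkS4class{PairProbabilityMatrix} objects (foreground
#'   and background) of equal size, or plain matrices.
#' @param constraints a \code{\link{pairingConstraints}} (phi, epsilon).
#' @return numeric L x L score matrix.
#' @export
scoreMatrix <- function(fg, bg, constraints = pairingConstraints()) {
  pf <- if (is(fg, "PairProbabilityMatrix")) probValues(fg) else fg
  pb <- if (is(bg, "PairProbabilityMatrix")) probValues(bg) else bg
  if (!identical(dim(pf), dim(pb)))
    stop(sprintf("shape mismatch: foreground %dx%d vs background %dx%d",
                 nrow(pf), ncol(pf), nrow(pb), ncol(pb)))
  eps <- constraints$epsilon
  pf <- pmin(pmax(pf, eps), 1 - eps)
  pb <- pmin(pmax(pb, eps), 1 - eps)
  log(pf / pb) + log((1 - pb) / (1 - pf)) - constraints$phi
}

#' Enumerate valid candidate pairs in score order
#'
#' A candidate is a pair (i, j), i < j, whose residues form an allowed
#' couple, with at least \code{min_loop} unpaired positions between them
#' (j - i - 1 >= min_loop) and strictly positive score. Sorted by score
#' descending; ties broken by (i ascending, j ascending) so the greedy
#' result is permutation-invariant.
#'
#' @param seq an \linkS4class{RnaSequence}.
#' @param S score matrix from \code{\link{scoreMatrix}}.
#' @param constraints a \code{\link{pairingConstraints}}.
#' @return data.frame with 0-based columns i, j and score.
#' @export
candidatePairs <- function(seq, S, constraints = pairingConstraints()) {
  L <- seqLength(seq)
  if (nrow(S) != L)
    stop(sprintf("score matrix size %d does not match sequence length %d",
                 nrow(S), L))
  chars <- strsplit(residues(seq), "")[[1L]]
  idx <- which(upper.tri(S), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  keep <- (j - i - 1L) >= constraints$min_loop &
    paste0(chars[i], chars[j]) %in% constraints$allowed_pairs &
    S[idx] > 0
  i <- i[keep]; j <- j[keep]; sc <- S[idx][keep]
  ord <- order(-sc, i, j)
  data.frame(i = i[ord] - 1L, j = j[ord] - 1L, score = sc[ord])
}

#' Greedy matching over sorted candidates
#'
#' One pass from the highest score down: a candidate is accepted iff both
#' endpoints are still unpaired (and, when \code{allow_crossing} is
#' FALSE, iff it crosses no accepted pair). The result always satisfies
#' the matching property and carries at least half the weight of the
#' exact maximum-weight matching.
#'
#' @param cands data.frame from \code{\link{candidatePairs}} (i, j, score;
#'   already sorted).
#' @param L sequence length.
#' @param allow_crossing permit pseudoknots.
#' @return a \linkS4class{SecondaryStructure}.
#' @export
greedyAssign <- function(cands, L, allow_crossing = TRUE) {
  paired <- logical(L)
  acc <- matrix(integer(0), ncol = 2L)
  if (nrow(cands) > 0L) {
    for (r in seq_len(nrow(cands))) {
      i <- cands$i[r]; j <- cands$j[r]
      if (paired[i + 1L] || paired[j + 1L]) next
      if (!allow_crossing && nrow(acc) > 0L) {
        k <- acc[, 1L]; l <- acc[, 2L]
        if (any((i < k & k < j & j < l) | (k < i & i < l & l < j))) next
      }
      acc <- rbind(acc, c(i, j))
      paired[i + 1L] <- TRUE
      paired[j + 1L] <- TRUE
    }
  }
  SecondaryStructure(L, acc)
}

#' Exact maximum-weight matching oracle (test support)
#'
#' Exhaustively enumerates all matchings over the candidate list (branch
#' on "use the first remaining candidate or not") and returns one of
#' maximum total score. Base pairing is a general (non-bipartite)
#' matching, so enumeration at small size is the reference, not an
#' assignment-problem solver.
#'
#' @param cands data.frame with columns i, j, score.
#' @param L sequence length.
#' @param max_candidates guard: instances above this size are refused.
#' @return a \linkS4class{SecondaryStructure}.
#' @export
exactMatchingOracle <- function(cands, L, max_candidates = 22L) {
  n <- nrow(cands)
  if (n > max_candidates)
    stop(sprintf(
      "instance too large for exhaustive matching (%d > %d candidates)",
      n, max_candidates))
  if (n == 0L) return(SecondaryStructure(L, NULL))
  best <- list(weight = 0, rows = integer(0))
  recur <- function(r, paired, weight, rows, remaining) {
    # prune: even taking every remaining candidate cannot beat the best
    if (weight + remaining <= best$weight) return()
    if (r > n) {
      if (weight > best$weight) best <<- list(weight = weight, rows = rows)
      return()
    }
    i <- cands$i[r] + 1L; j <- cands$j[r] + 1L
    rem <- remaining - max(cands$score[r], 0)
    if (!paired[i] && !paired[j]) {
      paired[c(i, j)] <- TRUE
      recur(r + 1L, paired, weight + cands$score[r], c(rows, r), rem)
      paired[c(i, j)] <- FALSE
    }
    recur(r + 1L, paired, weight, rows, rem)
  }
  recur(1L, logical(L), 0, integer(0), sum(pmax(cands$score, 0)))
  SecondaryStructure(L, cbind(cands$i[best$rows], cands$j[best$rows]))
}

#' Matching total weight under a candidate score table
#'
#' @param s a \linkS4class{SecondaryStructure}.
#' @param cands data.frame with i, j, score.
#' @return sum of scores of the structure's pairs found in \code{cands}.
#' @export
matchingWeight <- function(s, cands) {
  p <- basePairs(s)
  if (nrow(p) == 0L) return(0)
  key <- paste(p[, 1L], p[, 2L])
  ckey <- paste(cands$i, cands$j)
  sum(cands$score[match(key, ckey)], na.rm = TRUE)
}

#' Probability matrices to a discrete structure
#'
#' The full discretization pipeline: score matrix, candidate enumeration,
#' greedy assignment.
#'
#' @param seq an \linkS4class{RnaSequence}.
#' @param fg foreground \linkS4class{PairProbabilityMatrix}.
#' @param bg background matrix, or a scalar in (0, 1) used as a constant
#'   background (default the model-emitted channel when given, else 0.5).
#' @param constraints a \code{\link{pairingConstraints}}.
#' @return a \linkS4class{SecondaryStructure}.
#' @export
pairFromProbabilities <- function(seq, fg, bg = 0.5,
                                  constraints = pairingConstraints()) {
  pf <- if (is(fg, "PairProbabilityMatrix")) probValues(fg) else fg
  if (is.numeric(bg) && length(bg) == 1L) {
    bgm <- matrix(bg, nrow(pf), ncol(pf))
    diag(bgm) <- 0
  } else {
    bgm <- if (is(bg, "PairProbabilityMatrix")) probValues(bg) else bg
  }
  S <- scoreMatrix(pf, bgm, constraints)
  cands <- candidatePairs(seq, S, constraints)
  greedyAssign(cands, seqLength(seq), constraints$allow_crossing)
}
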