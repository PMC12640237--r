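# Ensemble sampling and diversity summaries. From K sampled structures:
# empirical pairing frequencies P_ij, per-position partner-distribution
# entropy H_i (bits, the unpaired outcome included), global entropy
# (mean of H_i), and PSDI (mean base-pair distance over all unordered
# sample pairs). Plus windowed prediction with probability stitching for
# sequences longer than the model's window.

#' Summarize a structure ensemble
#'
#' For each position i the partner distribution across the K samples is
#' {P_ij over partners j} plus the unpaired frequency; H_i is its Shannon
#' entropy in bits (0 log 0 := 0), H_global the mean of H_i, and PSDI the
#' mean symmetric-difference cardinality between the pair sets of all
#' K(K-1)/2 unordered sample pairs.
#'
#' @param e a \linkS4class{StructureEnsemble}.
#' @param require_psdi error when K = 1 and PSDI is requested (PSDI is
#'   undefined for a single sample; it is NA when FALSE).
#' @return list: \code{pair_freq} (L x L), \code{unpaired_freq} (length
#'   L), \code{H} (length L, bits), \code{H_global}, \code{psdi}, \code{K}.
#' @export
summarizeEnsemble <- function(e, require_psdi = FALSE) {
  K <- length(e@structures)
  L <- e@structures[[1L]]@L
  if (K == 1L && require_psdi)
    stop("PSDI is undefined for K = 1 (need at least two samples)")
  pairFreq <- matrix(0, L, L)
  for (s in e@structures) {
    p <- basePairs(s)
    if (nrow(p) > 0L) {
      pairFreq[cbind(p[, 1L] + 1L, p[, 2L] + 1L)] <-
        pairFreq[cbind(p[, 1L] + 1L, p[, 2L] + 1L)] + 1
      pairFreq[cbind(p[, 2L] + 1L, p[, 1L] + 1L)] <-
        pairFreq[cbind(p[, 2L] + 1L, p[, 1L] + 1L)] + 1
    }
  }
  pairFreq <- pairFreq / K
  unpairedFreq <- 1 - rowSums(pairFreq)
  H <- vapply(seq_len(L), function(i) {
    p <- c(pairFreq[i, ], unpairedFreq[i])
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  psdi <- NA_real_
  if (K >= 2L) {
    keys <- lapply(e@structures, pairKeys)
    tot <- 0
    for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
      tot <- tot + length(setdiff(keys[[a]], keys[[b]])) +
        length(setdiff(keys[[b]], keys[[a]]))
    }
    psdi <- tot / (K * (K - 1L) / 2L)
  }
  list(pair_freq = pairFreq, unpaired_freq = unpairedFreq, H = H,
       H_global = mean(H), psdi = psdi, K = K)
}

#' Windowed prediction with probability stitching
#'
#' Partitions a long sequence into overlapping windows (starts every
#' window - overlap positions), predicts each window's probability
#' matrices, embeds them at their global offsets and averages entries
#' covered by more than one window. Pairs spanning farther than a single
#' window receive probability 0 (a documented limitation of windowing).
#' For L <= window the output is identical to direct prediction.
#'
#' @param model a \linkS4class{TvaeModel}.
#' @param seq an \linkS4class{RnaSequence}.
#' @param window window length (default 512).
#' @param overlap overlap between consecutive windows (default 128; must
#'   be < window).
#' @return list(fg=, bg=) of \linkS4class{PairProbabilityMatrix}.
#' @export
segmentedPredict <- function(model, seq, window = 512L, overlap = 128L) {
  if (overlap >= window) stop("overlap must be smaller than window")
  L <- seqLength(seq)
  if (L <= window) return(predictMap(model, seq))
  stride <- window - overlap
  starts <- seq(0L, L - 1L, by = stride)
  # a start is needed only while the preceding window falls short of L
  if (length(starts) > 1L)
    starts <- starts[c(TRUE, (starts[-length(starts)] + window) < L)]
  accFg <- matrix(0, L, L); accBg <- matrix(0, L, L)
  count <- matrix(0, L, L)
  res <- residues(seq)
  for (s0 in starts) {
    s1 <- min(s0 + window, L)
    sub <- RnaSequence(sprintf("%s_w%d", seqId(seq), s0),
                       substr(res, s0 + 1L, s1))
    pm <- predictMap(model, sub)
    rng <- (s0 + 1L):s1
    accFg[rng, rng] <- accFg[rng, rng] + probValues(pm$fg)
    accBg[rng, rng] <- accBg[rng, rng] + probValues(pm$bg)
    count[rng, rng] <- count[rng, rng] + 1
  }
  covered <- count > 0
  accFg[covered] <- accFg[covered] / count[covered]
  accBg[covered] <- accBg[covered] / count[covered]
  # uncovered (cross-window) entries stay 0; background gets the 0.5 null
  accBg[!covered] <- 0.5
  diag(accFg) <- 0; diag(accBg) <- 0
  list(fg = PairProbabilityMatrix(symmetrize(accFg), "foreground"),
       bg = PairProbabilityMatrix(symmetrize(accBg), "background"))
}

#' Full ensemble pipeline for one sequence
#'
#' Draws K latent samples, discretizes each probability matrix with the
#' greedy log-odds matcher, summarizes ensemble diversity, and returns
#' the deterministic consensus (the structure decoded from the eps = 0
#' point prediction).
#'
#' @param model a \linkS4class{TvaeModel}.
#' @param seq an \linkS4class{RnaSequence} (or
#'   \linkS4class{EmbeddingMatrix}).
#' @param K ensemble size (default 16, inside the 10-20 band where
#'   diversity and accuracy balance).
#' @param seed RNG seed for the latent draws.
#' @param constraints a \code{\link{pairingConstraints}}.
#' @param background "model" uses the model's background channel;
#'   "constant" uses the 0.5 null.
#' @return list: \code{ensemble} (\linkS4class{StructureEnsemble}),
#'   \code{summary} (see \code{\link{summarizeEnsemble}}),
#'   \code{consensus} (\linkS4class{SecondaryStructure}).
#' @export
ensemblePipeline <- function(model, seq, K = 16L, seed = 1L,
                             constraints = pairingConstraints(),
                             background = c("model", "constant")) {
  if (K < 1L) stop("K must be >= 1")
  background <- match.arg(background)
  rnaSeq <- if (is(seq, "RnaSequence")) seq else
    stop("ensemblePipeline needs an RnaSequence (residue identity drives pairing constraints)")
  mats <- sampleMatrices(model, rnaSeq, K, seed)
  structs <- lapply(mats, function(m) {
    bg <- if (background == "model") m$bg else 0.5
    pairFromProbabilities(rnaSeq, m$fg, bg, constraints)
  })
  ens <- StructureEnsemble(structs, seed = seed)
  pm <- predictMap(model, rnaSeq)
  bg <- if (background == "model") pm$bg else 0.5
  consensus <- pairFromProbabilities(rnaSeq, pm$fg, bg, constraints)
  list(ensemble = ens, summary = summarizeEnsemble(ens), consensus = consensus)
}
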