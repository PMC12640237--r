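# Synthetic RNA with known ground-truth base pairs: hairpins, multiloop
# composites (a stem-loop inserted into another loop, depth-bounded), and
# H-type pseudoknots. All randomness flows through one RNG seeded per
# dataset call; no global state is left behind.

WC_PAIRS <- list(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"))
GU_PAIRS <- list(c("G", "U"), c("U", "G"))
BASES <- c("A", "C", "G", "U")

#' Configuration for the synthetic RNA generator
#'
#' @param n_sequences number of (sequence, structure) items to draw.
#' @param length_range total-length bounds (nucleotides).
#' @param stem_length_range bounds on helix length (base pairs).
#' @param loop_length_range bounds on loop length (unpaired nt); the hairpin
#'   minimum of 3 is enforced.
#' @param pseudoknot_fraction fraction of items built as H-type pseudoknots.
#' @param composite_fraction fraction of non-pseudoknot items built as
#'   multiloop composites (recursive stem-in-loop, depth <= 3).
#' @param gu_fraction per-pair probability of a G-U wobble instead of a
#'   Watson-Crick pair in stems.
#' @param mutation_rate per-paired-position probability of replacing one
#'   partner with a random base, breaking complementarity (the ground-truth
#'   pair is kept, emulating non-canonical pairs / label noise).
#' @param seed integer RNG seed.
#' @return a validated config list of class \code{generatorConfig}.
#' @export
generatorConfig <- function(n_sequences = 100L,
                            length_range = c(16L, 64L),
                            stem_length_range = c(4L, 12L),
                            loop_length_range = c(3L, 8L),
                            pseudoknot_fraction = 0.15,
                            composite_fraction = 0.25,
                            gu_fraction = 0.1,
                            mutation_rate = 0,
                            seed = 1L) {
  cfg <- list(n_sequences = as.integer(n_sequences),
              length_range = as.integer(length_range),
              stem_length_range = as.integer(stem_length_range),
              loop_length_range = as.integer(loop_length_range),
              pseudoknot_fraction = pseudoknot_fraction,
              composite_fraction = composite_fraction,
              gu_fraction = gu_fraction,
              mutation_rate = mutation_rate,
              seed = as.integer(seed))
  stopifnot(cfg$n_sequences >= 1L,
            length(cfg$length_range) == 2L,
            cfg$length_range[1L] <= cfg$length_range[2L],
            cfg$stem_length_range[1L] <= cfg$stem_length_range[2L],
            cfg$stem_length_range[1L] >= 1L,
            cfg$loop_length_range[1L] <= cfg$loop_length_range[2L],
            cfg$loop_length_range[1L] >= 3L)
  for (f in c("pseudoknot_fraction", "composite_fraction", "gu_fraction",
              "mutation_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(sprintf("%s must lie in [0, 1]", f))
  class(cfg) <- "generatorConfig"
  cfg
}

drawPairedBases <- function(n, gu_fraction) {
  # returns 2 x n matrix of (left, right) residues
  vapply(seq_len(n), function(k) {
    if (stats::runif(1) < gu_fraction) {
      unlist(GU_PAIRS[[sample.int(2L, 1L)]])
    } else {
      unlist(WC_PAIRS[[sample.int(4L, 1L)]])
    }
  }, character(2))
}

applyMutations <- function(chars, pairs, mutation_rate) {
  if (mutation_rate <= 0 || nrow(pairs) == 0L) return(chars)
  for (r in seq_len(nrow(pairs))) {
    if (stats::runif(1) < mutation_rate) {
      side <- if (stats::runif(1) < 0.5) 1L else 2L
      chars[pairs[r, side] + 1L] <- BASES[sample.int(4L, 1L)]
    }
  }
  chars
}

#' Sample a single stem-loop (hairpin)
#'
#' Builds a helix of \code{stem_len} pairs closed by \code{loop_len}
#' unpaired residues: length L = 2*stem_len + loop_len with ground-truth
#' pairs (k, L-1-k) for k < stem_len. Paired residues are Watson-Crick,
#' or G-U wobble at rate \code{gu_fraction}; loop residues are uniform.
#'
#' @param stem_len helix length in pairs (>= 1).
#' @param loop_len loop length in nucleotides (>= 3, the hairpin minimum).
#' @param gu_fraction wobble-pair rate.
#' @param mutation_rate complementarity-breaking rate (see
#'   \code{\link{generatorConfig}}).
#' @param id sequence identifier.
#' @return list(sequence = RnaSequence, structure = SecondaryStructure).
#' @export
sampleStemLoop <- function(stem_len, loop_len, gu_fraction = 0.1,
                           mutation_rate = 0, id = "stemloop") {
  stopifnot(stem_len >= 1L)
  if (loop_len < 3L)
    stop("loop_len must be >= 3 (minimum hairpin loop)")
  L <- 2L * stem_len + loop_len
  chars <- character(L)
  bp <- drawPairedBases(stem_len, gu_fraction)
  ks <- seq_len(stem_len)
  pairs <- cbind(ks - 1L, L - ks)
  chars[ks] <- bp[1L, ]
  chars[L - ks + 1L] <- bp[2L, ]
  loopIdx <- (stem_len + 1L):(stem_len + loop_len)
  chars[loopIdx] <- BASES[sample.int(4L, loop_len, replace = TRUE)]
  chars <- applyMutations(chars, pairs, mutation_rate)
  list(sequence = RnaSequence(id, paste(chars, collapse = "")),
       structure = SecondaryStructure(L, pairs))
}

#' Sample a multiloop composite structure
#'
#' Starts from a stem-loop and recursively replaces part of a loop with a
#' further stem-loop (depth bounded), producing nested multibranch
#' structures without a full stochastic grammar.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @param depth maximum insertion depth (<= 3).
#' @param id sequence identifier.
#' @return as \code{\link{sampleStemLoop}}.
#' @export
sampleComposite <- function(cfg, depth = 2L, id = "composite") {
  depth <- min(as.integer(depth), 3L)
  buildPart <- function(d) {
    stem <- sampleInRange(cfg$stem_length_range)
    loop <- sampleInRange(cfg$loop_length_range)
    inner <- if (d > 1L && stats::runif(1) < 0.6) buildPart(d - 1L) else NULL
    bp <- drawPairedBases(stem, cfg$gu_fraction)
    if (is.null(inner)) {
      loopChars <- BASES[sample.int(4L, loop, replace = TRUE)]
      innerPairs <- matrix(integer(0), ncol = 2L)
    } else {
      # inner part sits inside the loop, flanked by the loop residues
      lead <- max(1L, loop %/% 2L)
      trail <- max(1L, loop - lead)
      loopChars <- c(BASES[sample.int(4L, lead, replace = TRUE)],
                     inner$chars,
                     BASES[sample.int(4L, trail, replace = TRUE)])
      innerPairs <- inner$pairs + lead
    }
    n <- length(loopChars)
    L <- 2L * stem + n
    chars <- c(bp[1L, ], loopChars, rev(bp[2L, ]))
    ks <- seq_len(stem)
    pairs <- rbind(cbind(ks - 1L, L - ks), innerPairs + stem)
    list(chars = chars, pairs = pairs)
  }
  part <- buildPart(depth)
  L <- length(part$chars)
  chars <- applyMutations(part$chars, part$pairs, cfg$mutation_rate)
  list(sequence = RnaSequence(id, paste(chars, collapse = "")),
       structure = SecondaryStructure(L, part$pairs))
}

#' Sample an H-type pseudoknot
#'
#' Lays out five regions 1..5; stem A pairs region 1 with region 3 and stem
#' B pairs region 2 with region 4, so every (A, B) pair combination crosses:
#' the result is always pseudoknotted.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @param id sequence identifier.
#' @return as \code{\link{sampleStemLoop}}.
#' @export
samplePseudoknot <- function(cfg, id = "pseudoknot") {
  sa <- sampleInRange(cfg$stem_length_range)
  sb <- sampleInRange(cfg$stem_length_range)
  l1 <- sampleInRange(cfg$loop_length_range)
  l2 <- sampleInRange(cfg$loop_length_range)
  l3 <- sampleInRange(cfg$loop_length_range)
  # layout: [A-open] l1 [B-open] l2 [A-close] l3 [B-close]
  L <- 2L * (sa + sb) + l1 + l2 + l3
  chars <- character(L)
  offA <- 0L
  offBopen <- sa + l1
  offAclose <- offBopen + sb + l2
  offBclose <- offAclose + sa + l3
  bpA <- drawPairedBases(sa, cfg$gu_fraction)
  bpB <- drawPairedBases(sb, cfg$gu_fraction)
  ka <- seq_len(sa); kb <- seq_len(sb)
  # A-close region read 5'->3' is the reverse complement of the A-open run
  pairsA <- cbind(offA + ka - 1L, offAclose + sa - ka)
  pairsB <- cbind(offBopen + kb - 1L, offBclose + sb - kb)
  chars[offA + ka] <- bpA[1L, ]
  chars[offAclose + sa - ka + 1L] <- bpA[2L, ]
  chars[offBopen + kb] <- bpB[1L, ]
  chars[offBclose + sb - kb + 1L] <- bpB[2L, ]
  unpaired <- which(chars == "" | is.na(chars))
  chars[unpaired] <- BASES[sample.int(4L, length(unpaired), replace = TRUE)]
  pairs <- rbind(pairsA, pairsB)
  chars <- applyMutations(chars, pairs, cfg$mutation_rate)
  list(sequence = RnaSequence(id, paste(chars, collapse = "")),
       structure = SecondaryStructure(L, pairs))
}

sampleInRange <- function(range) {
  if (range[1L] == range[2L]) return(range[1L])
  range[1L] + sample.int(range[2L] - range[1L] + 1L, 1L) - 1L
}

#' Sample a dataset of synthetic RNA with ground truth
#'
#' Draws \code{n_sequences} items: \code{pseudoknot_fraction} of them
#' (rounded) are H-type pseudoknots, \code{composite_fraction} of the rest
#' are multiloop composites, the remainder simple stem-loops. Items whose
#' total length falls outside \code{length_range} are redrawn (rejection
#' sampling). Fully deterministic under \code{cfg$seed}.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @return list of list(sequence=, structure=) items.
#' @export
sampleDataset <- function(cfg) {
  stopifnot(inherits(cfg, "generatorConfig"))
  withSeed(cfg$seed, {
    n <- cfg$n_sequences
    nPk <- round(cfg$pseudoknot_fraction * n)
    kinds <- c(rep("pk", nPk), rep("plain", n - nPk))
    lapply(seq_len(n), function(k) {
      for (try in 1:1000) {
        item <- if (kinds[k] == "pk") {
          samplePseudoknot(cfg, id = sprintf("synth_%04d_pk", k))
        } else if (stats::runif(1) < cfg$composite_fraction) {
          sampleComposite(cfg, id = sprintf("synth_%04d_ml", k))
        } else {
          stem <- sampleInRange(cfg$stem_length_range)
          loop <- sampleInRange(cfg$loop_length_range)
          sampleStemLoop(stem, loop, cfg$gu_fraction, cfg$mutation_rate,
                         id = sprintf("synth_%04d_sl", k))
        }
        L <- seqLength(item$sequence)
        if (L >= cfg$length_range[1L] && L <= cfg$length_range[2L])
          return(item)
      }
      stop("length_range incompatible with stem/loop ranges: no draw fits")
    })
  })
}

# run expr under a private RNG state; restores the caller's state after
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
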