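# shared fixtures: brute-force oracles and random-instance generators.
# Everything is generated in code under fixed seeds; nothing is read from
# disk.

# independent brute-force constructor for the dynamic-span window mask:
# loops positions and enumerates the window directly from the span formula
bruteForceMask <- function(L, cfg, pad_mask = NULL) {
  if (is.null(pad_mask)) pad_mask <- rep(TRUE, L)
  m <- matrix(FALSE, L, L)
  for (i in 0:(L - 1L)) {
    span <- min(cfg$S_max, floor(1 + cfg$growth_rate * i))
    span <- max(1L, as.integer(span))
    for (j in max(0L, i - span):min(L - 1L, i + span)) {
      if (pad_mask[j + 1L]) m[i + 1L, j + 1L] <- TRUE
    }
  }
  diag(m) <- TRUE
  m
}

# random valid secondary structure: a random matching on 0..L-1
randomStructure <- function(L, maxPairs = floor(L / 2)) {
  avail <- sample(0:(L - 1L))
  n <- sample.int(maxPairs + 1L, 1L) - 1L
  pairs <- NULL
  while (n > 0L && length(avail) >= 2L) {
    ij <- sort(avail[1:2])
    avail <- avail[-(1:2)]
    pairs <- rbind(pairs, ij)
    n <- n - 1L
  }
  SecondaryStructure(L, pairs)
}

# random candidate-pair instance for matching tests
randomCandidates <- function(L, nCand) {
  all <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  pick <- all[sample.int(nrow(all), min(nCand, nrow(all))), , drop = FALSE]
  d <- data.frame(i = pick[, 1L] - 1L, j = pick[, 2L] - 1L,
                  score = round(stats::runif(nrow(pick), 0.1, 5), 3))
  d[order(-d$score, d$i, d$j), ]
}

# tiny hairpin-biased sequence/structure pair for IO round-trips
randomSynthetic <- function() {
  if (stats::runif(1) < 0.3) {
    samplePseudoknot(generatorConfig())
  } else {
    sampleStemLoop(sample(2:8, 1), sample(3:8, 1))
  }
}

tinyModelConfig <- function(...) {
  args <- utils::modifyList(
    list(d_model = 16L, n_encoder_layers = 1L, n_decoder_layers = 1L,
         n_heads = 2L, d_feedforward = 24L, d_latent = 4L,
         dropout = 0, S_max = 8L, max_relative_distance = 8L),
    list(...))
  do.call(modelConfig, args)
}
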