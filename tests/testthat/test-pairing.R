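test_that("log-odds score matrix matches the closed forms", {
  L <- 4L
  p <- matrix(0.3, L, L); diag(p) <- 0
  c0 <- pairingConstraints(phi = 0)
  S <- scoreMatrix(p, p, c0)
  expect_equal(S, matrix(0, L, L))  # equal channels cancel both terms
  fg <- matrix(0.9, L, L); bg <- matrix(0.5, L, L)
  S2 <- scoreMatrix(fg, bg, c0)
  expect_equal(S2[1, 2], log(1.8) + log(5), tolerance = 1e-12)
  # phi is a pure additive shift
  set.seed(23)
  for (rep in 1:100) {
    phi <- runif(1, -2, 5)
    fgR <- matrix(runif(L * L), L, L)
    bgR <- matrix(runif(L * L), L, L)
    expect_equal(scoreMatrix(fgR, bgR, pairingConstraints(phi = phi)),
                 scoreMatrix(fgR, bgR, c0) - phi, tolerance = 1e-12)
  }
  expect_error(scoreMatrix(matrix(0, 3, 3), matrix(0, 4, 4)), "mismatch")
})

test_that("probability clamping keeps scores finite at 0 and 1", {
  fg <- matrix(c(0, 1, 1, 0), 2, 2)
  bg <- matrix(c(1, 0, 0, 1), 2, 2)
  S <- scoreMatrix(fg, bg, pairingConstraints(epsilon = 1e-6))
  expect_true(all(is.finite(S)))
})

test_that("candidates respect alphabet, loop and score constraints", {
  sq <- RnaSequence("h", "GGGAAAUUU")
  L <- 9L
  S <- matrix(1, L, L)
  cands <- candidatePairs(sq, S, pairingConstraints(min_loop = 3))
  keys <- paste(cands$i, cands$j)
  expect_true("0 8" %in% keys)   # G-U wobble allowed
  expect_false("0 1" %in% keys)  # G-G not pairable
  expect_false("3 5" %in% keys)  # A-A not pairable
  expect_false(any(cands$j - cands$i < 4))  # min_loop = 3 -> j - i >= 4
  # scores <= 0 are not candidates
  S0 <- S; S0[1, 9] <- S0[9, 1] <- -0.5
  cands0 <- candidatePairs(sq, S0, pairingConstraints(min_loop = 3))
  expect_false("0 8" %in% paste(cands0$i, cands0$j))
})

test_that("equal scores break ties by (i asc, j asc)", {
  sq <- RnaSequence("h", "GGGGAAAACCCC")
  S <- matrix(0, 12, 12)
  S[1, 10] <- S[10, 1] <- 2; S[2, 9] <- S[9, 2] <- 2  # (0,9) and (1,8)
  cands <- candidatePairs(sq, S, pairingConstraints())
  expect_equal(cands$i[1:2], c(0L, 1L))
  expect_equal(cands$j[1:2], c(9L, 8L))
})

test_that("greedy assignment accepts highest-score-first without conflicts", {
  cands <- data.frame(i = c(0L, 1L), j = c(3L, 2L), score = c(5, 3))
  s <- greedyAssign(cands, 4L)
  expect_equal(nPairs(s), 2L)
  chain <- data.frame(i = c(0L, 1L, 2L), j = c(1L, 2L, 3L),
                      score = c(5, 4, 3))
  s2 <- greedyAssign(chain, 4L)
  expect_identical(basePairs(s2), rbind(c(0L, 1L), c(2L, 3L)))
  expect_equal(matchingWeight(s2, chain), 8)
  expect_equal(nPairs(greedyAssign(chain[0, ], 4L)), 0L)
})

test_that("exact oracle returns the maximum-weight matching", {
  chain <- data.frame(i = c(0L, 1L, 2L), j = c(1L, 2L, 3L),
                      score = c(5, 4, 3))
  s <- exactMatchingOracle(chain, 4L)
  expect_equal(matchingWeight(s, chain), 8)
  disj <- data.frame(i = c(0L, 2L), j = c(1L, 3L), score = c(1, 1))
  expect_identical(basePairs(exactMatchingOracle(disj, 4L)),
                   basePairs(greedyAssign(disj, 4L)))
  big <- randomCandidates(30L, 25L)
  expect_error(exactMatchingOracle(big, 30L, max_candidates = 20L),
               "too large")
})

test_that("greedy carries at least half the exact matching weight", {
  set.seed(24)
  for (rep in 1:500) {
    L <- sample(4:10, 1)
    cands <- randomCandidates(L, sample(3:12, 1))
    g <- greedyAssign(cands, L)
    o <- exactMatchingOracle(cands, L)
    wg <- matchingWeight(g, cands)
    wo <- matchingWeight(o, cands)
    expect_gte(wg, 0.5 * wo - 1e-9)
    expect_true(validObject(g))
  }
})

test_that("greedy is invariant to permutations of equal-score candidates", {
  set.seed(25)
  for (rep in 1:25) {
    L <- 10L
    cands <- randomCandidates(L, 8L)
    cands$score <- sample(c(1, 2), nrow(cands), TRUE)  # force ties
    sorted <- cands[order(-cands$score, cands$i, cands$j), ]
    shuffled <- cands[sample.int(nrow(cands)), ]
    resorted <- shuffled[order(-shuffled$score, shuffled$i, shuffled$j), ]
    expect_identical(basePairs(greedyAssign(sorted, L)),
                     basePairs(greedyAssign(resorted, L)))
  }
})

test_that("phi is monotone: raising it never adds a pair", {
  set.seed(26)
  sq <- RnaSequence("s", paste(sample(c("A", "C", "G", "U"), 20, TRUE),
                               collapse = ""))
  fg <- matrix(runif(400), 20, 20); fg <- (fg + t(fg)) / 2; diag(fg) <- 0
  phis <- c(0, 0.5, 1, 2)
  sets <- lapply(phis, function(phi) {
    s <- pairFromProbabilities(sq, fg, 0.5, pairingConstraints(phi = phi))
    paste(basePairs(s)[, 1], basePairs(s)[, 2])
  })
  for (k in 2:length(sets)) {
    surviving <- candidatePairs(
      sq, scoreMatrix(fg, matrix(0.5, 20, 20),
                      pairingConstraints(phi = phis[k])),
      pairingConstraints(phi = phis[k]))
    expect_true(all(sets[[k]] %in% paste(surviving$i, surviving$j)))
    # the candidate pool only shrinks with phi
    prev <- candidatePairs(
      sq, scoreMatrix(fg, matrix(0.5, 20, 20),
                      pairingConstraints(phi = phis[k - 1])),
      pairingConstraints(phi = phis[k - 1]))
    expect_true(all(paste(surviving$i, surviving$j) %in%
                      paste(prev$i, prev$j)))
  }
})

test_that("sharp probabilities recover a known hairpin exactly", {
  item <- sampleStemLoop(4, 5, gu_fraction = 0, id = "hp")
  L <- seqLength(item$sequence)
  fg <- matrix(0.1, L, L)
  p <- basePairs(item$structure)
  fg[cbind(p[, 1] + 1, p[, 2] + 1)] <- 0.95
  fg[cbind(p[, 2] + 1, p[, 1] + 1)] <- 0.95
  diag(fg) <- 0
  pred <- pairFromProbabilities(item$sequence, fg, 0.1)
  expect_identical(basePairs(pred), basePairs(item$structure))
  # and the greedy result matches the exact matching on this instance
  S <- scoreMatrix(fg, matrix(0.1, L, L), pairingConstraints())
  cands <- candidatePairs(item$sequence, S, pairingConstraints())
  o <- exactMatchingOracle(cands, L)
  expect_identical(basePairs(pred), basePairs(o))
})

test_that("equal channels with phi = 0 yield the empty structure", {
  sq <- RnaSequence("s", "GGGGAAAACCCC")
  p <- matrix(0.4, 12, 12); diag(p) <- 0
  s <- pairFromProbabilities(sq, p, p, pairingConstraints(phi = 0))
  expect_equal(nPairs(s), 0L)
})

test_that("crossing control: pseudoknots reachable iff allowed", {
  cfg <- generatorConfig(seed = 8)
  set.seed(8)
  item <- samplePseudoknot(cfg)
  L <- seqLength(item$sequence)
  fg <- matrix(0.05, L, L)
  p <- basePairs(item$structure)
  fg[cbind(p[, 1] + 1, p[, 2] + 1)] <- 0.95
  fg[cbind(p[, 2] + 1, p[, 1] + 1)] <- 0.95
  diag(fg) <- 0
  withPk <- pairFromProbabilities(item$sequence, fg, 0.5,
                                  pairingConstraints(allow_crossing = TRUE))
  expect_true(hasCrossing(withPk))
  expect_identical(basePairs(withPk), basePairs(item$structure))
  noPk <- pairFromProbabilities(item$sequence, fg, 0.5,
                                pairingConstraints(allow_crossing = FALSE))
  expect_false(hasCrossing(noPk))
})

test_that("matching property holds on fuzzed random matrices", {
  set.seed(27)
  for (rep in 1:30) {
    L <- sample(8:25, 1)
    sq <- RnaSequence("s", paste(sample(c("A", "C", "G", "U"), L, TRUE),
                                 collapse = ""))
    fg <- matrix(runif(L * L), L, L); fg <- (fg + t(fg)) / 2; diag(fg) <- 0
    s <- pairFromProbabilities(sq, fg, 0.5)
    expect_true(validObject(s))
  }
})
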