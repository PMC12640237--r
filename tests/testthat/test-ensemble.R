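test_that("identical samples give zero entropy and zero PSDI", {
  s <- parseDotBracket("((..))..")
  e <- StructureEnsemble(rep(list(s), 5), seed = 1L)
  sm <- summarizeEnsemble(e)
  expect_equal(sm$H, rep(0, 8))
  expect_equal(sm$H_global, 0)
  expect_equal(sm$psdi, 0)
})

test_that("a one-pair swap between two samples gives PSDI = 2", {
  base <- SecondaryStructure(12, rbind(c(2, 6)))
  a <- SecondaryStructure(12, rbind(c(2, 6), c(0, 9)))
  b <- SecondaryStructure(12, rbind(c(2, 6), c(1, 8)))
  e <- StructureEnsemble(list(a, b))
  expect_equal(summarizeEnsemble(e)$psdi, 2)
  expect_equal(basePairDistance(a, b), 2)
  expect_equal(basePairDistance(a, base), 1)
  expect_equal(basePairDistance(base, base), 0)
})

test_that("a half-paired position carries exactly one bit", {
  paired <- SecondaryStructure(8, rbind(c(0, 7)))
  unpaired <- SecondaryStructure(8)
  e <- StructureEnsemble(list(paired, paired, unpaired, unpaired))
  sm <- summarizeEnsemble(e)
  expect_equal(sm$H[1], 1)
  expect_equal(sm$H[8], 1)
  expect_equal(sm$H[4], 0)
})

test_that("partner distributions sum to one on fuzzed ensembles", {
  set.seed(28)
  for (rep in 1:20) {
    L <- sample(6:25, 1)
    K <- sample(2:8, 1)
    e <- StructureEnsemble(replicate(K, randomStructure(L),
                                     simplify = FALSE))
    sm <- summarizeEnsemble(e)
    expect_equal(rowSums(sm$pair_freq) + sm$unpaired_freq, rep(1, L),
                 tolerance = 1e-12)
    expect_true(all(sm$H >= 0 & sm$H <= log2(L + 1)))
    expect_gte(sm$psdi, 0)
    # PSDI bound: never above the largest pairwise pair-count sum
    sizes <- vapply(e@structures, nPairs, integer(1))
    expect_lte(sm$psdi, max(outer(sizes, sizes, "+")))
  }
})

test_that("summaries are invariant under sample-order permutation", {
  set.seed(29)
  structs <- replicate(6, randomStructure(15), simplify = FALSE)
  s1 <- summarizeEnsemble(StructureEnsemble(structs))
  s2 <- summarizeEnsemble(StructureEnsemble(structs[sample(6)]))
  expect_equal(s1$H_global, s2$H_global)
  expect_equal(s1$psdi, s2$psdi)
  expect_equal(s1$pair_freq, s2$pair_freq)
})

test_that("base-pair distance is a metric (triangle inequality fuzz)", {
  set.seed(30)
  for (rep in 1:50) {
    L <- sample(6:20, 1)
    a <- randomStructure(L); b <- randomStructure(L); c <- randomStructure(L)
    expect_equal(basePairDistance(a, b), basePairDistance(b, a))
    expect_lte(basePairDistance(a, c),
               basePairDistance(a, b) + basePairDistance(b, c))
  }
  expect_error(basePairDistance(randomStructure(5), randomStructure(6)),
               "mismatch")
})

test_that("K = 1 ensembles have zero entropy and no PSDI", {
  e <- StructureEnsemble(list(randomStructure(10)))
  sm <- summarizeEnsemble(e)
  expect_equal(sm$H, rep(0, 10))
  expect_true(is.na(sm$psdi))
  expect_error(summarizeEnsemble(e, require_psdi = TRUE), "K = 1")
})

test_that("evaluation reproduces the precision/recall/F1 formulas", {
  # construct structures with known TP=8, FP=2, FN=2
  ref <- SecondaryStructure(40, cbind(0:9, 39:30))
  predPairs <- rbind(cbind(0:7, 39:32),       # 8 true positives
                     cbind(c(10L, 12L), c(25L, 27L)))  # 2 false positives
  pred <- SecondaryStructure(40, predPairs)
  r <- evaluateStructure(pred, ref)
  expect_equal(c(r$tp, r$fp, r$fn), c(8, 2, 2))
  expect_equal(c(r$precision, r$recall, r$f1), c(0.8, 0.8, 0.8))
  # perfect prediction
  r2 <- evaluateStructure(ref, ref)
  expect_equal(c(r2$precision, r2$recall, r2$f1), c(1, 1, 1))
  # empty prediction vs non-empty reference
  r3 <- evaluateStructure(SecondaryStructure(40), ref)
  expect_equal(c(r3$precision, r3$recall, r3$f1), c(0, 0, 0))
  # both empty counts as perfect agreement
  r4 <- evaluateStructure(SecondaryStructure(5), SecondaryStructure(5))
  expect_equal(c(r4$precision, r4$recall, r4$f1), c(1, 1, 1))
  expect_error(evaluateStructure(SecondaryStructure(5), ref), "mismatch")
})

test_that("F1 is symmetric under (pred, ref) swap when FP = FN", {
  set.seed(32)
  for (rep in 1:25) {
    L <- 30L
    a <- randomStructure(L); b <- randomStructure(L)
    ra <- evaluateStructure(a, b); rb <- evaluateStructure(b, a)
    expect_equal(ra$tp, rb$tp)
    expect_equal(ra$f1, rb$f1)  # harmonic mean swaps precision/recall
  }
})

test_that("segmented prediction equals direct prediction when L <= window", {
  set.seed(33)
  m <- tvaeModel(tinyModelConfig(max_length = 64L), seed = 11)
  for (rep in 1:5) {
    L <- sample(10:30, 1)
    sq <- RnaSequence("s", paste(sample(c("A", "C", "G", "U"), L, TRUE),
                                 collapse = ""))
    direct <- predictMap(m, sq)
    seg <- segmentedPredict(m, sq, window = 32L, overlap = 8L)
    expect_identical(probValues(seg$fg), probValues(direct$fg))
    expect_identical(probValues(seg$bg), probValues(direct$bg))
  }
  expect_error(segmentedPredict(m, RnaSequence("s", "ACGU"),
                                window = 16L, overlap = 16L), "overlap")
})

test_that("windows tile long sequences with full coverage", {
  set.seed(34)
  cfg <- tinyModelConfig(max_length = 40L, S_max = 4L)
  m <- tvaeModel(cfg, seed = 12)
  L <- 75L
  sq <- RnaSequence("s", paste(sample(c("A", "C", "G", "U"), L, TRUE),
                               collapse = ""))
  seg <- segmentedPredict(m, sq, window = 40L, overlap = 10L)
  v <- probValues(seg$fg)
  expect_equal(dim(v), c(L, L))
  expect_true(validObject(seg$fg))
  # the within-window band must be covered (nonzero background average)
  bg <- probValues(seg$bg)
  expect_true(all(bg[abs(row(bg) - col(bg)) == 1] > 0))
  # distant pairs beyond any window carry zero foreground (stated limit)
  expect_true(all(v[abs(row(v) - col(v)) >= 40L] == 0))
})

test_that("ensemble pipeline is deterministic and internally consistent", {
  set.seed(35)
  m <- tvaeModel(tinyModelConfig(), seed = 13)
  sq <- sampleStemLoop(4, 4, id = "p")$sequence
  r1 <- ensemblePipeline(m, sq, K = 4, seed = 21, background = "constant")
  r2 <- ensemblePipeline(m, sq, K = 4, seed = 21, background = "constant")
  expect_identical(lapply(r1$ensemble@structures, basePairs),
                   lapply(r2$ensemble@structures, basePairs))
  expect_equal(r1$summary$psdi, r2$summary$psdi)
  expect_equal(r1$summary$K, 4L)
  expect_true(validObject(r1$ensemble))
  expect_true(validObject(r1$consensus))
  # near-zero posterior variance collapses the ensemble onto the consensus
  m2 <- m
  m2@params[["lv.W"]][] <- 0
  m2@params[["lv.b"]][] <- -50
  r3 <- ensemblePipeline(m2, sq, K = 4, seed = 22, background = "constant")
  expect_lte(r3$summary$psdi, 2)
  expect_lte(r3$summary$H_global, 0.3)
})
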