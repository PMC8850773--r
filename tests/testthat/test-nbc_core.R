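test_that("k-mer extraction windows, skipping and errors behave", {
  k8 <- extractKmers("ACGTACGTA", k = 8)
  expect_identical(names(k8), c("ACGTACGT", "CGTACGTA"))
  expect_identical(unname(as.integer(k8)), c(1L, 1L))

  # every window containing the N is skipped
  kN <- extractKmers("ACGTNACGTACGTACG", k = 8)
  expect_setequal(names(kN),
                  c("ACGTACGT", "CGTACGTA", "GTACGTAC", "TACGTACG"))

  # abundances retained
  rep2 <- extractKmers("ACGTACGTACGT", k = 4)
  expect_identical(unname(as.integer(rep2["ACGT"])), 3L)

  expect_error(extractKmers("ACGT", k = 8), "shorter than k")
})

test_that("training reproduces the smoothed probability formulas", {
  # one species, one sequence: every present word has n(w)=1, m_s(w)=1
  rs <- makeRefSet(c(a = "ACGTACGTA"), genus = "g1", species = "s1")
  cfg <- classifierConfig(k = 8)
  m <- trainClassifier(rs, cfg)
  # P(w) = (1+0.5)/(1+1) = 0.75; P(w|s) = (1+0.75)/(1+1) = 0.875
  expect_equal(unname(scoreQuery(m, "ACGTACGT")), log(0.875))
  # absent word: P(w) = 0.5/2 = 0.25; P(w|s) = (0+0.25)/2 = 0.125
  expect_equal(unname(scoreQuery(m, "AAAAAAAA")), log(0.125))

  # a sequence's own words score higher in its own species
  rs2 <- makeRefSet(c(a = "AAAAACAAAAA", b = "GGGGGTGGGGG"),
                    genus = c("g1", "g2"), species = c("s1", "s2"))
  m2 <- trainClassifier(rs2, classifierConfig(k = 4))
  sc <- scoreQuery(m2, names(extractKmers("AAAAACAAAAA", 4)))
  expect_gt(sc[["g1|s1"]], sc[["g2|s2"]])
})

test_that("scores ignore duplicate query words and stay finite", {
  rs <- makeRefSet(c(a = "AAAAACAAAAA", b = "GGGGGTGGGGG"),
                   genus = c("g1", "g2"), species = c("s1", "s2"))
  m <- trainClassifier(rs, classifierConfig(k = 4))
  once <- scoreQuery(m, c("AAAA", "CCCC"))
  thrice <- scoreQuery(m, c("AAAA", "AAAA", "CCCC", "AAAA"))
  expect_identical(once, thrice)
  # no word shared with training: smoothing keeps scores finite
  far <- scoreQuery(m, c("CCCC", "TTTT"))
  expect_true(all(is.finite(far)))
})

test_that("scores match the brute-force recount on random instances", {
  cfg <- classifierConfig(k = 3, nBootstrap = 5, seed = 1)
  for (seed in 1:40) {
    inst <- randomInstance(seed)
    model <- trainClassifier(inst$refset, cfg)
    query <- inst$seqs[[sample(length(inst$seqs), 1)]]
    words <- unique(oracleWindows(query, 3))
    expect_equal(scoreQuery(model, words),
                 oracleScores(inst$seqs, inst$speciesOf, words),
                 tolerance = 1e-12)
  }
})

test_that("classification is exact on isolated species and seeded", {
  # two species with disjoint word content
  rs <- makeRefSet(c(a1 = "AAAAACAAAAAA", a2 = "AAAAACAAAAAA",
                     b1 = "GGGGGTGGGGGG", b2 = "GGGGGTGGGGGG"),
                   genus = c("gA", "gA", "gB", "gB"),
                   species = c("sA", "sA", "sB", "sB"))
  cfg <- classifierConfig(k = 4, seed = 5)
  m <- trainClassifier(rs, cfg)
  res <- classifySequence(m, "q", "AAAAACAAAAAA", cfg)
  expect_identical(unname(res@lineage[["species"]]), "sA")
  expect_true(all(res@confidence == 100))

  # identical (model, query, seed) -> identical result
  res2 <- classifySequence(m, "q", "AAAAACAAAAAA", cfg)
  expect_equal(res, res2)
  # a different query id draws a different substream
  res3 <- classifySequence(m, "q_other", "AAAAACAAAAAA", cfg)
  expect_identical(res3@lineage, res@lineage)
})

test_that("duplicated species split votes ~50/50 but agree at genus", {
  # two species of one genus with identical training sequences
  rs <- makeRefSet(c(a1 = "ACGGTCAGTACGAT", a2 = "ACGGTCAGTACGAT",
                     b1 = "ACGGTCAGTACGAT", b2 = "ACGGTCAGTACGAT"),
                   genus = rep("gA", 4),
                   species = c("sA", "sA", "sB", "sB"))
  cfg0 <- classifierConfig(k = 4, nBootstrap = 100)
  m <- trainClassifier(rs, cfg0)
  confs <- vapply(1:20, function(s) {
    r <- classifySequence(m, "q", "ACGGTCAGTACGAT",
                          classifierConfig(k = 4, nBootstrap = 100,
                                           seed = s))
    expect_identical(unname(r@lineage[["species"]]), "sA")  # lexicographic
    expect_identical(unname(r@confidence[["genus"]]), 100)
    r@confidence[["species"]]
  }, numeric(1))
  expect_gt(mean(confs), 35)
  expect_lt(mean(confs), 65)
})

test_that("confidence is non-increasing from phylum to species", {
  cfg <- classifierConfig(k = 3, nBootstrap = 30, seed = 2)
  for (seed in 1:10) {
    inst <- randomInstance(seed)
    model <- trainClassifier(inst$refset, cfg)
    for (q in sample(names(inst$seqs), 2)) {
      r <- classifySequence(model, q, inst$seqs[[q]], cfg)
      expect_true(all(diff(r@confidence) <= 0))
      expect_identical(unname(r@pass), unname(r@confidence >= 80))
    }
  }
})

test_that("remove/add are exact inverses and match retraining", {
  cfg <- classifierConfig(k = 3)
  for (seed in 1:10) {
    inst <- randomInstance(seed)
    rs <- inst$refset
    model <- trainClassifier(rs, cfg)
    id <- sample(seqIds(rs), 1)
    i <- match(id, seqIds(rs))

    reduced <- removeSequence(model, id)
    # full-retrain oracle
    expect_equal(reduced, trainClassifier(rs[-i], cfg))
    # add o remove = identity, field by field
    restored <- addSequence(reduced, id, inst$seqs[[id]],
                            taxonomy(rs)[i, ])
    expect_equal(restored, model)
  }
  # removing a species' last sequence drops it from score output
  rs <- makeRefSet(c(a = "AAAAACAAAAAA", b = "GGGGGTGGGGGG"),
                   genus = c("g1", "g2"), species = c("s1", "s2"))
  m <- trainClassifier(rs, cfg)
  m2 <- removeSequence(m, "b")
  expect_identical(names(scoreQuery(m2, "AAA")), "g1|s1")
  expect_error(removeSequence(m2, "b"), "unknown seq_id")
})
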