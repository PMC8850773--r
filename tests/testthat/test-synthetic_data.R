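test_that("mutateSequence is identity at 0, total at 1, binomial in between", {
  s <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  set.seed(1)
  expect_identical(mutateSequence(s, 0), s)
  m1 <- mutateSequence(s, 1)
  expect_identical(nchar(m1), nchar(s))
  expect_true(all(strsplit(m1, "")[[1]] != strsplit(s, "")[[1]]))

  # expected Hamming distance ~ L * p (Monte Carlo vs binomial)
  L <- 100; p <- 0.1; reps <- 300
  set.seed(2)
  d <- replicate(reps, sum(strsplit(mutateSequence(s, p), "")[[1]] !=
                             strsplit(s, "")[[1]]))
  se <- sqrt(L * p * (1 - p) / reps)
  expect_lt(abs(mean(d) - L * p), 3 * se)
})

test_that("simulate produces the configured counts and structure", {
  cfg <- simConfig(markers = c(mk1 = 120L), nFamilies = 2,
                   generaPerFamily = 2, speciesPerGenus = 2,
                   seqsPerSpecies = 5, seed = 9)
  sim <- simulateMarkers(cfg)
  rs <- sim$refsets$mk1
  expect_identical(length(rs), 40L)
  s <- datasetSummary(rs)
  expect_identical(s$species, 8L)
  expect_identical(s$genera, 4L)
  expect_identical(s$families, 2L)
  expect_identical(s$phyla, 1L)
  expect_true(all(isCompleteLineage(taxonomy(rs))))
})

test_that("simulation is deterministic and markers share a taxonomy", {
  cfg <- simConfig(markers = c(mk1 = 100L, mk2 = 100L), seed = 4)
  a <- simulateMarkers(cfg)
  b <- simulateMarkers(cfg)
  expect_equal(a, b)
  taxNoId <- function(rs) {
    t <- taxonomy(rs); rownames(t) <- NULL; t
  }
  expect_identical(taxNoId(a$refsets$mk1), taxNoId(a$refsets$mk2))

  # byte-identical files from the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimOutput(a, d1); writeSimOutput(simulateMarkers(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("d_intra = 0 collapses conspecific sequences", {
  cfg <- simConfig(markers = c(mk1 = 100L), dIntra = 0, seed = 3)
  rs <- simulateMarkers(cfg)$refsets$mk1
  for (sp in unique(speciesKey(rs))) {
    seqs <- as.character(sequences(rs)[speciesKey(rs) == sp])
    expect_identical(length(unique(seqs)), 1L)
  }
})

test_that("within-species identity matches the d_intra expectation", {
  L <- 400; dIntra <- 0.01
  cfg <- simConfig(markers = c(mk1 = as.integer(L)), nFamilies = 2,
                   generaPerFamily = 2, speciesPerGenus = 2,
                   seqsPerSpecies = 6, dIntra = dIntra, seed = 12)
  rs <- simulateMarkers(cfg)$refsets$mk1
  # two conspecific sequences disagree at a site if exactly one of two
  # independent Bernoulli(dIntra) substitutions hit it, or both hit and
  # landed on different alternatives (2/3 of the time)
  pDiff <- 2 * dIntra * (1 - dIntra) + dIntra^2 * (2 / 3)
  ids <- numeric()
  for (sp in unique(speciesKey(rs))) {
    seqs <- as.character(sequences(rs)[speciesKey(rs) == sp])
    for (i in seq_len(length(seqs) - 1))
      for (j in (i + 1):length(seqs))
        ids <- c(ids, mean(strsplit(seqs[i], "")[[1]] !=
                             strsplit(seqs[j], "")[[1]]))
  }
  nPos <- length(ids) * L
  se <- sqrt(pDiff * (1 - pDiff) / nPos)
  expect_lt(abs(mean(ids) - pDiff), 3 * se)
})

test_that("problematic genera have identical species ancestors", {
  cfg <- simConfig(markers = c(mk1 = 150L), nFamilies = 1,
                   generaPerFamily = 2, speciesPerGenus = 3,
                   seqsPerSpecies = 2, dIntra = 0,
                   problematic = "Gen0101", seed = 5)
  sim <- simulateMarkers(cfg)
  rs <- sim$refsets$mk1
  tax <- taxonomy(rs)
  probSeqs <- unique(as.character(
    sequences(rs)[tax[, "genus"] == "Gen0101"]))
  expect_identical(length(probSeqs), 1L)  # dSpecies and dIntra both 0
  goodSeqs <- unique(as.character(
    sequences(rs)[tax[, "genus"] == "Gen0102"]))
  expect_gt(length(goodSeqs), 1L)
  expect_identical(sim$truth$problematic,
                   sim$truth$genus == "Gen0101")
})

test_that("singleton fraction emits single-sequence species", {
  cfg <- simConfig(markers = c(mk1 = 100L), nFamilies = 2,
                   generaPerFamily = 2, speciesPerGenus = 5,
                   seqsPerSpecies = 4, singletonFraction = 0.25, seed = 8)
  rs <- simulateMarkers(cfg)$refsets$mk1
  counts <- table(speciesKey(rs))
  expect_identical(sum(counts == 1L), 5L)  # 0.25 * 20 species
  expect_identical(sum(counts == 4L), 15L)
})

test_that("simulator output survives io round-trip and curation", {
  cfg <- simConfig(markers = c(mk1 = 100L), singletonFraction = 0.3,
                   seed = 6)
  sim <- simulateMarkers(cfg)
  d <- withr::local_tempdir()
  writeSimOutput(sim, d)
  rs <- joinReference(readFasta(file.path(d, "mk1.fasta")),
                      readTaxonomy(file.path(d, "mk1.tax")), "mk1")
  expect_identical(as.character(sequences(rs)),
                   as.character(sequences(sim$refsets$mk1)))
  expect_identical(taxonomy(rs), taxonomy(sim$refsets$mk1))
  suppressMessages({
    rs <- filterCompleteTaxonomy(rs)
    rs <- filterLength(rs, 50, 0.5)
    rs <- balanceSet(rs, balanceConfig("2-20", seed = 1))
  })
  expect_true(all(table(speciesKey(rs)) >= 2))
})
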