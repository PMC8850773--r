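test_that("bootstrap histogram bins and normalizes", {
  loo <- makeLooSpecies(c("a", "b", "c"), c("a", "b", "c"),
                        conf = c(95, 95, 60))
  h <- bootstrapHistogram(loo, "species")
  expect_equal(sum(h$pct), 100, tolerance = 1e-9)
  expect_equal(h$pct[h$bin == "95-100"], 200 / 3, tolerance = 1e-9)
  expect_equal(h$pct[h$bin == "60-69"], 100 / 3, tolerance = 1e-9)

  all100 <- bootstrapHistogram(makeLooSpecies("a", "a", conf = 100))
  expect_equal(all100$pct[all100$bin == "95-100"], 100)
  expect_error(bootstrapHistogram(makeLooSpecies("a", "a")[0, ]), "empty")
})

test_that("assignment rate counts trusted records and is monotone", {
  loo <- makeLooSpecies(rep("a", 10), rep("a", 10),
                        conf = c(rep(95, 8), 60, 60))
  expect_equal(assignmentRate(loo, "species", 80), 0.8)
  expect_equal(assignmentRate(loo, "species", 0), 1.0)
  expect_equal(assignmentRate(loo, "species", 101), 0.0)
  ts <- seq(0, 100, by = 5)
  rates <- vapply(ts, function(t) assignmentRate(loo, "species", t),
                  numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("rank accuracy splits correct/incorrect among trusted records", {
  loo <- makeLooSpecies(c("a", "a", "b", "b"), c("a", "a", "a", "b"),
                        conf = c(100, 100, 100, 50))
  acc <- rankAccuracy(loo, "species", 80)
  expect_equal(unname(acc["correct"]), 200 / 3)
  expect_equal(sum(acc), 100)
  # below-threshold records excluded from the denominator...
  accAll <- rankAccuracy(loo, "species", 80, denominator = "all")
  expect_equal(unname(accAll["correct"]), 50)  # ...unless denominator="all"
  expect_error(rankAccuracy(makeLooSpecies("a", "a", conf = 10),
                            "species", 80), "no record passes")
})

test_that("confusion matrix conserves row sums and routes failures", {
  loo <- makeLooSpecies(c("a", "a", "a", "b"), c("a", "a", "b", "b"),
                        conf = c(100, 100, 100, 50))
  cm <- markerNBC::confusionMatrix(loo, "species", 80)
  expect_identical(cm["G1|a", "G1|a"], 3L - 1L)
  expect_identical(cm["G1|a", "G1|b"], 1L)
  expect_identical(cm["G1|b", "unclassified"], 1L)
  expect_identical(as.integer(rowSums(cm)),
                   unname(as.vector(table(loo$true_species)[c("a", "b")])))
})

test_that("species scores implement one-vs-rest precision/recall/F1", {
  # perfect diagonal
  loo <- makeLooSpecies(c("a", "b", "c"), c("a", "b", "c"))
  ss <- speciesScores(markerNBC::confusionMatrix(loo, "species", 80))
  expect_true(all(ss$f1 == 1))

  # TP=1 FP=1 FN=1 -> P=R=F1=0.5 ; unclassified counts as FN only
  loo <- makeLooSpecies(c("a", "a", "b"), c("a", "b", "a"), conf = 100)
  ss <- speciesScores(markerNBC::confusionMatrix(loo, "species", 80))
  a <- ss[ss$species == "G1|a", ]
  expect_equal(c(a$precision, a$recall, a$f1), c(0.5, 0.5, 0.5))

  # TP=2 FP=0 FN=2 -> P=1, R=0.5, F1=2/3
  loo <- makeLooSpecies(rep("a", 4), c("a", "a", "b", "b"),
                        conf = c(100, 100, 100, 10))
  ss <- speciesScores(markerNBC::confusionMatrix(loo, "species", 80))
  a <- ss[ss$species == "G1|a", ]
  expect_identical(c(a$TP, a$FP, a$FN), c(2L, 0L, 2L))
  expect_equal(a$f1, 2 / 3)
})

test_that("species scores agree with caret on a random clean matrix", {
  skip_if_not_installed("caret")
  set.seed(7)
  species <- paste0("s", 1:5)
  true <- sample(species, 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.7, true, sample(species, 60, replace = TRUE))
  loo <- makeLooSpecies(true, pred, conf = 100)
  ss <- speciesScores(markerNBC::confusionMatrix(loo, "species", 80))
  lev <- paste0("G1|", species)
  byClass <- caret::confusionMatrix(
    data = factor(paste0("G1|", pred), levels = lev),
    reference = factor(paste0("G1|", true), levels = lev))$byClass
  for (s in lev) {
    row <- ss[ss$species == s, ]
    cp <- byClass[paste0("Class: ", s), "Precision"]
    cr <- byClass[paste0("Class: ", s), "Recall"]
    cf <- byClass[paste0("Class: ", s), "F1"]
    if (!is.na(cp)) expect_equal(row$precision, unname(cp))
    if (!is.na(cr)) expect_equal(row$recall, unname(cr))
    if (!is.na(cf)) expect_equal(row$f1, unname(cf))
  }
})

test_that("genus F1 is the unweighted mean of species F1", {
  ss <- data.frame(species = c("x", "y", "z"), f1 = c(1, 0.5, 0))
  g <- genusF1(ss, setNames(c("G1", "G1", "G1"), c("x", "y", "z")))
  expect_equal(g$mean_f1, 0.5)
  # single-species genus and permutation invariance
  g2 <- genusF1(ss[c(3, 1, 2), ], setNames(c("G1", "G2", "G1"),
                                           c("x", "y", "z")))
  expect_equal(g2$mean_f1[g2$genus == "G2"], 0.5)
  expect_equal(g2$mean_f1[g2$genus == "G1"], 0.5)
  expect_error(genusF1(ss, setNames("G1", "x")), "no genus mapping")
})

test_that("cumulative F1 curve is a non-decreasing step reaching 100", {
  g <- data.frame(genus = c("a", "b"), mean_f1 = c(0.1, 0.9))
  curve <- cumulativeF1Curve(g)
  expect_equal(curve$cumulative_pct[curve$threshold == 0.25], 50)
  expect_equal(curve$cumulative_pct[curve$threshold == 1], 100)
  expect_true(all(diff(curve$cumulative_pct) >= 0))

  all1 <- cumulativeF1Curve(data.frame(genus = "a", mean_f1 = 1))
  expect_equal(all1$cumulative_pct[all1$threshold == 1], 100)
  expect_true(all(all1$cumulative_pct[all1$threshold < 1] == 0))
})

test_that("genus categorization matches the three scenarios", {
  tabs <- list(
    matK = data.frame(genus = c("ga", "gb2", "gc"),
                      mean_f1 = c(0.9, 0.9, 0.1)),
    rbcL = data.frame(genus = c("ga", "gonly", "gc"),
                      mean_f1 = c(0.1, 0.2, 0.2)))
  out <- categorizeGenera(tabs, 0.25)
  get <- function(g) out[out$genus == g, ]
  expect_identical(get("ga")$scenario, "a")      # one good, one poor
  expect_true(get("ga")$has_poor_marker)
  expect_identical(get("gb2")$scenario, "a")     # one good only
  expect_false(get("gb2")$has_poor_marker)
  expect_identical(get("gonly")$scenario, "b")   # single poor marker
  expect_identical(get("gc")$scenario, "c")      # all poor, >= 2 markers
  # boundary: poor means f1 <= cutoff
  border <- categorizeGenera(list(m1 = data.frame(genus = "g",
                                                  mean_f1 = 0.25)), 0.25)
  expect_identical(border$scenario, "b")
})

test_that("divergence diagnostic measures identity and flags no-gap genera", {
  rs <- makeRefSet(
    c(a1 = strrep("ACGT", 25), a2 = strrep("ACGT", 25),
      b1 = strrep("ACGT", 25), b2 = strrep("ACGT", 25)),
    genus = rep("g1", 4), species = c("s1", "s1", "s2", "s2"))
  d <- divergenceDiagnostic(rs, "g1")
  expect_equal(d$within, 1)
  expect_equal(d$between, 1)
  expect_true(d$no_gap)

  # two sequences differing at 5 of 100 positions -> 0.95
  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("A", 95), strrep("C", 5))
  rs2 <- makeRefSet(c(a1 = s1, a2 = s1, b1 = s2, b2 = s2),
                    genus = rep("g1", 4),
                    species = c("s1", "s1", "s2", "s2"))
  d2 <- divergenceDiagnostic(rs2, "g1")
  expect_equal(d2$within, 1)
  expect_equal(d2$between, 0.95)
  expect_false(d2$no_gap)

  expect_error(divergenceDiagnostic(rs, "nope"), "not in reference set")
  one <- makeRefSet(c(x = "ACGT"), genus = "g9", species = "s")
  expect_error(divergenceDiagnostic(one, "g9"), "single sequence")
})
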