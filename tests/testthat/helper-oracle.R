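# Independent brute-force implementation of the Wang-style word-count
# Bayes score, written over plain strings with no shared code with the
# package internals. Used as the oracle the classifier is checked against.

oracleWindows <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  w <- substring(seq, 1:(n - k + 1), k:n)
  w[grepl("^[ACGT]+$", w)]
}

# Per-species log joint probability of a set of query words, recomputing
# n(w), m_s(w), M_s and N from the raw training strings each time.
oracleScores <- function(trainSeqs, speciesOf, queryWords) {
  queryWords <- unique(queryWords)
  species <- sort(unique(speciesOf), method = "radix")
  N <- length(trainSeqs)
  k <- nchar(queryWords[1])
  hasWord <- lapply(trainSeqs, function(s) unique(oracleWindows(s, k)))
  scores <- sapply(species, function(sp) {
    idx <- which(speciesOf == sp)
    Ms <- length(idx)
    total <- 0
    for (w in queryWords) {
      nw <- sum(vapply(hasWord, function(h) w %in% h, logical(1)))
      msw <- sum(vapply(hasWord[idx], function(h) w %in% h, logical(1)))
      Pw <- (nw + 0.5) / (N + 1)
      total <- total + log((msw + Pw) / (Ms + 1))
    }
    total
  })
  scores
}

oraclePoint <- function(scores) names(scores)[which(scores == max(scores))[1]]

# Random small classification instance: named sequences, species keys and
# the matching ReferenceSet. Sequences share a genus-level backbone so
# species overlap in words (exercising non-trivial score differences).
randomInstance <- function(seed, nSpeciesMax = 5, seqLenMax = 30,
                           minPerSpecies = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  nSpecies <- sample(2:nSpeciesMax, 1)
  nGenera <- sample(1:2, 1)
  genusOf <- sample(paste0("g", 1:nGenera), nSpecies, replace = TRUE)
  len <- sample(10:seqLenMax, 1)
  backbone <- lapply(1:nGenera, function(i)
    paste(sample(bases, len, replace = TRUE), collapse = ""))
  names(backbone) <- paste0("g", 1:nGenera)
  seqs <- character(); speciesOf <- character(); lineages <- character()
  for (s in 1:nSpecies) {
    n <- sample(minPerSpecies:4, 1)
    anc <- strsplit(backbone[[genusOf[s]]], "")[[1]]
    flip <- sample(len, max(1, round(0.15 * len)))
    anc[flip] <- sample(bases, length(flip), replace = TRUE)
    for (i in 1:n) {
      v <- anc
      noise <- sample(len, 1)
      v[noise] <- sample(bases, 1)
      id <- paste0("sp", s, "_", i)
      seqs[id] <- paste(v, collapse = "")
      speciesOf[id] <- paste0(genusOf[s], "|sp", s)
      lineages[id] <- paste0("p__P;c__C;o__O;f__F;g__", genusOf[s],
                             ";s__sp", s)
    }
    if (length(seqs) >= 20) break
  }
  keep <- seq_len(min(length(seqs), 20))
  list(seqs = seqs[keep], speciesOf = speciesOf[keep],
       refset = ReferenceSet("test", seqs[keep], lineages[keep]))
}
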