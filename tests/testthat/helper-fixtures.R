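# Small deterministic fixture builders shared across test files.

LIN <- function(p = "P", c = "C", o = "O", f = "F", g = "G", s = "S")
  paste0("p__", p, ";c__", c, ";o__", o, ";f__", f, ";g__", g, ";s__", s)

# refset with explicit per-record genus/species and sequences
makeRefSet <- function(seqs, genus, species, marker = "test",
                       family = "F1") {
  ids <- names(seqs)
  lineages <- setNames(
    mapply(function(g, s, f) LIN(f = f, g = g, s = s), genus, species,
           rep_len(family, length(genus))),
    ids)
  ReferenceSet(marker, seqs, lineages)
}

# balanced random refset (every species has >= 2 sequences), for LOO tests
makeBalancedRandomSet <- function(seed, nSpecies = 3, perSpecies = 2:3,
                                  len = 40) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- character(); genus <- character(); species <- character()
  for (s in seq_len(nSpecies)) {
    anc <- sample(bases, len, replace = TRUE)
    for (i in seq_len(sample(perSpecies, 1))) {
      v <- anc
      flip <- sample(len, 2)
      v[flip] <- sample(bases, 2, replace = TRUE)
      id <- paste0("sp", s, "_", i)
      seqs[id] <- paste(v, collapse = "")
      genus[id] <- paste0("g", (s + 1) %/% 2)
      species[id] <- paste0("sp", s)
    }
  }
  makeRefSet(seqs, genus, species)
}

# naive leave-one-out oracle: full retrain on N-1 for every record
naiveLoo <- function(rs, cfg) {
  ids <- seqIds(rs)
  lapply(seq_along(ids), function(i) {
    model <- trainClassifier(rs[-i], cfg)
    classifySequence(model, ids[i],
                     as.character(sequences(rs)[[i]]), cfg)
  })
}

# one-genus refset with the given per-species sequence counts
counts2rs <- function(counts) {
  seqs <- character(); genus <- character(); species <- character()
  for (s in seq_along(counts)) {
    for (i in seq_len(counts[s])) {
      id <- paste0("sp", s, "_", i)
      seqs[id] <- "ACGTACGTAC"
      genus[id] <- "g1"
      species[id] <- paste0("sp", s)
    }
  }
  makeRefSet(seqs, genus, species)
}

# minimal leave-one-out frame at species level: constant upper ranks,
# given genus per species label, everything classified
makeLooSpecies <- function(trueSpecies, predSpecies, conf = 100,
                           genusOf = NULL) {
  n <- length(trueSpecies)
  if (is.null(genusOf)) {
    all <- unique(c(trueSpecies, predSpecies))
    genusOf <- setNames(rep("G1", length(all)), all)
  }
  conf <- rep_len(conf, n)
  df <- data.frame(query_id = paste0("q", seq_len(n)), classified = TRUE,
                   stringsAsFactors = FALSE)
  for (r in c("phylum", "class", "order", "family")) {
    df[[paste0("true_", r)]] <- "X"
    df[[paste0("pred_", r)]] <- "X"
  }
  df$true_genus <- unname(genusOf[trueSpecies])
  df$pred_genus <- unname(genusOf[predSpecies])
  df$true_species <- trueSpecies
  df$pred_species <- predSpecies
  for (r in taxonomicRanks()) {
    df[[paste0("conf_", r)]] <- conf
    df[[paste0("pass_", r)]] <- conf >= 80
  }
  df
}
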