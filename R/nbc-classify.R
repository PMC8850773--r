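# Stable 31-bit polynomial hash of (seed, id): the per-query RNG substream.
# Keeps classification results independent of query order and safe for
# parallel evaluation. Pure-integer arithmetic in doubles (exact: values
# stay far below 2^53).
.deriveSeed <- function(seed, id) {
  bytes <- utf8ToInt(paste0(seed, ":", id))
  h <- 17
  p <- 2147483629  # largest-but-one prime below 2^31
  for (b in bytes) h <- (h * 31 + b) %% p
  as.integer(h)
}

# Argmax over per-species scores with explicit tie policy.
# ties = "first": lexicographically smallest species id (species columns are
# sorted) — the deterministic headline call.
# ties = "random": uniform among tied species — used inside bootstrap trials
# so symmetric ties contribute symmetric votes.
.argmaxSpecies <- function(scores, ties = c("first", "random")) {
  ties <- match.arg(ties)
  # exact equality: genuinely tied species arise from identical count
  # profiles, which produce bit-identical column sums
  idx <- which(scores == max(scores))
  if (length(idx) == 1L || ties == "first") idx[1L]
  else idx[sample.int(length(idx), 1L)]
}

#' Classify a query sequence with bootstrap confidence
#'
#' The point assignment is the species maximizing the log joint probability
#' of the query's distinct words (ties broken toward the lexicographically
#' smallest species key); its full lineage is reported. Confidence is then
#' estimated by re-classifying \code{nBootstrap} random subsets of
#' \code{max(1, floor(W / subsampleDivisor))} distinct words (W = number of
#' distinct query words; drawn without replacement by default): the
#' confidence at a rank is the percentage of trials whose winning species
#' agrees with the point assignment's lineage down to that rank. Because a
#' trial that agrees at a rank necessarily agrees at all shallower ranks,
#' confidences are non-increasing from phylum to species.
#'
#' All randomness comes from a substream derived from
#' \code{(config@seed, queryId)}, so results do not depend on the order in
#' which queries are processed.
#'
#' @param model A \linkS4class{WordModel}.
#' @param queryId Query identifier (also seeds the RNG substream).
#' @param sequence Query sequence (character or \code{DNAString}), length
#'   >= k.
#' @param config A \linkS4class{ClassifierConfig}.
#' @return A \linkS4class{ClassificationResult}.
#' @export
classifySequence <- function(model, queryId, sequence,
                             config = classifierConfig()) {
  stopifnot(is(model, "WordModel"), is(config, "ClassifierConfig"))
  if (config@k != model@k)
    stop("classifySequence: config k (", config@k,
         ") does not match model k (", model@k, ")")
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  codes <- .wordCodes(sequence, model@k)
  if (config@checkReverseComplement) {
    rcCodes <- .wordCodes(Biostrings::reverseComplement(sequence), model@k)
    if (length(rcCodes) &&
        (!length(codes) ||
         max(.scoreCodes(model, rcCodes)) > max(.scoreCodes(model, codes))))
      codes <- rcCodes
  }
  if (!length(codes))
    stop("classifySequence: query '", queryId,
         "' has no scorable (ACGT-only) words")

  fullScores <- .scoreCodes(model, codes)
  point <- .argmaxSpecies(fullScores, ties = "first")
  pointLineage <- model@lineages[point, ]

  W <- length(codes)
  subSize <- max(1L, W %/% config@subsampleDivisor)
  agree <- integer(length(RANKS))

  set.seed(.deriveSeed(config@seed, queryId))
  for (trial in seq_len(config@nBootstrap)) {
    drawn <- codes[sample.int(W, subSize, replace = config@bootstrapReplace)]
    winner <- .argmaxSpecies(.scoreCodes(model, drawn), ties = "random")
    depth <- match(FALSE,
                   model@lineages[winner, ] == pointLineage,
                   nomatch = length(RANKS) + 1L) - 1L
    if (depth > 0L) agree[seq_len(depth)] <- agree[seq_len(depth)] + 1L
  }

  confidence <- setNames(100 * agree / config@nBootstrap, RANKS)
  new("ClassificationResult", queryId = queryId,
      lineage = setNames(as.character(pointLineage), RANKS),
      confidence = confidence,
      pass = confidence >= config@confidenceThreshold,
      threshold = config@confidenceThreshold)
}
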