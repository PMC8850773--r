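# C-locale (radix) sorting so model layout and seeded draws are
# reproducible regardless of the session's collation locale.
.sortC <- function(x) sort(x, method = "radix")
.orderC <- function(x) order(x, method = "radix")

#' Train the naive Bayesian k-mer classifier
#'
#' Builds a \linkS4class{WordModel} from a reference set: for every word of
#' length \code{k} it counts the training sequences containing the word at
#' least once, globally and per species. Species are keyed by the
#' (genus, species) pair and require complete lineages. Species represented
#' by a single sequence are permitted (whether they exist is a curation
#' decision).
#'
#' @param refset A non-empty \linkS4class{ReferenceSet} with complete
#'   lineages; every sequence must be at least \code{k} long.
#' @param config A \linkS4class{ClassifierConfig} (only \code{k} is used at
#'   training time).
#' @return A \linkS4class{WordModel}.
#' @seealso [classifySequence()], [removeSequence()], [addSequence()]
#' @export
trainClassifier <- function(refset, config = classifierConfig()) {
  stopifnot(is(refset, "ReferenceSet"), is(config, "ClassifierConfig"))
  if (!length(refset)) stop("trainClassifier: empty reference set")
  if (!all(isCompleteLineage(taxonomy(refset))))
    stop("trainClassifier: all training lineages must be complete")
  k <- config@k
  w <- Biostrings::width(sequences(refset))
  if (any(w < k))
    stop("trainClassifier: sequence(s) shorter than k = ", k, ": ",
         paste(utils::head(seqIds(refset)[w < k], 5L), collapse = ", "))

  key <- speciesKey(refset)
  speciesIds <- .sortC(unique(key))
  spIndex <- match(key, speciesIds)
  lineages <- taxonomy(refset)[match(speciesIds, key), , drop = FALSE]
  rownames(lineages) <- speciesIds

  seqWords <- .wordCodeList(sequences(refset), k)
  # canonical (sorted-id) order so incremental remove/add round-trips
  # reproduce the trained model field-by-field
  ord <- .orderC(names(seqWords))
  seqWords <- seqWords[ord]
  seqSpecies <- setNames(key[ord], names(seqWords))

  nWords <- as.integer(4^k)
  m <- matrix(0L, nrow = nWords, ncol = length(speciesIds),
              dimnames = list(NULL, speciesIds))
  for (i in seq_along(key)) {
    codes <- seqWords[[seqIds(refset)[i]]]
    m[codes, spIndex[i]] <- m[codes, spIndex[i]] + 1L
  }
  n <- as.integer(rowSums(m))
  M <- vapply(split(seq_along(key), factor(key, levels = speciesIds)),
              length, integer(1L))

  new("WordModel", k = k, speciesIds = speciesIds, lineages = lineages,
      M = M, N = length(refset), m = m, n = n,
      seqWords = seqWords, seqSpecies = seqSpecies)
}

# Smoothed log P(w|s) summed over the given word codes, for every species.
# Returns a named numeric vector of per-species log joint probabilities.
# `codes` may contain duplicates (multiset semantics for with-replacement
# bootstrap draws); standard callers pass distinct codes.
.scoreCodes <- function(model, codes) {
  pw <- (model@n[codes] + 0.5) / (model@N + 1)
  A <- model@m[codes, , drop = FALSE] + pw  # pw recycles down columns
  colSums(log(A)) - length(codes) * log(model@M + 1)
}

#' Score a query word set against every species
#'
#' Computes, for each species \eqn{s}, the log joint probability
#' \eqn{\sum_{w} \log P(w|s)} over the distinct words of the query, with
#' Wang-style smoothing (see \linkS4class{WordModel}). Duplicate words in
#' the input are collapsed, so abundance never affects the score.
#'
#' @param model A \linkS4class{WordModel}.
#' @param kmers Character vector of k-mers (duplicates allowed), or a named
#'   abundance vector as returned by [extractKmers()].
#' @return Named numeric vector of per-species log probabilities.
#' @export
scoreQuery <- function(model, kmers) {
  if (!is.character(kmers)) kmers <- names(kmers)
  if (!length(kmers)) stop("scoreQuery: empty word set")
  codes <- .encodeWords(unique(kmers), model@k)
  codes <- codes[!is.na(codes)]
  if (!length(codes)) stop("scoreQuery: no scorable (ACGT-only) words")
  .scoreCodes(model, codes)
}

#' Incrementally remove / re-add a training sequence
#'
#' \code{removeSequence} subtracts one training sequence's word presences
#' from the model; when that was a species' last sequence the species is
#' dropped from the model entirely. \code{addSequence} is its exact
#' inverse: re-adding a removed record restores the model field-by-field,
#' and \code{removeSequence(trainClassifier(all), x)} equals
#' \code{trainClassifier(all minus x)}. These two operations make exhaustive
#' leave-one-out linear in the dataset instead of quadratic.
#'
#' @param model A \linkS4class{WordModel}.
#' @param seqId Id of a sequence currently in the model.
#' @return The updated \linkS4class{WordModel}.
#' @export
removeSequence <- function(model, seqId) {
  codes <- model@seqWords[[seqId]]
  if (is.null(codes))
    stop("removeSequence: unknown seq_id '", seqId, "'")
  sp <- model@seqSpecies[[seqId]]
  model@m[codes, sp] <- model@m[codes, sp] - 1L
  model@n[codes] <- model@n[codes] - 1L
  model@M[[sp]] <- model@M[[sp]] - 1L
  model@N <- model@N - 1L
  model@seqWords[[seqId]] <- NULL
  model@seqSpecies <- model@seqSpecies[names(model@seqSpecies) != seqId]
  if (model@M[[sp]] == 0L) {
    keep <- model@speciesIds != sp
    model@speciesIds <- model@speciesIds[keep]
    model@lineages <- model@lineages[keep, , drop = FALSE]
    model@M <- model@M[keep]
    model@m <- model@m[, keep, drop = FALSE]
  }
  model
}

#' @rdname removeSequence
#' @param sequence The record's sequence (character or \code{DNAString});
#'   required by \code{addSequence}.
#' @param lineage The record's complete six-rank lineage (named character
#'   vector).
#' @export
addSequence <- function(model, seqId, sequence, lineage) {
  if (!is.null(model@seqWords[[seqId]]))
    stop("addSequence: seq_id '", seqId, "' is already in the model")
  if (!all(isCompleteLineage(lineage)))
    stop("addSequence: lineage must be complete")
  lineage <- lineage[RANKS]
  sp <- paste(lineage[["genus"]], lineage[["species"]], sep = "|")
  codes <- .wordCodes(sequence, model@k)
  if (!sp %in% model@speciesIds) {
    newIds <- .sortC(c(model@speciesIds, sp))
    m2 <- cbind(model@m,
                matrix(0L, nrow = nrow(model@m), ncol = 1L,
                       dimnames = list(NULL, sp)))
    model@m <- m2[, newIds, drop = FALSE]
    lin2 <- rbind(model@lineages,
                  matrix(lineage, nrow = 1L, dimnames = list(sp, RANKS)))
    model@lineages <- lin2[newIds, , drop = FALSE]
    model@M <- c(model@M, setNames(0L, sp))[newIds]
    model@speciesIds <- newIds
  }
  model@m[codes, sp] <- model@m[codes, sp] + 1L
  model@n[codes] <- model@n[codes] + 1L
  model@M[[sp]] <- model@M[[sp]] + 1L
  model@N <- model@N + 1L
  # re-insert bookkeeping in canonical sorted-id order
  allIds <- .sortC(c(names(model@seqWords), seqId))
  sw <- model@seqWords
  sw[[seqId]] <- codes
  model@seqWords <- sw[allIds]
  model@seqSpecies <- c(model@seqSpecies, setNames(sp, seqId))[allIds]
  model
}
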