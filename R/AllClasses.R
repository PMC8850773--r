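#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet oligonucleotideFrequency width reverseComplement
#' @importFrom stats median runif setNames
#' @importFrom utils write.table read.table packageVersion head
NULL

setOldClass("data.frame")

#' ReferenceSet: marker sequences with six-rank taxonomy
#'
#' Container pairing a set of marker sequences (a
#' \linkS4class{DNAStringSet} named by sequence id) with a six-rank lineage
#' table (character matrix, rows parallel to the sequences). This is the
#' unit that curation, training and cross-validation operate on.
#'
#' @slot marker Single marker name, e.g. \code{"matK"}.
#' @slot sequences \code{DNAStringSet} named by unique sequence ids.
#' @slot taxonomy Character matrix with columns \code{taxonomicRanks()} and
#'   rownames equal to the sequence ids; \code{NA} marks a missing rank.
#'
#' @seealso [joinReference()], [filterCompleteTaxonomy()], [balanceSet()],
#'   [trainClassifier()]
#' @export
setClass("ReferenceSet",
  representation(marker = "character",
                 sequences = "DNAStringSet",
                 taxonomy = "matrix"))

setValidity("ReferenceSet", function(object) {
  msg <- character()
  if (length(object@marker) != 1L || is.na(object@marker) ||
      !nzchar(object@marker))
    msg <- c(msg, "marker must be a single non-empty string")
  ids <- names(object@sequences)
  if (length(object@sequences)) {
    if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
      msg <- c(msg, "all sequences must be named by a non-empty seq_id")
    else if (anyDuplicated(ids))
      msg <- c(msg, paste0("duplicate seq_id: ",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (any(Biostrings::width(object@sequences) < 1L))
      msg <- c(msg, "all sequences must have length >= 1")
  }
  if (!identical(colnames(object@taxonomy), RANKS))
    msg <- c(msg, "taxonomy columns must be the six ranks")
  if (nrow(object@taxonomy) != length(object@sequences) ||
      (length(object@sequences) &&
       !identical(rownames(object@taxonomy), ids)))
    msg <- c(msg, "taxonomy rows must parallel the sequence ids")
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceSet
#'
#' @param marker Marker name.
#' @param sequences Named \code{DNAStringSet} (or named character vector of
#'   DNA strings).
#' @param taxonomy Character matrix of lineages (columns =
#'   \code{taxonomicRanks()}, rownames = sequence ids), or a character
#'   vector of Greengenes-style lineage strings named by sequence id.
#' @return A \linkS4class{ReferenceSet}.
#' @export
ReferenceSet <- function(marker, sequences, taxonomy) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(dim(taxonomy)))
    taxonomy <- parseLineages(taxonomy)
  taxonomy <- taxonomy[names(sequences), , drop = FALSE]
  new("ReferenceSet", marker = marker, sequences = sequences,
      taxonomy = taxonomy)
}

#' ClassifierConfig: tuning parameters of the naive Bayesian classifier
#'
#' @slot k Word (k-mer) size; default 8.
#' @slot nBootstrap Number of bootstrap trials per query; default 100.
#' @slot subsampleDivisor Each trial draws \code{max(1, floor(W/divisor))}
#'   of the query's W distinct words; default 8 (one eighth).
#' @slot confidenceThreshold Bootstrap percentage above which an assignment
#'   is trusted; default 80.
#' @slot seed Global seed; every query derives its own substream from
#'   \code{(seed, query_id)} so results are order-independent.
#' @slot bootstrapReplace Draw bootstrap words with replacement instead of
#'   without; default \code{FALSE}.
#' @slot checkReverseComplement Also score the reverse complement of each
#'   query and keep the better-scoring orientation; default \code{FALSE}.
#' @export
setClass("ClassifierConfig",
  representation(k = "integer", nBootstrap = "integer",
                 subsampleDivisor = "integer",
                 confidenceThreshold = "numeric", seed = "integer",
                 bootstrapReplace = "logical",
                 checkReverseComplement = "logical"))

setValidity("ClassifierConfig", function(object) {
  msg <- character()
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (object@nBootstrap < 1L) msg <- c(msg, "nBootstrap must be >= 1")
  if (object@subsampleDivisor < 1L)
    msg <- c(msg, "subsampleDivisor must be >= 1")
  if (object@confidenceThreshold < 0 || object@confidenceThreshold > 100)
    msg <- c(msg, "confidenceThreshold must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' @rdname ClassifierConfig-class
#' @param k,nBootstrap,subsampleDivisor,confidenceThreshold,seed,bootstrapReplace,checkReverseComplement
#'   See the class slots.
#' @return A \linkS4class{ClassifierConfig}.
#' @export
classifierConfig <- function(k = 8L, nBootstrap = 100L,
                             subsampleDivisor = 8L,
                             confidenceThreshold = 80,
                             seed = 1L,
                             bootstrapReplace = FALSE,
                             checkReverseComplement = FALSE) {
  new("ClassifierConfig", k = as.integer(k),
      nBootstrap = as.integer(nBootstrap),
      subsampleDivisor = as.integer(subsampleDivisor),
      confidenceThreshold = as.numeric(confidenceThreshold),
      seed = as.integer(seed),
      bootstrapReplace = isTRUE(bootstrapReplace),
      checkReverseComplement = isTRUE(checkReverseComplement))
}

#' BalanceConfig: per-species sequence count bounds
#'
#' Species with fewer than \code{minPerSpecies} sequences are removed
#' entirely; species with more than \code{maxPerSpecies} are randomly
#' downsampled (without replacement) to \code{maxPerSpecies}. The presets
#' \code{"2-20"} and \code{"5-20"} are the two balancing regimes used for
#' marker evaluation.
#'
#' @slot minPerSpecies,maxPerSpecies Integer bounds.
#' @slot seed Seed for the downsampling draws.
#' @export
setClass("BalanceConfig",
  representation(minPerSpecies = "integer", maxPerSpecies = "integer",
                 seed = "integer"))

setValidity("BalanceConfig", function(object) {
  if (object@minPerSpecies < 1L) return("minPerSpecies must be >= 1")
  if (object@maxPerSpecies < object@minPerSpecies)
    return("maxPerSpecies must be >= minPerSpecies")
  TRUE
})

#' @rdname BalanceConfig-class
#' @param preset One of \code{"2-20"}, \code{"5-20"}, or \code{NULL} to give
#'   explicit bounds.
#' @param minPerSpecies,maxPerSpecies Explicit bounds (ignored when a preset
#'   is given).
#' @param seed Seed for the subsampling draws.
#' @return A \linkS4class{BalanceConfig}.
#' @examples
#' balanceConfig("5-20", seed = 1)
#' @export
balanceConfig <- function(preset = NULL, minPerSpecies = 2L,
                          maxPerSpecies = 20L, seed = 1L) {
  if (!is.null(preset)) {
    bounds <- switch(preset,
      "2-20" = c(2L, 20L),
      "5-20" = c(5L, 20L),
      stop("unknown balance preset: ", preset))
    minPerSpecies <- bounds[1L]
    maxPerSpecies <- bounds[2L]
  }
  new("BalanceConfig", minPerSpecies = as.integer(minPerSpecies),
      maxPerSpecies = as.integer(maxPerSpecies), seed = as.integer(seed))
}

#' WordModel: trained state of the naive Bayesian k-mer classifier
#'
#' Words of length \code{k} over ACGT are encoded as integers 1..4^k
#' (lexicographic / base-4, A<C<G<T). Training records, for each word, the
#' number of training sequences containing it at least once, globally
#' (\code{n}) and per species (\code{m}); abundance beyond presence is not
#' used. The smoothed probabilities are
#' \deqn{P(w) = (n(w) + 0.5) / (N + 1)}
#' \deqn{P(w | s) = (m_s(w) + P(w)) / (M_s + 1)}
#' where N is the total number of training sequences and M_s the number in
#' species s.
#'
#' @slot k Word size.
#' @slot speciesIds Sorted species keys (\code{"genus|species"}).
#' @slot lineages Character matrix (one row per species, six rank columns).
#' @slot M Integer vector of per-species sequence counts (named).
#' @slot N Total number of training sequences.
#' @slot m Integer matrix, 4^k rows (words) by species columns: per-species
#'   per-word presence counts.
#' @slot n Integer vector of global per-word presence counts.
#' @slot seqWords List, per training sequence id, of the sorted integer
#'   codes of its distinct words (enables exact incremental removal).
#' @slot seqSpecies Character vector mapping sequence id to species key.
#' @export
setClass("WordModel",
  representation(k = "integer", speciesIds = "character",
                 lineages = "matrix", M = "integer", N = "integer",
                 m = "matrix", n = "integer", seqWords = "list",
                 seqSpecies = "character"))

setValidity("WordModel", function(object) {
  msg <- character()
  if (sum(object@M) != object@N)
    msg <- c(msg, "species sequence counts must sum to N")
  if (ncol(object@m) != length(object@speciesIds))
    msg <- c(msg, "word-count matrix must have one column per species")
  if (length(object@seqWords) != object@N)
    msg <- c(msg, "one word list per training sequence required")
  if (is.unsorted(object@speciesIds, strictly = TRUE))
    msg <- c(msg, "speciesIds must be strictly sorted")
  if (length(msg)) msg else TRUE
})

#' ClassificationResult: one query's assignment with bootstrap confidence
#'
#' @slot queryId Query sequence id.
#' @slot lineage Assigned six-rank lineage (named character vector).
#' @slot confidence Bootstrap confidence (0-100) at each rank, guaranteed
#'   non-increasing from phylum to species.
#' @slot pass Logical: confidence >= threshold, per rank.
#' @slot threshold The threshold the flags were computed against.
#' @export
setClass("ClassificationResult",
  representation(queryId = "character", lineage = "character",
                 confidence = "numeric", pass = "logical",
                 threshold = "numeric"))

#' SimConfig: parameters of the hierarchical marker simulator
#'
#' The simulator emulates the barcoding-gap structure of real marker
#' databases: a single phylum/class/order, families with independent random
#' ancestral sequences, genus ancestors derived by per-site substitution at
#' rate \code{dGenus}, species ancestors at \code{dSpecies}, and individual
#' sequences at \code{dIntra}. Problematic genera have \code{dSpecies}
#' forced to 0 (zero interspecific divergence) on the listed markers,
#' reproducing the collapsed-genus failure mode.
#'
#' @slot markers Named integer vector: marker name -> sequence length (bp).
#' @slot nFamilies,generaPerFamily,speciesPerGenus Integer tree shape.
#' @slot seqsPerSpecies Integer vector of length 1 (fixed count) or 2
#'   (inclusive range sampled uniformly per species).
#' @slot dFamily,dGenus,dSpecies,dIntra Per-site substitution
#'   probabilities; must satisfy dIntra < dSpecies < dGenus < dFamily.
#'   Family roots are drawn independently and uniformly, so dFamily acts as
#'   an upper-bound declaration rather than a generative rate.
#' @slot problematic \code{data.frame} with columns \code{genus} (genus
#'   name, e.g. \code{"Gen0101"}) and \code{marker} (\code{NA} = all
#'   markers): genera whose interspecific divergence is forced to zero.
#' @slot singletonFraction Fraction of species emitted with exactly one
#'   sequence (to exercise the balancing filters).
#' @slot seed Simulation seed.
#' @export
setClass("SimConfig",
  representation(markers = "integer", nFamilies = "integer",
                 generaPerFamily = "integer", speciesPerGenus = "integer",
                 seqsPerSpecies = "integer", dFamily = "numeric",
                 dGenus = "numeric", dSpecies = "numeric",
                 dIntra = "numeric", problematic = "data.frame",
                 singletonFraction = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@markers) < 1L || is.null(names(object@markers)) ||
      any(object@markers < 1L))
    msg <- c(msg, "markers must be a named vector of positive lengths")
  if (object@nFamilies < 1L || object@generaPerFamily < 1L ||
      object@speciesPerGenus < 1L)
    msg <- c(msg, "tree shape counts must all be >= 1")
  if (!length(object@seqsPerSpecies) %in% 1:2 ||
      any(object@seqsPerSpecies < 1L))
    msg <- c(msg, "seqsPerSpecies must be a positive count or range")
  p <- c(object@dFamily, object@dGenus, object@dSpecies, object@dIntra)
  if (any(p < 0) || any(p > 1))
    msg <- c(msg, "substitution probabilities must lie in [0, 1]")
  if (!(object@dIntra < object@dSpecies && object@dSpecies < object@dGenus &&
        object@dGenus < object@dFamily))
    msg <- c(msg, "require dIntra < dSpecies < dGenus < dFamily")
  if (object@singletonFraction < 0 || object@singletonFraction > 1)
    msg <- c(msg, "singletonFraction must lie in [0, 1]")
  if (!all(c("genus", "marker") %in% colnames(object@problematic)))
    msg <- c(msg, "problematic must have columns genus, marker")
  if (length(msg)) msg else TRUE
})
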