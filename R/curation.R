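#' Keep only records with a complete six-rank lineage
#'
#' Mirrors the first curation filter applied to marker databases: records
#' lacking any of the six rank labels cannot support per-rank evaluation
#' and are removed. Idempotent.
#'
#' @param refset A \linkS4class{ReferenceSet}.
#' @return The filtered \linkS4class{ReferenceSet} (possibly empty).
#' @export
filterCompleteTaxonomy <- function(refset) {
  keep <- isCompleteLineage(taxonomy(refset))
  removed <- sum(!keep)
  if (removed)
    message("filterCompleteTaxonomy [", markerName(refset), "]: removed ",
            removed, " record(s) with incomplete taxonomy")
  refset[keep]
}

#' Drop short sequences
#'
#' Removes records shorter than
#' \code{max(minLen, minFracOfMedian * median(length))} — a hard floor
#' (50 bp by default, matching the usual minimum useful barcode fragment)
#' combined with a configurable fraction-of-median rule standing in for
#' manual "almost full-length" triage.
#'
#' @param refset A non-empty \linkS4class{ReferenceSet}.
#' @param minLen Hard minimum length in bp (default 50).
#' @param minFracOfMedian Fraction of the set's median length (default 0.5).
#' @return The filtered \linkS4class{ReferenceSet}.
#' @export
filterLength <- function(refset, minLen = 50L, minFracOfMedian = 0.5) {
  stopifnot(minLen >= 1L, minFracOfMedian > 0, minFracOfMedian <= 1)
  if (!length(refset)) stop("filterLength: empty reference set")
  w <- Biostrings::width(sequences(refset))
  threshold <- max(minLen, minFracOfMedian * stats::median(w))
  keep <- w >= threshold
  message("filterLength [", markerName(refset), "]: threshold ",
          format(threshold), " bp, removed ", sum(!keep), " record(s)")
  refset[keep]
}

#' Balance per-species sequence counts
#'
#' Species (identified by the genus/species pair) with fewer than
#' \code{minPerSpecies} sequences are dropped entirely; species with more
#' than \code{maxPerSpecies} are downsampled uniformly at random without
#' replacement. Record order of the retained sequences is preserved, and
#' the result is fully determined by the config seed (species are visited
#' in sorted key order, so input order is irrelevant).
#'
#' @param refset A \linkS4class{ReferenceSet}.
#' @param config A \linkS4class{BalanceConfig}, e.g.
#'   \code{balanceConfig("5-20", seed = 1)}.
#' @return The balanced \linkS4class{ReferenceSet}.
#' @export
balanceSet <- function(refset, config) {
  stopifnot(is(config, "BalanceConfig"))
  validObject(config)
  key <- speciesKey(refset)
  ids <- seqIds(refset)
  bySpecies <- split(ids, key)
  bySpecies <- bySpecies[order(names(bySpecies))]
  keep <- character()
  nDroppedSpecies <- 0L
  set.seed(config@seed)
  for (sp in names(bySpecies)) {
    spIds <- bySpecies[[sp]]
    n <- length(spIds)
    if (n < config@minPerSpecies) {
      nDroppedSpecies <- nDroppedSpecies + 1L
    } else if (n > config@maxPerSpecies) {
      keep <- c(keep, sample(sort(spIds), config@maxPerSpecies))
    } else {
      keep <- c(keep, spIds)
    }
  }
  message("balanceSet [", markerName(refset), "]: ", nDroppedSpecies,
          " species below ", config@minPerSpecies, " sequence(s) dropped, ",
          length(ids) - length(keep), " of ", length(ids),
          " sequences removed")
  refset[ids %in% keep]
}

#' Summarize taxonomic representation
#'
#' Counts the distinct taxa at every rank plus the number of sequences —
#' the per-marker representation table used to compare marker databases.
#' Species are counted by the (genus, species) pair.
#'
#' @param refset A \linkS4class{ReferenceSet} with complete lineages.
#' @return One-row \code{data.frame} with columns \code{marker},
#'   \code{sequences}, \code{species}, \code{genera}, \code{families},
#'   \code{orders}, \code{classes}, \code{phyla}.
#' @export
datasetSummary <- function(refset) {
  tax <- taxonomy(refset)
  nU <- function(col) length(unique(tax[, col]))
  data.frame(
    marker = markerName(refset),
    sequences = length(refset),
    species = if (length(refset)) length(unique(speciesKey(refset))) else 0L,
    genera = if (length(refset)) nU("genus") else 0L,
    families = if (length(refset)) nU("family") else 0L,
    orders = if (length(refset)) nU("order") else 0L,
    classes = if (length(refset)) nU("class") else 0L,
    phyla = if (length(refset)) nU("phylum") else 0L,
    stringsAsFactors = FALSE)
}
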