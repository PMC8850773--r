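#' @name ReferenceSet-accessors
#' @title Accessors for ReferenceSet objects
#' @param x,object A \linkS4class{ReferenceSet}.
#' @param i Index: integer, logical, or sequence-id character vector.
#' @param j,...,drop Ignored (present for generic compatibility).
#' @return \code{markerName}: the marker name; \code{sequences}: the
#'   \code{DNAStringSet}; \code{taxonomy}: the lineage matrix;
#'   \code{seqIds}: the sequence ids; \code{speciesKey}: per-record species
#'   keys (\code{"genus|species"} — species identity is the pair, so shared
#'   epithets across genera never collide).
NULL

#' @rdname ReferenceSet-accessors
#' @export
setGeneric("markerName", function(x) standardGeneric("markerName"))
#' @rdname ReferenceSet-accessors
#' @export
setMethod("markerName", "ReferenceSet", function(x) x@marker)

#' @rdname ReferenceSet-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname ReferenceSet-accessors
#' @export
setMethod("sequences", "ReferenceSet", function(x) x@sequences)

#' @rdname ReferenceSet-accessors
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))
#' @rdname ReferenceSet-accessors
#' @export
setMethod("taxonomy", "ReferenceSet", function(x) x@taxonomy)

#' @rdname ReferenceSet-accessors
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))
#' @rdname ReferenceSet-accessors
#' @export
setMethod("seqIds", "ReferenceSet", function(x) names(x@sequences))

#' @rdname ReferenceSet-accessors
#' @export
setGeneric("speciesKey", function(x) standardGeneric("speciesKey"))
#' @rdname ReferenceSet-accessors
#' @export
setMethod("speciesKey", "ReferenceSet", function(x) {
  paste(x@taxonomy[, "genus"], x@taxonomy[, "species"], sep = "|")
})

#' @rdname ReferenceSet-accessors
#' @export
setMethod("length", "ReferenceSet", function(x) length(x@sequences))

#' @rdname ReferenceSet-accessors
#' @export
setMethod("[", "ReferenceSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  new("ReferenceSet", marker = x@marker,
      sequences = x@sequences[i],
      taxonomy = x@taxonomy[i, , drop = FALSE])
})

setMethod("show", "ReferenceSet", function(object) {
  tax <- object@taxonomy
  nsp <- length(unique(paste(tax[, "genus"], tax[, "species"], sep = "|")))
  cat("ReferenceSet for marker '", object@marker, "'\n", sep = "")
  cat("  ", length(object@sequences), " sequences, ", nsp,
      " species, ", length(unique(tax[, "genus"])), " genera\n", sep = "")
  if (length(object@sequences)) {
    w <- Biostrings::width(object@sequences)
    cat("  sequence length: ", min(w), "-", max(w),
        " bp (median ", stats::median(w), ")\n", sep = "")
  }
})

setMethod("show", "ClassifierConfig", function(object) {
  cat("ClassifierConfig: k=", object@k, ", bootstrap=", object@nBootstrap,
      " x 1/", object@subsampleDivisor, " of words, threshold=",
      object@confidenceThreshold, "%, seed=", object@seed, "\n", sep = "")
})

setMethod("show", "WordModel", function(object) {
  cat("WordModel (naive Bayesian k-mer classifier)\n")
  cat("  k=", object@k, ", ", object@N, " training sequences, ",
      length(object@speciesIds), " species\n", sep = "")
  cat("  words observed: ", sum(object@n > 0L), " / ", length(object@n),
      "\n", sep = "")
})

setMethod("show", "ClassificationResult", function(object) {
  cat("ClassificationResult for query '", object@queryId, "'\n", sep = "")
  for (r in RANKS) {
    cat(sprintf("  %-8s %-28s %3d%% %s\n", r, object@lineage[[r]],
                as.integer(round(object@confidence[[r]])),
                if (object@pass[[r]]) "" else "(below threshold)"))
  }
})
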