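#' Exhaustive leave-one-out cross-validation
#'
#' Classifies every record of a reference set with a model trained on all
#' the other records. The full model is trained once and each query's
#' sequence is removed incrementally before classification
#' ([removeSequence()]), which is exactly equivalent to retraining from
#' scratch on N-1 records but linear instead of quadratic in N. Each query
#' draws its bootstrap randomness from a substream derived from
#' \code{(config@seed, seq_id)}, so the output is independent of record
#' order and reproducible.
#'
#' Records shorter than \code{k} (or without a single ACGT-only window)
#' cannot be classified; they are reported with a warning and returned as
#' unclassified rows (confidence 0 at every rank) rather than dropped.
#'
#' @param refset A \linkS4class{ReferenceSet} with complete lineages. A
#'   warning is issued if any species has fewer than 2 sequences (its
#'   record can never be recovered, since leaving it out removes the
#'   species from the model).
#' @param config A \linkS4class{ClassifierConfig}.
#' @return A \code{data.frame} with one row per record, in input order:
#'   \code{query_id}, \code{classified}, six \code{true_*} columns, six
#'   \code{pred_*} columns, six \code{conf_*} columns and six
#'   \code{pass_*} columns.
#' @export
leaveOneOut <- function(refset, config = classifierConfig()) {
  stopifnot(is(refset, "ReferenceSet"))
  if (!length(refset)) stop("leaveOneOut: empty reference set")
  key <- speciesKey(refset)
  if (any(table(key) < 2L))
    warning("leaveOneOut: ", sum(table(key) < 2L), " species have a ",
            "single sequence; their records cannot be recovered ",
            "(balance the set first)")
  trainable <- Biostrings::width(sequences(refset)) >= config@k
  if (!all(trainable))
    warning("leaveOneOut: ", sum(!trainable), " record(s) shorter than ",
            "k = ", config@k, " excluded from training and reported as ",
            "unclassifiable: ",
            paste(utils::head(seqIds(refset)[!trainable], 5L),
                  collapse = ", "))
  model <- trainClassifier(refset[trainable], config)
  ids <- seqIds(refset)
  tax <- taxonomy(refset)
  seqs <- sequences(refset)

  blank <- setNames(rep(NA_character_, 6L), RANKS)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    res <- if (!trainable[i]) {
      simpleError("sequence shorter than k")
    } else tryCatch({
      reduced <- removeSequence(model, id)
      classifySequence(reduced, id, seqs[[i]], config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("leaveOneOut: query '", id, "' unclassifiable: ",
              conditionMessage(res))
      rows[[i]] <- data.frame(
        query_id = id, classified = FALSE,
        t(setNames(tax[i, ], paste0("true_", RANKS))),
        t(setNames(blank, paste0("pred_", RANKS))),
        t(setNames(rep(0, 6L), paste0("conf_", RANKS))),
        t(setNames(rep(FALSE, 6L), paste0("pass_", RANKS))),
        stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        query_id = id, classified = TRUE,
        t(setNames(tax[i, ], paste0("true_", RANKS))),
        t(setNames(res@lineage, paste0("pred_", RANKS))),
        t(setNames(res@confidence, paste0("conf_", RANKS))),
        t(setNames(res@pass, paste0("pass_", RANKS))),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read leave-one-out results as TSV
#'
#' @param loo A leave-one-out \code{data.frame} from [leaveOneOut()].
#' @param path Output path.
#' @return Invisibly, \code{path} (\code{writeLoo}); the \code{data.frame}
#'   (\code{readLoo}).
#' @export
writeLoo <- function(loo, path) {
  utils::write.table(loo, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeLoo
#' @export
readLoo <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}
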