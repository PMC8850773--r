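# Deterministic FNV-1a-style content hash of a file (hex string). Used for
# the run manifest; not cryptographic.
.contentHash <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  h <- 2166136261
  p <- 2^32
  for (b in as.integer(bytes)) {
    h <- (h + b) %% p          # additive mix
    h <- (h * 16777619) %% p   # FNV prime
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full marker-evaluation pipeline
#'
#' One-command binding of all stages: read each marker's FASTA + taxonomy,
#' apply the completeness and length filters, balance per-species counts,
#' run exhaustive leave-one-out classification, and write every evaluation
#' summary plus a machine-readable manifest. Stage order and outputs
#' mirror the marker-evaluation workflow: per marker a curated-set summary,
#' leave-one-out TSV, bootstrap-confidence histograms, per-rank accuracy,
#' per-rank confusion matrices, species and genus F1 tables and the
#' cumulative genus-F1 curve; across markers the genus scenario table.
#'
#' All outputs are deterministic given the seeds: the manifest records
#' package version, parameters, seeds and input checksums, and contains no
#' timestamps, so re-running with identical inputs reproduces every output
#' byte for byte.
#'
#' @param fastaFiles,taxFiles Named character vectors (marker -> path).
#' @param outDir Output directory.
#' @param minLen,minFracOfMedian Length-filter parameters
#'   (see [filterLength()]).
#' @param balance A \linkS4class{BalanceConfig} (default preset
#'   \code{"5-20"}, seed 1).
#' @param classifier A \linkS4class{ClassifierConfig}.
#' @param threshold Trust threshold for evaluation (default:
#'   the classifier's confidence threshold).
#' @param f1Cutoff Poor-F1 cutoff for genus categorization (default 0.25).
#' @param force Overwrite an existing non-empty \code{outDir}
#'   (default \code{FALSE}).
#' @return Invisibly, a list with the in-memory results
#'   (\code{summaries}, \code{loo}, \code{genusF1}, \code{scenarios},
#'   \code{manifest}) and \code{outDir}.
#' @export
runPipeline <- function(fastaFiles, taxFiles, outDir,
                        minLen = 50L, minFracOfMedian = 0.5,
                        balance = balanceConfig("5-20", seed = 1L),
                        classifier = classifierConfig(),
                        threshold = classifier@confidenceThreshold,
                        f1Cutoff = 0.25, force = FALSE) {
  stopifnot(length(fastaFiles) >= 1L,
            identical(names(fastaFiles), names(taxFiles)))
  missing <- c(fastaFiles[!file.exists(fastaFiles)],
               taxFiles[!file.exists(taxFiles)])
  if (length(missing))
    stop("runPipeline: input file(s) not found: ",
         paste(missing, collapse = ", "))
  if (dir.exists(outDir) && length(list.files(outDir)) && !force)
    stop("runPipeline: output directory ", outDir,
         " is not empty (use force = TRUE to overwrite)")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  markers <- names(fastaFiles)
  summaries <- list(); looAll <- list(); genusTables <- list()
  dropLog <- list()
  for (marker in markers) {
    message("== pipeline stage: prepare [", marker, "] ==")
    seqs <- readFasta(fastaFiles[[marker]])
    tax <- readTaxonomy(taxFiles[[marker]])
    rs <- joinReference(seqs, tax, marker)
    n0 <- length(rs)
    rs <- filterCompleteTaxonomy(rs)
    n1 <- length(rs)
    rs <- filterLength(rs, minLen, minFracOfMedian)
    n2 <- length(rs)
    message("== pipeline stage: balance [", marker, "] ==")
    rs <- balanceSet(rs, balance)
    n3 <- length(rs)
    dropLog[[marker]] <- list(joined = n0, complete_taxonomy = n1,
                              length_filter = n2, balanced = n3)
    summaries[[marker]] <- datasetSummary(rs)

    message("== pipeline stage: leave-one-out [", marker, "] ==")
    loo <- leaveOneOut(rs, classifier)
    looAll[[marker]] <- loo
    .writeTsv(loo, file.path(outDir, paste0("loo_", marker, ".tsv")))

    message("== pipeline stage: evaluate [", marker, "] ==")
    hist <- do.call(rbind, lapply(c("genus", "species"), function(r)
      cbind(rank = r, bootstrapHistogram(loo, r))))
    .writeTsv(hist, file.path(outDir, paste0("bootstrap_hist_", marker,
                                             ".tsv")))
    acc <- do.call(rbind, lapply(RANKS, function(r) {
      a <- tryCatch(rankAccuracy(loo, r, threshold),
                    error = function(e) c(correct = NA_real_,
                                          incorrect = NA_real_))
      all_ <- tryCatch(rankAccuracy(loo, r, threshold, "all"),
                       error = function(e) c(correct = NA_real_,
                                             incorrect = NA_real_))
      data.frame(rank = r, assignment_rate = assignmentRate(loo, r,
                                                            threshold),
                 correct_pct = a[["correct"]],
                 incorrect_pct = a[["incorrect"]],
                 correct_pct_of_all = all_[["correct"]],
                 stringsAsFactors = FALSE)
    }))
    .writeTsv(acc, file.path(outDir, paste0("rank_accuracy_", marker,
                                            ".tsv")))
    for (r in RANKS) {
      cm <- confusionMatrix(loo, r, threshold)
      .writeTsv(cbind(true = rownames(cm), as.data.frame(cm)),
                file.path(outDir, paste0("confusion_", r, "_", marker,
                                         ".tsv")))
    }
    cmSpecies <- confusionMatrix(loo, "species", threshold)
    spScores <- speciesScores(cmSpecies)
    .writeTsv(spScores, file.path(outDir, paste0("species_f1_", marker,
                                                 ".tsv")))
    gf1 <- genusF1(spScores, genusMap(loo))
    genusTables[[marker]] <- gf1
    .writeTsv(gf1, file.path(outDir, paste0("genus_f1_", marker, ".tsv")))
    .writeTsv(cumulativeF1Curve(gf1),
              file.path(outDir, paste0("cumulative_f1_", marker, ".tsv")))
  }

  .writeTsv(do.call(rbind, summaries),
            file.path(outDir, "dataset_summary.tsv"))
  scenarios <- categorizeGenera(genusTables, f1Cutoff)
  .writeTsv(scenarios, file.path(outDir, "genus_scenarios.tsv"))

  manifest <- list(
    package = "markerNBC",
    version = as.character(utils::packageVersion("markerNBC")),
    markers = markers,
    inputs = lapply(setNames(markers, markers), function(mk) list(
      fasta = unname(fastaFiles[[mk]]),
      fasta_hash = .contentHash(fastaFiles[[mk]]),
      taxonomy = unname(taxFiles[[mk]]),
      taxonomy_hash = .contentHash(taxFiles[[mk]]))),
    parameters = list(
      min_len = minLen, min_frac_of_median = minFracOfMedian,
      balance_min = balance@minPerSpecies,
      balance_max = balance@maxPerSpecies,
      balance_seed = balance@seed,
      k = classifier@k, n_bootstrap = classifier@nBootstrap,
      subsample_divisor = classifier@subsampleDivisor,
      classifier_seed = classifier@seed,
      threshold = threshold, f1_cutoff = f1Cutoff),
    record_counts = dropLog)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(summaries = do.call(rbind, summaries), loo = looAll,
                 genusF1 = genusTables, scenarios = scenarios,
                 manifest = manifest, outDir = outDir))
}
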