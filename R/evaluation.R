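# Per-record taxon label at a rank. Species are labelled by the
# genus|species pair (species identity); other ranks use the rank label.
.rankLabel <- function(loo, rank, prefix) {
  stopifnot(rank %in% RANKS)
  lab <- loo[[paste0(prefix, rank)]]
  if (rank == "species") {
    gen <- loo[[paste0(prefix, "genus")]]
    ifelse(is.na(lab) | is.na(gen), NA_character_,
           paste(gen, lab, sep = "|"))
  } else lab
}

#' Histogram of bootstrap confidence values
#'
#' Bins the per-record bootstrap confidences at one rank. The default bins
#' are the ranges conventionally reported for classifier confidence:
#' [0,60), [60,70), [70,80), [80,90), [90,95), [95,100].
#'
#' @param loo Leave-one-out results from [leaveOneOut()].
#' @param rank One of \code{taxonomicRanks()}.
#' @param breaks Increasing numeric bin edges covering [0, 100].
#' @return \code{data.frame} with columns \code{bin} and \code{pct};
#'   percentages over all records, summing to 100.
#' @export
bootstrapHistogram <- function(loo, rank = "species",
                               breaks = c(0, 60, 70, 80, 90, 95, 100)) {
  if (!nrow(loo)) stop("bootstrapHistogram: empty input")
  stopifnot(breaks[1L] <= 0, breaks[length(breaks)] >= 100,
            !is.unsorted(breaks, strictly = TRUE))
  conf <- loo[[paste0("conf_", rank)]]
  labels <- paste0(breaks[-length(breaks)], "-",
                   c(breaks[-c(1L, length(breaks))] - 1, breaks[length(breaks)]))
  cut_ <- cut(conf, breaks = breaks, right = FALSE, include.lowest = TRUE,
              labels = labels)
  counts <- table(cut_)
  data.frame(bin = names(counts),
             pct = 100 * as.vector(counts) / length(conf),
             stringsAsFactors = FALSE)
}

#' Fraction of queries with trusted assignments
#'
#' @param loo Leave-one-out results.
#' @param rank One of \code{taxonomicRanks()}.
#' @param threshold Bootstrap confidence threshold (default 80).
#' @return Fraction in [0, 1] of records whose confidence at the rank is
#'   >= threshold.
#' @export
assignmentRate <- function(loo, rank = "species", threshold = 80) {
  stopifnot(threshold >= 0)
  mean(loo[[paste0("conf_", rank)]] >= threshold)
}

#' Percentage of correct classifications at a rank
#'
#' Among the records whose assignment is trusted (bootstrap confidence >=
#' threshold at the rank), the percentage whose predicted taxon at that
#' rank equals the true one. With \code{denominator = "all"} the same
#' correct count is instead expressed over all records, trusted or not
#' (then correct + incorrect < 100 when some records fail the threshold).
#'
#' @param loo Leave-one-out results.
#' @param rank One of \code{taxonomicRanks()}.
#' @param threshold Bootstrap confidence threshold (default 80).
#' @param denominator \code{"assigned"} (default) or \code{"all"}.
#' @return Named numeric vector \code{c(correct = , incorrect = )} in
#'   percent. Errors if no record passes the threshold.
#' @export
rankAccuracy <- function(loo, rank = "species", threshold = 80,
                         denominator = c("assigned", "all")) {
  denominator <- match.arg(denominator)
  passed <- loo$classified & loo[[paste0("conf_", rank)]] >= threshold
  if (!any(passed))
    stop("rankAccuracy: no record passes the ", threshold,
         "% threshold at rank ", rank)
  correct <- passed &
    .rankLabel(loo, rank, "pred_") == .rankLabel(loo, rank, "true_")
  denom <- if (denominator == "assigned") sum(passed) else nrow(loo)
  c(correct = 100 * sum(correct, na.rm = TRUE) / denom,
    incorrect = 100 * sum(passed & !correct, na.rm = TRUE) / denom)
}

#' Confusion matrix of true vs predicted taxa at a rank
#'
#' Rows are true taxa, columns are predicted taxa plus a final
#' \code{"unclassified"} column collecting the records whose confidence
#' fell below the threshold (or that could not be classified at all).
#' Row sums therefore equal the per-taxon record counts.
#'
#' @param loo Leave-one-out results.
#' @param rank One of \code{taxonomicRanks()}.
#' @param threshold Bootstrap confidence threshold (default 80).
#' @return Integer matrix with dimnames \code{(true, predicted)}.
#' @export
confusionMatrix <- function(loo, rank = "species", threshold = 80) {
  trueLab <- .rankLabel(loo, rank, "true_")
  predLab <- .rankLabel(loo, rank, "pred_")
  passed <- loo$classified & loo[[paste0("conf_", rank)]] >= threshold
  predLab[!passed] <- "unclassified"
  taxa <- .sortC(unique(c(trueLab, predLab[predLab != "unclassified"])))
  cm <- table(factor(trueLab, levels = taxa),
              factor(predLab, levels = c(taxa, "unclassified")))
  m <- matrix(as.integer(cm), nrow = nrow(cm), dimnames = dimnames(cm))
  names(dimnames(m)) <- c("true", "predicted")
  m
}

#' Per-species precision, recall and F1
#'
#' One-vs-rest counts from a species-rank confusion matrix: TP is the
#' diagonal cell, FP the off-diagonal mass of the species' predicted
#' column, FN the off-diagonal mass of its true row (including
#' \code{"unclassified"}, which counts toward no species' FP). Precision
#' and recall are 0 when their denominator is 0, and
#' F1 = 2PR/(P+R) (harmonic mean; 0 when P + R = 0).
#'
#' @param cm Confusion matrix from [confusionMatrix()] at species rank.
#' @return \code{data.frame} with columns \code{species}, \code{TP},
#'   \code{FP}, \code{FN}, \code{precision}, \code{recall}, \code{f1}.
#' @export
speciesScores <- function(cm) {
  species <- rownames(cm)
  predCols <- setdiff(colnames(cm), "unclassified")
  tp <- vapply(species, function(s)
    if (s %in% predCols) cm[s, s] else 0L, numeric(1L))
  fp <- vapply(species, function(s)
    if (s %in% predCols) sum(cm[, s]) - tp[[s]] else 0L, numeric(1L))
  fn <- rowSums(cm)[species] - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  data.frame(species = species, TP = as.integer(tp), FP = as.integer(fp),
             FN = as.integer(fn), precision = precision, recall = recall,
             f1 = f1, row.names = NULL, stringsAsFactors = FALSE)
}

#' Genus-level F1
#'
#' The F1 score of a genus is the unweighted arithmetic mean of the F1
#' scores of its species.
#'
#' @param scores Per-species scores from [speciesScores()].
#' @param genusOf Named character vector mapping every species label (as in
#'   \code{scores$species}) to its genus.
#' @return \code{data.frame} with columns \code{genus}, \code{mean_f1},
#'   \code{n_species}.
#' @export
genusF1 <- function(scores, genusOf) {
  genus <- genusOf[scores$species]
  if (anyNA(genus))
    stop("genusF1: no genus mapping for species ",
         paste(utils::head(scores$species[is.na(genus)], 5L),
               collapse = ", "))
  agg <- split(scores$f1, genus)
  agg <- agg[.sortC(names(agg))]
  data.frame(genus = names(agg),
             mean_f1 = vapply(agg, mean, numeric(1L)),
             n_species = lengths(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

# species label -> genus mapping from LOO true lineages
#' Species-to-genus mapping from leave-one-out results
#'
#' @param loo Leave-one-out results.
#' @return Named character vector: species label (\code{"genus|species"})
#'   -> genus.
#' @export
genusMap <- function(loo) {
  sp <- .rankLabel(loo, "species", "true_")
  setNames(loo$true_genus, sp)[!duplicated(sp)]
}

#' Cumulative distribution of genus F1 scores
#'
#' For each threshold, the percentage of genera whose mean F1 is at or
#' below it — a non-decreasing step curve that reaches 100\% at 1.0.
#'
#' @param genusTable Genus F1 table from [genusF1()].
#' @param thresholds Numeric thresholds (default 0 to 1 by 0.05).
#' @return \code{data.frame} with columns \code{threshold} and
#'   \code{cumulative_pct}.
#' @export
cumulativeF1Curve <- function(genusTable, thresholds = seq(0, 1, by = 0.05)) {
  data.frame(threshold = thresholds,
             cumulative_pct = vapply(thresholds, function(t)
               100 * mean(genusTable$mean_f1 <= t), numeric(1L)))
}

#' Categorize genera across markers by F1 performance
#'
#' A genus/marker combination is "poor" when its mean F1 is at or below
#' \code{f1Cutoff}. Each genus falls into one scenario:
#' \describe{
#'   \item{a}{at least one marker performs well (a flag records whether a
#'     poor marker also exists for the genus);}
#'   \item{b}{data for exactly one marker, and it performs poorly;}
#'   \item{c}{data for two or more markers, all poor — the "problematic
#'     genera" that no marker can resolve.}
#' }
#'
#' @param genusTables Named list (marker -> [genusF1()] table).
#' @param f1Cutoff Poor-performance cutoff (default 0.25).
#' @return \code{data.frame} with one row per genus: \code{genus},
#'   \code{n_markers}, \code{n_poor}, \code{scenario} (\code{"a"},
#'   \code{"b"} or \code{"c"}), \code{has_poor_marker}, and one
#'   \code{f1_<marker>} column per marker (\code{NA} = no data).
#' @export
categorizeGenera <- function(genusTables, f1Cutoff = 0.25) {
  stopifnot(length(genusTables) >= 1L, !is.null(names(genusTables)))
  genera <- .sortC(unique(unlist(lapply(genusTables, `[[`, "genus"))))
  if (!length(genera)) stop("categorizeGenera: no genus has data")
  f1 <- sapply(genusTables, function(tab)
    tab$mean_f1[match(genera, tab$genus)])
  f1 <- matrix(f1, nrow = length(genera),
               dimnames = list(genera, names(genusTables)))
  nMarkers <- rowSums(!is.na(f1))
  nPoor <- rowSums(f1 <= f1Cutoff, na.rm = TRUE)
  nGood <- nMarkers - nPoor
  scenario <- ifelse(nGood >= 1L, "a",
              ifelse(nMarkers == 1L, "b", "c"))
  out <- data.frame(genus = genera, n_markers = nMarkers, n_poor = nPoor,
                    scenario = scenario,
                    has_poor_marker = nPoor >= 1L,
                    row.names = NULL, stringsAsFactors = FALSE)
  colnames(f1) <- paste0("f1_", colnames(f1))
  cbind(out, as.data.frame(f1, row.names = NULL))
}

#' Within- vs between-species identity for a genus
#'
#' Numeric surrogate for eyeballing an alignment of a suspect genus: mean
#' ungapped pairwise identity (matching positions over the length of the
#' shorter sequence) within each species and between species of the genus.
#' A genus with no barcoding gap — between-species identity at or above
#' within-species identity minus \code{epsilon} — is flagged: its species
#' cannot be separated by this marker regardless of classifier.
#'
#' @param refset A \linkS4class{ReferenceSet}.
#' @param genus Genus label present in the set with >= 2 species.
#' @param epsilon Gap tolerance on the identity scale (default 0.01).
#' @return List with elements \code{within}, \code{between} (mean
#'   identities; \code{within} is \code{NA} when every species is a
#'   singleton) and \code{no_gap} (logical flag).
#' @export
divergenceDiagnostic <- function(refset, genus, epsilon = 0.01) {
  inGenus <- taxonomy(refset)[, "genus"] == genus
  if (!any(inGenus)) stop("divergenceDiagnostic: genus '", genus,
                          "' not in reference set")
  sub <- refset[inGenus]
  if (length(sub) < 2L)
    stop("divergenceDiagnostic: genus '", genus,
         "' has a single sequence")
  sp <- speciesKey(sub)
  if (length(unique(sp)) < 2L)
    stop("divergenceDiagnostic: genus '", genus,
         "' has fewer than 2 species")
  seqs <- as.character(sequences(sub))
  pairId <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    av <- strsplit(substr(a, 1L, n), "")[[1L]]
    bv <- strsplit(substr(b, 1L, n), "")[[1L]]
    mean(av == bv)
  }
  within <- numeric(); between <- numeric()
  for (i in seq_len(length(seqs) - 1L)) {
    for (j in (i + 1L):length(seqs)) {
      id <- pairId(seqs[i], seqs[j])
      if (sp[i] == sp[j]) within <- c(within, id)
      else between <- c(between, id)
    }
  }
  w <- if (length(within)) mean(within) else NA_real_
  b <- mean(between)
  list(within = w, between = b,
       no_gap = if (is.na(w)) NA else b >= w - epsilon)
}
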