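#' Taxonomic ranks used throughout the package
#'
#' The six ranks carried by every reference record, ordered from the most
#' inclusive (phylum) to the least (species). Lineages follow the
#' Greengenes-style prefixed string convention,
#' \code{"p__X;c__X;o__X;f__X;g__X;s__X"}, with an empty label after a
#' prefix denoting a missing rank.
#'
#' @return Character vector of the six rank names, in order.
#' @examples
#' taxonomicRanks()
#' @export
taxonomicRanks <- function() RANKS

RANKS <- c("phylum", "class", "order", "family", "genus", "species")
RANK_PREFIXES <- c("p", "c", "o", "f", "g", "s")

#' Parse a Greengenes-style lineage string
#'
#' Splits a six-field, semicolon-separated lineage string of the form
#' \code{"p__A;c__B;o__C;f__D;g__E;s__F"} into a named character vector over
#' the six ranks. Spaces after semicolons and a trailing semicolon are
#' tolerated. An empty label after a prefix (e.g. \code{"g__"}) yields
#' \code{NA} (the missing sentinel) at that rank.
#'
#' @param text A single lineage string.
#' @return Named character vector of length 6 (names \code{taxonomicRanks()});
#'   \code{NA} marks a missing rank.
#' @seealso [formatLineage()] for the inverse operation.
#' @examples
#' parseLineage("p__Streptophyta;c__Magnoliopsida;o__Poales;f__Poaceae;g__Oryza;s__Oryza_sativa")
#' @export
parseLineage <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- sub(";\\s*$", "", text)
  fields <- strsplit(text, ";")[[1]]
  fields <- sub("^\\s+", "", fields)
  if (length(fields) != 6L) {
    stop("lineage must have exactly 6 rank fields, got ", length(fields),
         " in: ", text)
  }
  prefixes <- substr(fields, 1L, 3L)
  expected <- paste0(RANK_PREFIXES, "__")
  bad <- which(prefixes != expected)
  if (length(bad)) {
    stop("unknown or misplaced rank prefix in lineage token: '",
         fields[bad[1L]], "' (expected prefix '", expected[bad[1L]], "')")
  }
  labels <- substring(fields, 4L)
  labels[labels == ""] <- NA_character_
  names(labels) <- RANKS
  labels
}

#' Format a lineage as a Greengenes-style string
#'
#' @param lineage Named character vector over the six ranks (as returned by
#'   [parseLineage()]); \code{NA} entries are written as empty labels.
#' @return A single lineage string.
#' @examples
#' formatLineage(c(phylum = "A", class = "B", order = "C",
#'                 family = "D", genus = NA, species = NA))
#' @export
formatLineage <- function(lineage) {
  stopifnot(length(lineage) == 6L)
  if (!is.null(names(lineage)) && !identical(names(lineage), RANKS)) {
    lineage <- lineage[RANKS]
  }
  labels <- as.character(lineage)
  labels[is.na(labels)] <- ""
  paste0(RANK_PREFIXES, "__", labels, collapse = ";")
}

#' @rdname parseLineage
#' @param texts Character vector of lineage strings.
#' @return \code{parseLineages}: a character matrix with one row per input
#'   and the six ranks as columns.
#' @export
parseLineages <- function(texts) {
  m <- t(vapply(texts, parseLineage, character(6L)))
  dimnames(m) <- list(names(texts), RANKS)
  m
}

#' Test whether lineages are complete
#'
#' A lineage is complete when all six rank labels are present (non-missing).
#'
#' @param lineages Character matrix with the six ranks as columns (one row
#'   per record), or a single named lineage vector.
#' @return Logical vector, one element per lineage.
#' @export
isCompleteLineage <- function(lineages) {
  if (is.null(dim(lineages))) lineages <- matrix(lineages, nrow = 1L,
                                                 dimnames = list(NULL, RANKS))
  rowSums(is.na(lineages[, RANKS, drop = FALSE])) == 0L
}
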