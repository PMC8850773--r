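#' Read marker sequences from a FASTA file
#'
#' Headers are truncated at the first whitespace to form the sequence id;
#' sequences are stored uppercased (IUPAC ambiguity codes are accepted and
#' preserved). Records with an empty sequence body or a duplicated id are
#' rejected with an error naming the record.
#'
#' @param path Path to a FASTA file.
#' @return A named \code{DNAStringSet}, input order preserved.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  empty <- Biostrings::width(x) == 0L
  if (any(empty))
    stop("malformed FASTA: empty sequence for record(s) ",
         paste(names(x)[empty], collapse = ", "), " in ", path)
  if (anyDuplicated(names(x)))
    stop("malformed FASTA: duplicate id(s) ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         " in ", path)
  x
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named \code{DNAStringSet} (or character vector).
#' @param path Output path (UTF-8, LF line endings).
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(sequences, path) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, filepath = path)
  invisible(path)
}

#' Read a two-column taxonomy file
#'
#' Reads a mothur-style tab-delimited file mapping sequence id to a
#' Greengenes-style six-rank lineage string, and parses every lineage.
#'
#' @param path Path to the taxonomy file.
#' @return Character matrix of lineages: one row per sequence id (rownames),
#'   six rank columns. An empty file yields a 0-row matrix.
#' @export
readTaxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(matrix(character(), nrow = 0L, ncol = 6L,
                  dimnames = list(NULL, RANKS)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("taxonomy line ", bad[1L], " is not 'seq_id<TAB>lineage': ",
         lines[bad[1L]])
  ids <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicate seq_id in taxonomy file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lin <- vapply(parts, `[[`, character(1L), 2L)
  m <- parseLineages(lin)
  rownames(m) <- ids
  m
}

#' Write a two-column taxonomy file
#'
#' @param taxonomy Character matrix of lineages (rownames = sequence ids).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeTaxonomy <- function(taxonomy, path) {
  lines <- paste0(rownames(taxonomy), "\t",
                  apply(taxonomy, 1L, formatLineage))
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Join sequences and taxonomy into a ReferenceSet
#'
#' Keeps the sequence ids present in both inputs (a message reports how
#' many ids were dropped on each side) and errors if the intersection is
#' empty.
#'
#' @param sequences Named \code{DNAStringSet} as from [readFasta()].
#' @param taxonomy Lineage matrix as from [readTaxonomy()].
#' @param marker Marker name for the resulting set.
#' @return A \linkS4class{ReferenceSet}, in FASTA input order.
#' @export
joinReference <- function(sequences, taxonomy, marker) {
  keep <- intersect(names(sequences), rownames(taxonomy))
  nDropSeq <- length(sequences) - length(keep)
  nDropTax <- nrow(taxonomy) - length(keep)
  if (nDropSeq || nDropTax)
    message("joinReference: dropped ", nDropSeq, " sequence(s) without ",
            "taxonomy and ", nDropTax, " taxonomy row(s) without sequence")
  if (!length(keep))
    stop("joinReference: no sequence ids shared between FASTA and taxonomy")
  sequences <- sequences[names(sequences) %in% keep]
  ReferenceSet(marker, sequences, taxonomy[names(sequences), , drop = FALSE])
}

#' Write a ReferenceSet to FASTA + taxonomy files
#'
#' @param refset A \linkS4class{ReferenceSet}.
#' @param fastaPath,taxPath Output paths.
#' @return Invisibly, the two paths.
#' @export
writeReferenceSet <- function(refset, fastaPath, taxPath) {
  writeFasta(sequences(refset), fastaPath)
  writeTaxonomy(taxonomy(refset), taxPath)
  invisible(c(fasta = fastaPath, tax = taxPath))
}
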