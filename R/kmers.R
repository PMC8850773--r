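#' Decompose a sequence into overlapping k-mers
#'
#' Slides a window of length \code{k} along the given strand and returns
#' the abundance of every word observed. Windows containing any non-ACGT
#' character (IUPAC ambiguity codes, gaps) carry no usable word and are
#' skipped.
#'
#' @param sequence A DNA string (character or \code{DNAString}).
#' @param k Word size (default 8).
#' @return Named integer vector: word -> abundance, lexicographic order.
#'   Distinct words are \code{names()}; training and query scoring use
#'   presence only.
#' @examples
#' extractKmers("ACGTACGTA", k = 8)
#' @export
extractKmers <- function(sequence, k = 8L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  if (length(sequence) < k)
    stop("sequence of length ", length(sequence),
         " is shorter than k = ", k)
  f <- Biostrings::oligonucleotideFrequency(sequence, width = k)
  f[f > 0L]
}

# Integer codes (1 .. 4^k, lexicographic over A<C<G<T) of the distinct
# valid words of each sequence in an XStringSet. Returns a list parallel
# to the set. Chunked to bound the 4^k-column scratch matrix.
.wordCodeList <- function(sequences, k) {
  n <- length(sequences)
  out <- vector("list", n)
  chunk <- max(1L, as.integer(2^26 / 4^k))  # ~256 MB of ints per chunk
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    f <- Biostrings::oligonucleotideFrequency(sequences[idx], width = k)
    out[idx] <- lapply(seq_len(nrow(f)), function(i) which(f[i, ] > 0L))
  }
  names(out) <- names(sequences)
  out
}

# Codes of the distinct valid words of one sequence (character or DNAString).
.wordCodes <- function(sequence, k) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  if (length(sequence) < k)
    stop("sequence of length ", length(sequence),
         " is shorter than k = ", k)
  which(Biostrings::oligonucleotideFrequency(sequence, width = k) > 0L)
}

# Decode integer word codes back to k-mer strings (for reporting/tests).
.decodeWords <- function(codes, k) {
  bases <- c("A", "C", "G", "T")
  vapply(codes, function(code) {
    x <- code - 1L
    chars <- character(k)
    for (i in k:1) {
      chars[i] <- bases[x %% 4L + 1L]
      x <- x %/% 4L
    }
    paste(chars, collapse = "")
  }, character(1L))
}

# Encode k-mer strings to integer codes; NA for words with non-ACGT letters.
.encodeWords <- function(words, k) {
  bases <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  vapply(words, function(w) {
    ch <- strsplit(w, "")[[1L]]
    v <- bases[ch]
    if (length(v) != k || anyNA(v)) return(NA_integer_)
    as.integer(sum(v * 4^((k - 1L):0)) + 1L)
  }, integer(1L), USE.NAMES = FALSE)
}
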