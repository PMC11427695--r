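#' Reverse complement of DNA sequences
#'
#' Complements A<->T, C<->G (N self-complements) and reverses each string.
#' Used both on expected indices (barcode templates with reverse-complement
#' segments) and on observed index sequences extracted from reads.
#'
#' @param seq Character vector of DNA strings over the alphabet A/C/G/T/N.
#' @return Character vector of the same length with each element
#'   reverse-complemented.
#' @examples
#' reverse_complement("AAC")   # "GTT"
#' reverse_complement("ACGT")  # palindrome: "ACGT"
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq)) {
    stop_validation("reverse_complement() expects a character vector")
  }
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop_validation(sprintf(
      "non-ACGTN character in sequence %s",
      paste(sQuote(seq[bad][seq_len(min(3L, sum(bad)))]), collapse = ", ")
    ))
  }
  comp <- chartr("ACGT", "TGCA", seq)
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(x) paste(rev(x), collapse = ""),
    character(1)
  )
}

#' Hamming distance between equal-length strings
#'
#' @param a,b Character vectors (recycled) of equal-length strings.
#' @return Integer vector of per-pair mismatch counts.
#' @export
hamming_distance <- function(a, b) {
  if (any(nchar(a) != nchar(b))) {
    stop_validation("hamming_distance() requires equal-length strings")
  }
  mapply(
    function(x, y) sum(x != y),
    strsplit(a, "", fixed = TRUE),
    strsplit(b, "", fixed = TRUE),
    USE.NAMES = FALSE
  )
}

# Random DNA string helper used by the simulator; vectorised over n strings.
random_dna <- function(n, length, alphabet = c("A", "C", "G", "T")) {
  if (n == 0L || length == 0L) {
    return(character(n))
  }
  chars <- sample(alphabet, n * length, replace = TRUE)
  apply(matrix(chars, nrow = n), 1L, paste, collapse = "")
}
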