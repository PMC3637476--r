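# Small shared helpers.

DNA_BASES <- c("A", "C", "G", "T")

# sample() misbehaves on a length-1 numeric vector; this never does.
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

#' Reverse complement of nucleotide strings
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors (IUPAC codes, including `N`, are handled).
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(resample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Substitute single characters at 1-based positions of one string.
str_sub_at <- function(seq, pos1, repl) {
  v <- strsplit(seq, NULL)[[1]]
  v[pos1] <- repl
  paste(v, collapse = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
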