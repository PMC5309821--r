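DNA_ALPHABET <- c("A", "C", "G", "T", "N")

.check_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}: %s",
                 what, substr(x[bad][1], 1, 40)), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of plain character sequences
#'
#' @param x character vector of A/C/G/T/N sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substring of a 0-based half-open interval [start, end)
.subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

# run code under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
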