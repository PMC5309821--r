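#' Variant keys: coordinate+allele identifiers for insertions
#'
#' An insertion is identified by the triple `chrom:position:sequence`, where
#' `position` is the 0-based index of the reference base immediately to the
#' left of the insertion point and `sequence` contains the inserted bases
#' (1-31 bp, plus strand).  Key equality is exactly string equality of the
#' serialized form; keys are the identity used for dbSNP matching,
#' cross-sample recurrence and catalogue union.
#'
#' @param chrom chromosome name.
#' @param position 0-based anchor (base left of the insertion point).
#' @param sequence inserted bases.
#' @return a `data.frame` with columns `chrom`, `position`, `sequence`, `key`.
#' @export
variant_key <- function(chrom, position, sequence) {
  stopifnot(length(chrom) == length(position),
            length(position) == length(sequence))
  sequence <- toupper(sequence)
  .check_alphabet(sequence, "inserted sequence")
  if (any(nchar(sequence) < 1L | nchar(sequence) > 31L)) {
    stop("inserted sequence length must be in [1, 31]", call. = FALSE)
  }
  if (any(position < 0)) stop("anchor position must be >= 0", call. = FALSE)
  data.frame(chrom = as.character(chrom),
             position = as.integer(position),
             sequence = sequence,
             key = sprintf("%s:%d:%s", chrom, as.integer(position), sequence),
             stringsAsFactors = FALSE)
}

#' Parse serialized variant keys
#'
#' @param key character vector of `chrom:position:sequence` strings.
#' @return a `data.frame` as from [variant_key()].
#' @export
parse_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  ok <- vapply(parts, length, 1L) == 3L
  if (!all(ok)) {
    stop("malformed key (expected chrom:position:sequence): ", key[!ok][1],
         call. = FALSE)
  }
  variant_key(vapply(parts, `[`, "", 1L),
              as.integer(vapply(parts, `[`, "", 2L)),
              vapply(parts, `[`, "", 3L))
}

#' Left-normalize an insertion against the reference
#'
#' Shifts the anchor left while the inserted sequence can be rotated into
#' the preceding reference bases, so that identical events inside repeats
#' collapse onto one canonical key.  Equivalent to VCF-style left alignment.
#'
#' @param chrom_seq reference chromosome sequence (single string).
#' @param position 0-based anchor.
#' @param sequence inserted bases.
#' @return list with normalized `position` and `sequence`.
#' @export
left_normalize_insertion <- function(chrom_seq, position, sequence) {
  pos <- as.integer(position)
  seq <- toupper(sequence)
  k <- nchar(seq)
  while (pos >= 1L) {
    ref_base <- substr(chrom_seq, pos + 1L, pos + 1L)
    if (ref_base != substr(seq, k, k) || ref_base == "N") break
    seq <- paste0(ref_base, substr(seq, 1L, k - 1L))
    pos <- pos - 1L
  }
  list(position = pos, sequence = seq)
}

# left-normalize a deletion of reference interval [start, end), 0-based.
# Shift left while the base entering from the left equals the base leaving
# on the right (classic indel left-alignment).
.left_normalize_deletion <- function(chrom_seq, start, end) {
  s <- as.integer(start); e <- as.integer(end)
  while (s >= 1L &&
         substr(chrom_seq, s, s) == substr(chrom_seq, e, e)) {
    s <- s - 1L
    e <- e - 1L
  }
  list(start = s, end = e)
}

# normalized key for a raw (anchor, sequence) call on a genome
.normalized_key <- function(genome, chrom, position, sequence) {
  nn <- left_normalize_insertion(genome[[chrom]], position, sequence)
  variant_key(chrom, nn$position, nn$sequence)
}
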