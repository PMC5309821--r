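#' Build reference and insertion mini-genomes for a variant
#'
#' Mini-genomes are twice the read length, centred on the insertion
#' locus: the reference window runs from `read_len - 1` bases left of the
#' anchor to `read_len` bases right of it (length `2 * read_len`), and
#' the insertion mini is the same window with the inserted sequence
#' spliced in after the anchor.  Windows are clipped at chromosome ends
#' with the actual extent recorded; a window clipped on both sides (the
#' anchor within `read_len` of both ends) is an error.
#'
#' @param genome an `enh_genome`.
#' @param key one-row key `data.frame` (see [variant_key()]) or serialized
#'   key string.
#' @param read_len sample read length in bases.
#' @return list with `ref`, `alt` (sequences), `window_start`,
#'   `window_end` (0-based half-open on the reference), `anchor_offset`
#'   (0-based index of the anchor inside `ref`), `clipped`.
#' @export
build_mini_genomes <- function(genome, key, read_len) {
  if (is.character(key)) key <- parse_key(key)
  chrom_seq <- genome[[key$chrom]]
  if (is.null(chrom_seq)) stop("unknown chromosome: ", key$chrom,
                               call. = FALSE)
  clen <- nchar(chrom_seq)
  anchor <- key$position
  if (anchor < 0L || anchor >= clen) {
    stop("anchor outside chromosome", call. = FALSE)
  }
  w0 <- anchor - read_len + 1L
  w1 <- anchor + read_len + 1L
  clipped_left <- w0 < 0L
  clipped_right <- w1 > clen
  if (clipped_left && clipped_right) {
    stop("anchor within read_len of both chromosome ends; window too small",
         call. = FALSE)
  }
  w0 <- max(0L, w0)
  w1 <- min(clen, w1)
  ref <- .subseq0(chrom_seq, w0, w1)
  off <- anchor - w0
  alt <- paste0(substr(ref, 1L, off + 1L), key$sequence,
                substr(ref, off + 2L, nchar(ref)))
  list(ref = ref, alt = alt, window_start = w0, window_end = w1,
       anchor_offset = off, clipped = clipped_left || clipped_right,
       key = key$key)
}

#' Count reads supporting each allele of an insertion
#'
#' Each read is aligned gaplessly, full length, on both strands against
#' both mini-genomes (unique placement, at most `max_mismatches`
#' mismatches).  A read is informative for an allele iff it aligns to
#' exactly one mini-genome; reads aligning to both (not spanning the
#' insertion junction) or to neither are not counted.  The bias ratio is
#' `(alt + 1) / (ref + 1)`: a single pseudocount keeps the ratio defined
#' at zero reference coverage, and raw counts are reported alongside.
#'
#' @param reads reads `data.frame` or character vector.
#' @param minis mini-genome pair from [build_mini_genomes()].
#' @param max_mismatches mismatch budget, mirroring the main gapless pass.
#' @return one-row `data.frame`: `key`, `ref_reads`, `alt_reads`,
#'   `bias_ratio`.
#' @export
count_allele_reads <- function(reads, minis, max_mismatches = 2) {
  reads <- .as_reads_df(reads)
  ref_g <- as_genome(c(ref = minis$ref))
  alt_g <- as_genome(c(alt = minis$alt))
  if (nrow(reads) == 0L) {
    ref_n <- 0L
    alt_n <- 0L
  } else {
    on_ref <- map_ungapped(reads, ref_g, max_mismatches = max_mismatches)
    on_alt <- map_ungapped(reads, alt_g, max_mismatches = max_mismatches)
    ref_ok <- on_ref$status == "unique"
    alt_ok <- on_alt$status == "unique"
    ref_n <- sum(ref_ok & !alt_ok)
    alt_n <- sum(alt_ok & !ref_ok)
  }
  data.frame(key = if (is.null(minis$key)) NA_character_ else minis$key,
             ref_reads = ref_n, alt_reads = alt_n,
             bias_ratio = (alt_n + 1) / (ref_n + 1),
             stringsAsFactors = FALSE)
}

#' Allele-specific coverage for every catalogue entry
#'
#' @param catalogue catalogue `data.frame`.
#' @param reads the sample's reads.
#' @param genome an `enh_genome`.
#' @param read_len read length used to size mini-genomes.
#' @param max_mismatches per-mini alignment mismatch budget.
#' @return `data.frame` with one row per entry: `key`, `ref_reads`,
#'   `alt_reads`, `bias_ratio`.
#' @export
allelic_coverage <- function(catalogue, reads, genome, read_len = 40,
                             max_mismatches = 2) {
  reads <- .as_reads_df(reads)
  rows <- lapply(seq_len(nrow(catalogue)), function(i) {
    minis <- build_mini_genomes(genome, catalogue[i, , drop = FALSE],
                                read_len)
    count_allele_reads(reads, minis, max_mismatches = max_mismatches)
  })
  do.call(rbind, rows)
}

#' Keep insertions with at least a given coverage bias
#'
#' Retains entries whose insertion-allele reads exceed reference-allele
#' reads by at least `min_ratio` (twofold by default), the filter that
#' prioritizes candidate enhancer-activating insertions.
#'
#' @param coverages `data.frame` from [allelic_coverage()].
#' @param min_ratio minimum `bias_ratio` kept (boundary included).
#' @return filtered `data.frame`.
#' @export
filter_bias <- function(coverages, min_ratio = 2.0) {
  coverages[coverages$bias_ratio >= min_ratio, , drop = FALSE]
}
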