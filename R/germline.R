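#' Flag catalogue entries present in dbSNP
#'
#' An entry is flagged germline-by-annotation iff its serialized key
#' (position AND sequence) is present in the dbSNP key set.
#'
#' @param catalogue catalogue `data.frame` from [build_catalogue()].
#' @param dbsnp_keys character vector of serialized dbSNP insertion keys
#'   (same left-normalization as the caller; see [dbsnp_keys_from_vcf()]).
#' @return logical vector `in_dbsnp`, one per entry.
#' @export
annotate_dbsnp <- function(catalogue, dbsnp_keys) {
  catalogue$key %in% dbsnp_keys
}

#' Flag recurrent catalogue entries
#'
#' An insertion with the same position and sequence identified in more
#' than `max_samples` samples is considered germline by recurrence:
#' recurrence across many unrelated individuals is more parsimonious with
#' inherited variation than with independent somatic events.
#'
#' @param catalogue catalogue `data.frame`.
#' @param max_samples largest sample count NOT considered recurrent
#'   (default 2: the validated somatic exemplar was present in only two
#'   samples).
#' @return logical vector `recurrent`, one per entry.
#' @export
flag_recurrent <- function(catalogue, max_samples = 2) {
  vapply(.catalogue_samples(catalogue), length, 1L) > max_samples
}

#' Annotate a catalogue with germline flags
#'
#' @inheritParams annotate_dbsnp
#' @inheritParams flag_recurrent
#' @return the catalogue with `in_dbsnp`, `recurrent` filled and a
#'   derived `germline` column (`in_dbsnp | recurrent`).
#' @export
annotate_germline <- function(catalogue, dbsnp_keys = character(),
                              max_samples = 2) {
  catalogue$in_dbsnp <- annotate_dbsnp(catalogue, dbsnp_keys)
  catalogue$recurrent <- flag_recurrent(catalogue, max_samples)
  catalogue$germline <- catalogue$in_dbsnp | catalogue$recurrent
  catalogue
}

#' Partition a catalogue into putative-germline and remaining entries
#'
#' @param catalogue annotated catalogue (see [annotate_germline()]).
#' @return list with `non_germline` (entries with `germline = FALSE`) and
#'   `summary`: named counts (`total`, `dbsnp`, `recurrent`, `both`,
#'   `union`, `remaining`).  The union obeys inclusion-exclusion.
#' @export
partition_somatic <- function(catalogue) {
  if (is.null(catalogue$germline)) {
    stop("catalogue lacks germline annotations; run annotate_germline()",
         call. = FALSE)
  }
  summary <- germline_accounting(
    total_unique = nrow(catalogue),
    n_dbsnp = sum(catalogue$in_dbsnp),
    n_recurrent = sum(catalogue$recurrent),
    n_both = sum(catalogue$in_dbsnp & catalogue$recurrent))
  list(non_germline = catalogue[!catalogue$germline, , drop = FALSE],
       summary = summary)
}

#' Germline accounting arithmetic
#'
#' Inclusion-exclusion bookkeeping for the deprioritization step: the
#' union of annotation-flagged and recurrence-flagged entries, the
#' remaining (putatively somatic) entries, and optionally the expanded
#' total after adding previously reported insertions.
#'
#' @param total_unique number of unique candidate keys.
#' @param n_dbsnp entries present in dbSNP.
#' @param n_recurrent entries recurrent across samples.
#' @param n_both entries flagged by both criteria.
#' @param prior_reported previously reported insertion count to add to the
#'   remaining entries (optional).
#' @return named numeric vector with `total`, `dbsnp`, `recurrent`,
#'   `both`, `union`, `remaining`, and `expanded_total` when
#'   `prior_reported` is given.
#' @export
germline_accounting <- function(total_unique, n_dbsnp, n_recurrent, n_both,
                                prior_reported = NULL) {
  stopifnot(n_both <= n_dbsnp, n_both <= n_recurrent)
  u <- n_dbsnp + n_recurrent - n_both
  if (u > total_unique) stop("union exceeds total", call. = FALSE)
  out <- c(total = total_unique, dbsnp = n_dbsnp, recurrent = n_recurrent,
           both = n_both, union = u, remaining = total_unique - u)
  if (!is.null(prior_reported)) {
    out <- c(out, expanded_total = prior_reported + total_unique - u)
  }
  out
}

#' Convert dbSNP records to insertion keys
#'
#' Accepts either a plain key file (one `chrom:pos:seq` per line) or a
#' VCF restricted to insertion records (ALT longer than REF, REF a prefix
#' of ALT).  VCF POS is 1-based at the anchor base; keys are converted to
#' the package's 0-based anchors and left-normalized against the supplied
#' genome so that matching against caller output is meaningful.
#'
#' @param path key file or VCF.
#' @param genome an `enh_genome` (required for VCF input).
#' @return character vector of serialized keys.
#' @export
dbsnp_keys_from_vcf <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) return(character())
  if (!grepl("\t", lines[1])) {
    # plain key file
    return(unique(parse_key(lines)$key))
  }
  if (is.null(genome)) {
    stop("VCF dbSNP input requires the genome for normalization",
         call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keys <- character()
  for (f in fields) {
    chrom <- f[1]
    pos1 <- as.integer(f[2])
    ref <- toupper(f[4])
    for (alt in strsplit(toupper(f[5]), ",", fixed = TRUE)[[1]]) {
      if (nchar(alt) <= nchar(ref)) next
      if (substr(alt, 1L, nchar(ref)) != ref) next
      ins <- substr(alt, nchar(ref) + 1L, nchar(alt))
      anchor <- pos1 - 1L + nchar(ref) - 1L  # 0-based base left of insert
      if (nchar(ins) > 31L) next
      keys <- c(keys, .normalized_key(genome, chrom, anchor, ins)$key)
    }
  }
  unique(keys)
}

#' Collapsed union of enhancer peaks across samples
#'
#' @param peak_list list of peak `data.frame`s (or a single one).
#' @return merged peaks `data.frame` (`chrom`, `start`, `end`).
#' @export
enhancer_union <- function(peak_list) {
  if (is.data.frame(peak_list)) peak_list <- list(peak_list)
  peaks <- do.call(rbind, peak_list)
  if (is.null(peaks) || nrow(peaks) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(peaks$chrom,
                           IRanges::IRanges(peaks$start + 1L, peaks$end)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Strict intersection with an external insertion catalogue
#'
#' External keys are first restricted to those lying inside the collapsed
#' enhancer union (strict overlap of the anchor), then matched against
#' catalogue entries by exact key equality (position AND sequence).
#'
#' @param catalogue catalogue `data.frame`.
#' @param external_keys character vector of serialized external keys.
#' @param union_peaks collapsed enhancer union from [enhancer_union()].
#' @return catalogue entries whose key matches a retained external key.
#' @export
intersect_external_catalogue <- function(catalogue, external_keys,
                                         union_peaks) {
  if (length(external_keys) == 0L || nrow(union_peaks) == 0L) {
    return(catalogue[integer(0), , drop = FALSE])
  }
  ext <- parse_key(external_keys)
  q <- GenomicRanges::GRanges(ext$chrom,
                              IRanges::IRanges(ext$position + 1L,
                                               width = 1L))
  s <- GenomicRanges::GRanges(union_peaks$chrom,
                              IRanges::IRanges(union_peaks$start + 1L,
                                               union_peaks$end))
  inside <- GenomicRanges::countOverlaps(q, s) > 0L
  catalogue[catalogue$key %in% ext$key[inside], , drop = FALSE]
}
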