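#' Poisson sliding-window peak calling
#'
#' A stand-in for MACS at desk scale: read start positions are
#' deduplicated up to an expected per-position maximum (the keep-dup
#' analogue), counted in sliding windows, and windows whose Poisson tail
#' probability against the local background falls below `p_threshold` are
#' merged into peaks.  When control positions are supplied the local rate
#' is the larger of the genome-wide rate and the depth-scaled control
#' count in the window.  Users reproducing published-scale analyses
#' should supply externally called peaks as BED instead.
#'
#' @param positions `data.frame` with `chrom` and `pos` (0-based read
#'   starts) from the gapless pass.
#' @param genome an `enh_genome`.
#' @param control_positions optional control (input DNA) read starts.
#' @param p_threshold Poisson tail threshold for an enriched window.
#' @param window window width in bases.
#' @param step window step (defaults to `window / 2`).
#' @return peaks `data.frame` (`chrom`, `start`, `end`).
#' @export
call_peaks <- function(positions, genome, control_positions = NULL,
                       p_threshold = 1e-9, window = 500, step = NULL) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (is.null(positions) || nrow(positions) == 0L) return(empty)
  if (is.null(step)) step <- max(1L, as.integer(window / 2))
  glen <- sum(nchar(genome))

  cap_positions <- function(df) {
    lambda_pos <- nrow(df) / glen
    cap <- max(1L, qpois(1e-5, lambda_pos, lower.tail = FALSE))
    key <- paste(df$chrom, df$pos)
    keep <- stats::ave(seq_along(key), key, FUN = seq_along) <= cap
    df[keep, , drop = FALSE]
  }
  positions <- cap_positions(positions)
  n_treat <- nrow(positions)
  lambda_bg_win <- n_treat * window / glen
  scale <- if (!is.null(control_positions) && nrow(control_positions) > 0L) {
    n_treat / nrow(control_positions)
  } else NA_real_

  peaks <- empty
  for (chrom in names(genome)) {
    clen <- nchar(genome[[chrom]])
    pos <- positions$pos[positions$chrom == chrom]
    if (length(pos) == 0L) next
    starts <- seq(0L, max(0L, clen - 1L), by = step)
    counts <- vapply(starts, function(s) {
      sum(pos >= s & pos < s + window)
    }, 0L)
    lambda <- rep(lambda_bg_win, length(starts))
    if (!is.na(scale)) {
      cpos <- control_positions$pos[control_positions$chrom == chrom]
      ctrl <- vapply(starts, function(s) {
        sum(cpos >= s & cpos < s + window)
      }, 0L)
      lambda <- pmax(lambda, ctrl * scale)
    }
    pvals <- ppois(counts - 1L, lambda, lower.tail = FALSE)
    sig <- which(pvals < p_threshold)
    if (length(sig) == 0L) next
    ir <- IRanges::reduce(IRanges::IRanges(start = starts[sig] + 1L,
                                           end = pmin(starts[sig] + window,
                                                      clen)))
    peaks <- rbind(peaks, data.frame(chrom = chrom,
                                     start = IRanges::start(ir) - 1L,
                                     end = IRanges::end(ir),
                                     stringsAsFactors = FALSE))
  }
  peaks
}

#' Extract an insertion call from a verified hit
#'
#' The single I op of the CIGAR yields the inserted bases; the anchor is
#' the reference base immediately left of the insertion point.  The key is
#' left-normalized against the reference and reported on the plus strand.
#'
#' @param hit verified hit (from [verify_hit()]/[map_gapped()]); must carry
#'   `query_seq`, the query oriented as aligned.
#' @param genome an `enh_genome`.
#' @param sample sample identifier.
#' @param min_flank minimum aligned bases required on each side of the
#'   insertion (over equivalent placements; guards against soft-clip-like
#'   end insertions).
#' @return one-row `data.frame` insertion call, or `NULL` when the CIGAR
#'   does not contain exactly one I op or a flank is too short.
#' @export
extract_insertion <- function(hit, genome, sample, min_flank = 0) {
  ops <- parse_cigar(hit$cigar)
  if (sum(ops$op == "I") != 1L || any(ops$op == "D")) return(NULL)
  qlen <- .cigar_query_len(ops)
  i_idx <- which(ops$op == "I")
  a <- if (i_idx == 1L) 0L else sum(ops$len[seq_len(i_idx - 1L)])
  k <- ops$len[i_idx]
  b <- qlen - a - k
  qseq <- hit$query_seq
  if (is.null(qseq)) stop("hit lacks query_seq", call. = FALSE)
  # maximal equivalent flanks: slide the insertion left/right across equal
  # characters to measure how well each side is anchored
  a_min <- a
  while (a_min > 0L &&
         substr(qseq, a_min, a_min) == substr(qseq, a_min + k, a_min + k)) {
    a_min <- a_min - 1L
  }
  a_max <- a
  while (a_max + k < qlen &&
         substr(qseq, a_max + 1L, a_max + 1L) ==
         substr(qseq, a_max + k + 1L, a_max + k + 1L)) {
    a_max <- a_max + 1L
  }
  if (a_max < min_flank || (qlen - k - a_min) < min_flank) return(NULL)
  anchor <- hit$start + a - 1L
  insert <- substr(qseq, a + 1L, a + k)
  key <- .normalized_key(genome, hit$chrom, anchor, insert)
  data.frame(key = key$key, chrom = key$chrom, position = key$position,
             sequence = key$sequence, sample = sample,
             source = NA_character_, query_id = hit$query_id,
             hit_start = hit$start, hit_cigar = hit$cigar,
             stringsAsFactors = FALSE)
}

.empty_calls <- function() {
  data.frame(key = character(), chrom = character(), position = integer(),
             sequence = character(), sample = character(),
             source = character(), query_id = character(),
             hit_start = integer(), hit_cigar = character(),
             stringsAsFactors = FALSE)
}

#' Rescue initially unmapped reads and contigs
#'
#' The rescue path of the discovery pipeline: unmapped reads are assembled
#' into contigs; each read and each contig is realigned with the gapped
#' aligner, verified by exhaustive zero-mismatch realignment, required to
#' agree with the verification placement within `consistency_tol` bases,
#' and turned into a left-normalized insertion call.  Read-derived and
#' contig-derived calls for the same key are merged downstream by
#' [build_catalogue()].
#'
#' @param unmapped_reads reads that failed gapless mapping (both
#'   `no_hit` and `ambiguous`), as `data.frame` or named character.
#' @param genome an `enh_genome`.
#' @param sample sample identifier.
#' @param min_overlap,min_coverage assembly parameters.
#' @param max_insertion_read insertion cap for read-derived calls
#'   (BLAT-style 20 bp).
#' @param max_insertion_contig insertion cap for contig-derived calls
#'   (31 bp, the upper end of the catalogue's size range).
#' @param min_flank minimum aligned flank on each side of an insertion.
#' @param consistency_tol maximum distance between gapped and
#'   verification hits.
#' @return list with `calls` (insertion call `data.frame`), `contigs`,
#'   and `stats` (per-stage counts).
#' @export
rescue_unmapped <- function(unmapped_reads, genome, sample = "sample",
                            min_overlap = 20, min_coverage = 5,
                            max_insertion_read = 20,
                            max_insertion_contig = 31,
                            min_flank = 5, consistency_tol = 100) {
  unmapped_reads <- .as_reads_df(unmapped_reads)
  contigs <- assemble_contigs(unmapped_reads, min_overlap = min_overlap,
                              min_coverage = min_coverage)
  queries <- rbind(
    data.frame(id = unmapped_reads$id, sequence = unmapped_reads$sequence,
               source = rep("read", nrow(unmapped_reads)),
               stringsAsFactors = FALSE),
    data.frame(id = vapply(contigs, `[[`, "", "id"),
               sequence = vapply(contigs, `[[`, "", "sequence"),
               source = rep("contig", length(contigs)),
               stringsAsFactors = FALSE))
  stats <- c(unmapped = nrow(unmapped_reads), contigs = length(contigs),
             gapped = 0L, with_insertion = 0L, verified = 0L,
             consistent = 0L, calls = 0L)
  calls <- .empty_calls()
  if (nrow(queries) == 0L) return(list(calls = calls, contigs = contigs,
                                       stats = stats))
  hits <- map_gapped_batch(stats::setNames(queries$sequence, queries$id),
                           genome)
  for (i in seq_len(nrow(queries))) {
    h <- hits[[i]]
    if (!identical(h$status, "mapped")) next
    stats["gapped"] <- stats["gapped"] + 1L
    if (!grepl("I", h$cigar)) next
    stats["with_insertion"] <- stats["with_insertion"] + 1L
    cap <- if (queries$source[i] == "contig") max_insertion_contig else
      max_insertion_read
    oriented <- if (h$strand == "-") revcomp(queries$sequence[i]) else
      queries$sequence[i]
    v <- verify_hit(oriented, genome, h, max_insertion = cap)
    if (!v$accepted) next
    stats["verified"] <- stats["verified"] + 1L
    if (!hits_consistent(h, v$hit, tolerance = consistency_tol)) next
    stats["consistent"] <- stats["consistent"] + 1L
    vh <- v$hit
    vh$query_seq <- v$aligned_seq
    call <- extract_insertion(vh, genome, sample, min_flank = min_flank)
    if (is.null(call)) next
    call$source <- queries$source[i]
    calls <- rbind(calls, call)
  }
  stats["calls"] <- nrow(calls)
  list(calls = calls, contigs = contigs, stats = stats)
}

#' Keep calls whose anchor lies inside an enhancer peak
#'
#' @param calls insertion call `data.frame`.
#' @param peaks peaks `data.frame` (`chrom`, `start`, `end`, half-open).
#' @return filtered calls.
#' @export
filter_enhancer_overlap <- function(calls, peaks) {
  if (nrow(calls) == 0L || nrow(peaks) == 0L) {
    return(calls[integer(0), , drop = FALSE])
  }
  q <- GenomicRanges::GRanges(calls$chrom,
                              IRanges::IRanges(calls$position + 1L,
                                               width = 1L))
  s <- GenomicRanges::GRanges(peaks$chrom,
                              IRanges::IRanges(peaks$start + 1L, peaks$end))
  hit <- GenomicRanges::countOverlaps(q, s) > 0L
  calls[hit, , drop = FALSE]
}

#' Build a multi-sample insertion catalogue
#'
#' Groups per-sample calls by variant key; each entry records the sample
#' set, the summed read+contig support, and source flags.  The entry count
#' equals the number of distinct keys and does not depend on input order.
#'
#' @param per_sample_calls insertion call `data.frame` (possibly spanning
#'   samples), or a list of them.
#' @return catalogue `data.frame` with columns `key`, `chrom`, `position`,
#'   `sequence`, `samples`, `support`, `source_read`, `source_contig`,
#'   `in_dbsnp`, `recurrent`.
#' @export
build_catalogue <- function(per_sample_calls) {
  if (is.data.frame(per_sample_calls)) {
    calls <- per_sample_calls
  } else {
    calls <- do.call(rbind, per_sample_calls)
  }
  if (is.null(calls) || nrow(calls) == 0L) {
    return(data.frame(key = character(), chrom = character(),
                      position = integer(), sequence = character(),
                      samples = character(), support = integer(),
                      source_read = logical(), source_contig = logical(),
                      in_dbsnp = logical(), recurrent = logical(),
                      stringsAsFactors = FALSE))
  }
  keys <- sort(unique(calls$key))
  rows <- lapply(keys, function(k) {
    sub <- calls[calls$key == k, , drop = FALSE]
    data.frame(key = k, chrom = sub$chrom[1], position = sub$position[1],
               sequence = sub$sequence[1],
               samples = paste(sort(unique(sub$sample)), collapse = ","),
               support = nrow(sub),
               source_read = any(sub$source == "read"),
               source_contig = any(sub$source == "contig"),
               in_dbsnp = NA, recurrent = NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.catalogue_samples <- function(entries) {
  strsplit(entries$samples, ",", fixed = TRUE)
}

#' Contig-only deletion calling
#'
#' Deletions are determined from contigs only: each contig is realigned
#' with the gapped aligner and accepted iff its alignment is exactly
#' M,D,M with zero I ops and zero mismatches, confirmed by an exhaustive
#' zero-mismatch scan around the locus.  The deletion interval is the
#' reference span of the D op, left-normalized.
#'
#' @param contigs list from [assemble_contigs()].
#' @param genome an `enh_genome`.
#' @param sample sample identifier.
#' @param consistency_tol maximum distance between gapped and
#'   verification placements.
#' @return `data.frame` with `chrom`, `start`, `end`, `sample`,
#'   `contig_id`.
#' @export
call_deletions <- function(contigs, genome, sample = "sample",
                           consistency_tol = 100) {
  out <- data.frame(chrom = character(), start = integer(),
                    end = integer(), sample = character(),
                    contig_id = character(), stringsAsFactors = FALSE)
  if (length(contigs) == 0L) return(out)
  hits <- map_gapped_batch(
    stats::setNames(vapply(contigs, `[[`, "", "sequence"),
                    vapply(contigs, `[[`, "", "id")), genome)
  for (i in seq_along(contigs)) {
    h <- hits[[i]]
    if (!identical(h$status, "mapped")) next
    ops <- parse_cigar(h$cigar)
    if (!(nrow(ops) == 3L && all(ops$op == c("M", "D", "M")))) next
    if (h$mismatches != 0L) next
    seq <- contigs[[i]]$sequence
    oriented <- if (h$strand == "-") revcomp(seq) else seq
    chrom_seq <- genome[[h$chrom]]
    pad <- nchar(seq) + 210L
    w0 <- max(0L, h$start - pad)
    w1 <- min(nchar(chrom_seq),
              h$start + .cigar_ref_span(ops) + pad)
    sc <- .scan_single_deletion(oriented, .subseq0(chrom_seq, w0, w1))
    if (nrow(sc) == 0L) next
    if (length(unique(sc$g)) > 1L) next  # ambiguous placement
    g <- w0 + sc$g[1]
    if (abs(g - h$start) > consistency_tol) next
    a <- sc$a_min[1]
    d <- sc$d[1]
    nn <- .left_normalize_deletion(chrom_seq, g + a, g + a + d)
    out <- rbind(out, data.frame(chrom = h$chrom, start = nn$start,
                                 end = nn$end, sample = sample,
                                 contig_id = contigs[[i]]$id,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Per-sample discovery pipeline
#'
#' Runs the full per-sample flow: gapless mapping, peak definition (or a
#' supplied peak BED), rescue of unmapped reads and contigs, enhancer
#' filtering.
#'
#' @param reads `data.frame` with `id`, `sequence`.
#' @param genome an `enh_genome`.
#' @param sample sample identifier.
#' @param peaks optional externally supplied peaks (bypasses
#'   [call_peaks()]).
#' @param control_reads optional control reads for peak calling.
#' @param include_ambiguous feed ambiguously placed (multiread) reads to
#'   the rescue path along with no-hit reads.
#' @param max_mismatches gapless-pass mismatch budget.
#' @param ... passed to [rescue_unmapped()].
#' @return list with `calls` (enhancer-filtered), `all_calls`, `peaks`,
#'   `contigs`, `stats`.
#' @export
call_sample <- function(reads, genome, sample = "sample", peaks = NULL,
                        control_reads = NULL, include_ambiguous = TRUE,
                        max_mismatches = 2, ...) {
  reads <- .as_reads_df(reads)
  aligned <- map_ungapped(reads, genome, max_mismatches = max_mismatches)
  mapped <- aligned[aligned$status == "unique", , drop = FALSE]
  keep_status <- if (include_ambiguous) c("no_hit", "ambiguous") else
    "no_hit"
  unmapped_ids <- aligned$id[aligned$status %in% keep_status]
  unmapped <- reads[reads$id %in% unmapped_ids, , drop = FALSE]
  if (is.null(peaks)) {
    ctrl <- NULL
    if (!is.null(control_reads)) {
      ca <- map_ungapped(.as_reads_df(control_reads), genome,
                         max_mismatches = max_mismatches)
      ca <- ca[ca$status == "unique", , drop = FALSE]
      ctrl <- data.frame(chrom = ca$chrom, pos = ca$start,
                         stringsAsFactors = FALSE)
    }
    peaks <- call_peaks(data.frame(chrom = mapped$chrom, pos = mapped$start,
                                   stringsAsFactors = FALSE),
                        genome, control_positions = ctrl)
  }
  rescue <- rescue_unmapped(unmapped, genome, sample = sample, ...)
  in_enh <- filter_enhancer_overlap(rescue$calls, peaks)
  stats <- c(total = nrow(reads), mapped = nrow(mapped),
             rescue$stats, in_enhancer = nrow(in_enh))
  list(calls = in_enh, all_calls = rescue$calls, peaks = peaks,
       contigs = rescue$contigs, stats = stats)
}
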