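#' CIGAR utilities
#'
#' CIGARs use M (consumes read and reference), I (read only) and
#' D (reference only); adjacent operations always differ.
#'
#' @param cigar CIGAR string such as `"20M4I20M"`.
#' @return `data.frame` with columns `op`, `len`.
#' @export
parse_cigar <- function(cigar) {
  ops <- gregexpr("[0-9]+[MID]", cigar)[[1]]
  if (ops[1] == -1L || sum(attr(ops, "match.length")) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar, call. = FALSE)
  }
  toks <- regmatches(cigar, gregexpr("[0-9]+[MID]", cigar))[[1]]
  data.frame(op = substr(toks, nchar(toks), nchar(toks)),
             len = as.integer(substr(toks, 1L, nchar(toks) - 1L)),
             stringsAsFactors = FALSE)
}

.cigar_string <- function(ops) {
  ops <- ops[ops$len > 0L, , drop = FALSE]
  # merge adjacent identical ops
  keep <- c(TRUE, ops$op[-1] != ops$op[-nrow(ops)])
  grp <- cumsum(keep)
  len <- tapply(ops$len, grp, sum)
  op <- ops$op[keep]
  paste0(as.integer(len), op, collapse = "")
}

.cigar_query_len <- function(ops) sum(ops$len[ops$op %in% c("M", "I")])
.cigar_ref_span <- function(ops) sum(ops$len[ops$op %in% c("M", "D")])

# rebuild the query implied by (reference, start, cigar, query) M/I/D walk;
# used by tests and the verification invariant
.reconstruct_query <- function(chrom_seq, start, cigar, query) {
  ops <- parse_cigar(cigar)
  out <- character(0)
  qpos <- 0L
  rpos <- start
  for (i in seq_len(nrow(ops))) {
    len <- ops$len[i]
    if (ops$op[i] == "M") {
      out <- c(out, .subseq0(chrom_seq, rpos, rpos + len))
      qpos <- qpos + len
      rpos <- rpos + len
    } else if (ops$op[i] == "I") {
      out <- c(out, substr(query, qpos + 1L, qpos + len))
      qpos <- qpos + len
    } else {
      rpos <- rpos + len
    }
  }
  paste0(out, collapse = "")
}

.as_reads_df <- function(reads) {
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read%d", seq_along(reads))
    reads <- data.frame(id = ids, sequence = unname(reads),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "sequence") %in% names(reads)))
  reads$sequence <- toupper(reads$sequence)
  reads
}

#' Gapless best-stratum read mapping
#'
#' Maps each read full-length and without gaps against both strands of the
#' genome, keeping the unique placement in the best (minimal) mismatch
#' stratum.  Two or more placements tied at the best mismatch count give
#' `status = "ambiguous"`; no placement within `max_mismatches` gives
#' `status = "no_hit"`.  Both kinds of unmapped read feed the rescue path.
#'
#' @param reads character vector of sequences (optionally named) or a
#'   `data.frame` with `id` and `sequence`.
#' @param genome an `enh_genome`.
#' @param max_mismatches maximum mismatches for a valid placement.
#' @return `data.frame` with columns `id`, `status` (`unique`, `ambiguous`,
#'   `no_hit`), `chrom`, `start` (0-based), `strand`, `mismatches`.
#' @export
map_ungapped <- function(reads, genome, max_mismatches = 2) {
  reads <- .as_reads_df(reads)
  .check_alphabet(reads$sequence, "read")
  if (nrow(reads) == 0L) {
    return(data.frame(id = character(), status = character(),
                      chrom = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- .cpp_map_ungapped_batch(reads$sequence, unclass(genome),
                                 as.integer(max_mismatches))
  data.frame(id = reads$id,
             status = c("unique", "ambiguous", "no_hit")[res$status + 1L],
             chrom = names(genome)[res$chrom],
             start = res$start,
             strand = as.character(res$strand),
             mismatches = res$mismatches,
             stringsAsFactors = FALSE)
}

# canonical (leftmost) gap placement: shifting a gap left across equal
# characters leaves the aligned sequence pair unchanged, so equivalent
# placements collapse onto one representation.  Insertions rotate on query
# characters, deletions on reference characters.
.canonical_gap_a <- function(op, a, gap_len, query, chrom_seq, start) {
  if (op == "I") {
    while (a > 0L &&
           substr(query, a, a) == substr(query, a + gap_len, a + gap_len)) {
      a <- a - 1L
    }
  } else if (op == "D") {
    while (a > 1L &&
           .subseq0(chrom_seq, start + a - 1L, start + a) ==
           .subseq0(chrom_seq, start + a + gap_len - 1L,
                    start + a + gap_len)) {
      a <- a - 1L
    }
  }
  a
}

.gap_cigar <- function(op, a, gap_len, qlen) {
  if (op == "N") return(sprintf("%dM", qlen))
  if (op == "I") {
    ops <- data.frame(op = c("M", "I", "M"),
                      len = c(a, gap_len, qlen - a - gap_len),
                      stringsAsFactors = FALSE)
  } else {
    ops <- data.frame(op = c("M", "D", "M"),
                      len = c(a, gap_len, qlen - a),
                      stringsAsFactors = FALSE)
  }
  .cigar_string(ops)
}

#' Insertion-aware gapped alignment
#'
#' Seeded single-indel alignment: the query is aligned end-to-end against
#' both strands, allowing at most one contiguous gap (an insertion of up
#' to `max_insertion` bases or a deletion of up to `max_deletion` bases),
#' scored match +1, mismatch -1, gap open -2 and gap extend -1 (a gap of
#' length k costs k + 1).  The single best-scoring placement is reported;
#' distinct placements tied at the best score yield
#' `unmapped(ambiguous)`.  The returned CIGAR is authoritative for where
#' and what an insertion is.  The one-gap restriction matches what the
#' downstream verification accepts - a short read or contig is interpreted
#' as carrying at most one small indel - and makes the aligner exactly
#' equivalent to an exhaustive split-point enumeration over seeded loci.
#'
#' @param seq query sequence (single string), at least 20 bp.
#' @param genome an `enh_genome`.
#' @param seed_k seed k-mer size for candidate window discovery.
#' @param window_pad bases of slack around seed clusters.
#' @param max_insertion largest insertion considered by the aligner.
#' @param max_deletion largest deletion considered by the aligner.
#' @return a hit: list with `query_id`, `chrom`, `start`, `strand`,
#'   `cigar`, `score`, `mismatches`, `unique`; or a list with
#'   `status = "no_hit"` / `"ambiguous"` when unmapped.
#' @export
map_gapped <- function(seq, genome, seed_k = 11, window_pad = 50,
                       max_insertion = 31, max_deletion = 50) {
  res <- map_gapped_batch(stats::setNames(seq, "query"), genome,
                          seed_k = seed_k, window_pad = window_pad,
                          max_insertion = max_insertion,
                          max_deletion = max_deletion)
  res[[1]]
}

#' Batch version of [map_gapped()]
#'
#' @param seqs named character vector of query sequences.
#' @inheritParams map_gapped
#' @return list of hits / unmapped markers, one per query.
#' @export
map_gapped_batch <- function(seqs, genome, seed_k = 11, window_pad = 50,
                             max_insertion = 31, max_deletion = 50) {
  seqs <- toupper(seqs)
  .check_alphabet(seqs, "query")
  if (any(nchar(seqs) < 20L)) {
    stop("gapped alignment requires sequences of at least 20 bp",
         call. = FALSE)
  }
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("query%d", seq_along(seqs))
  raw <- .cpp_map_gapped_batch(unname(seqs), unclass(genome),
                               as.integer(seed_k), as.integer(window_pad),
                               as.integer(max_insertion),
                               as.integer(max_deletion))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    hits <- raw[[i]]
    if (is.null(hits) || nrow(hits) == 0L) {
      out[[i]] <- list(query_id = ids[i], status = "no_hit")
      next
    }
    qseq <- unname(seqs[i])
    qlen <- nchar(qseq)
    cigars <- character(nrow(hits))
    for (h in seq_len(nrow(hits))) {
      chrom <- names(genome)[hits$chrom[h]]
      q <- if (hits$strand[h] == "-") revcomp(qseq) else qseq
      a_c <- .canonical_gap_a(hits$op[h], hits$a[h], hits$gap_len[h], q,
                              genome[[chrom]], hits$start[h])
      cigars[h] <- .gap_cigar(hits$op[h], a_c, hits$gap_len[h], qlen)
    }
    sig <- paste(hits$chrom, hits$start, hits$strand, cigars)
    keep <- !duplicated(sig)
    hits <- hits[keep, , drop = FALSE]
    cigars <- cigars[keep]
    if (nrow(hits) > 1L) {
      out[[i]] <- list(query_id = ids[i], status = "ambiguous")
      next
    }
    out[[i]] <- list(query_id = ids[i],
                     status = "mapped",
                     chrom = names(genome)[hits$chrom[1]],
                     start = hits$start[1],
                     strand = hits$strand[1],
                     cigar = cigars[1],
                     score = hits$score[1],
                     mismatches = hits$mismatches[1],
                     unique = TRUE)
  }
  names(out) <- ids
  out
}

#' Exhaustive verification of an insertion-bearing hit
#'
#' Independent replacement for the BLAT cross-check: the query is
#' exhaustively realigned around the hit locus, enumerating every
#' single-insertion decomposition with zero mismatches.  The hit is
#' accepted iff a single best placement (1) consumes the whole query,
#' (2) contains exactly one insertion, (3) the insertion is shorter than
#' the query, (4) the flanks match without mismatches, and (5) the
#' insertion is at most `max_insertion` bases.  The accepted hit is
#' left-normalized.
#'
#' @param seq query sequence, oriented as aligned (plus strand of the
#'   reference); pass the reverse complement for minus-strand hits.
#' @param genome an `enh_genome`.
#' @param hit hit from [map_gapped()] (used to centre the search window).
#' @param max_insertion maximum accepted insertion length (the stricter
#'   BLAT-style cap of 20 by default; raise to 31 for contig calls).
#' @return list with `accepted`, `reason` (`ok`, `gapless`, `mismatch`,
#'   `too_long`, `ambiguous`), and for accepted hits the canonical `hit`
#'   plus `anchor`, `insert`, `a_min`, `a_max` (range of left-flank
#'   lengths over equivalent placements).
#' @export
verify_hit <- function(seq, genome, hit, max_insertion = 20) {
  seq <- toupper(seq)
  L <- nchar(seq)
  chrom <- hit$chrom
  chrom_seq <- genome[[chrom]]
  pad <- L + max(max_insertion, 31L) + 10L
  ref_span <- .cigar_ref_span(parse_cigar(hit$cigar))
  w0 <- max(0L, hit$start - pad)
  w1 <- min(nchar(chrom_seq), hit$start + ref_span + pad)
  text <- .subseq0(chrom_seq, w0, w1)
  found <- .scan_single_insertion(seq, text)
  # the reverse orientation is a competing placement for ambiguity purposes
  found_rc <- .scan_single_insertion(revcomp(seq), text)

  if (found$gapless || found_rc$gapless) {
    return(list(accepted = FALSE, reason = "gapless"))
  }
  k_best <- min(found$k, found_rc$k)
  if (!is.finite(k_best)) {
    return(list(accepted = FALSE, reason = "mismatch"))
  }
  if (k_best > max_insertion) {
    # distinguish a genuinely long insertion (the aligner's own CIGAR
    # already exceeds the cap) from flank mismatches that force the
    # zero-mismatch realignment to absorb extra bases into the gap
    hit_ops <- parse_cigar(hit$cigar)
    hit_k <- sum(hit_ops$len[hit_ops$op == "I"])
    reason <- if (hit_k > max_insertion) "too_long" else "mismatch"
    return(list(accepted = FALSE, reason = reason))
  }
  use_rc <- found_rc$k < found$k
  both <- is.finite(found$k) && is.finite(found_rc$k) && found$k == found_rc$k
  placements <- if (use_rc) found_rc$placements else found$placements
  if (both) placements <- rbind(found$placements, found_rc$placements)
  placements <- placements[placements$k == k_best, , drop = FALSE]
  if (length(unique(placements$g)) > 1L || both) {
    return(list(accepted = FALSE, reason = "ambiguous"))
  }
  qseq <- if (use_rc) revcomp(seq) else seq
  strand <- hit$strand
  if (use_rc) strand <- if (identical(strand, "-")) "+" else "-"
  g <- placements$g[1]
  a_min <- placements$a_min[1]
  a_max <- placements$a_max[1]
  k <- k_best
  b <- L - k - a_min
  start <- w0 + g
  cigar <- .cigar_string(data.frame(op = c("M", "I", "M"),
                                    len = c(a_min, k, b),
                                    stringsAsFactors = FALSE))
  anchor <- start + a_min - 1L
  insert <- substr(qseq, a_min + 1L, a_min + k)
  vh <- list(query_id = hit$query_id, status = "mapped", chrom = chrom,
             start = start, strand = strand,
             cigar = cigar, score = (L - k) - (k + 1L), mismatches = 0L,
             unique = TRUE)
  list(accepted = TRUE, reason = "ok", hit = vh, anchor = anchor,
       insert = insert, a_min = a_min, a_max = a_max,
       aligned_seq = qseq)
}

# enumerate all zero-mismatch single-insertion placements of seq in text.
# Returns gapless flag, minimal insertion size k, and for each genome
# offset g the feasible left-flank range [a_min, a_max].
.scan_single_insertion <- function(seq, text) {
  L <- nchar(seq)
  nt <- nchar(text)
  if (nt < 1L || L < 2L) {
    return(list(gapless = FALSE, k = Inf,
                placements = data.frame(g = integer(), k = integer(),
                                        a_min = integer(),
                                        a_max = integer())))
  }
  P <- .cpp_prefix_match_lengths(seq, text)      # length nt, P[g+1]
  E <- .cpp_suffix_match_lengths(seq, text)      # length nt+1, E[p+1]
  gapless <- any(P >= L)
  rows <- list()
  k_min <- Inf
  g_all <- seq_len(nt) - 1L                      # 0-based offsets
  for (k in seq_len(L - 1L)) {
    span <- L - k                                # reference bases consumed
    ends <- g_all + span                         # 0-based end position
    ok <- ends <= nt
    if (!any(ok)) break
    g <- g_all[ok]
    e_at <- E[ends[ok] + 1L]
    p_at <- P[g + 1L]
    a_min <- pmax(0L, span - e_at)
    a_max <- pmin(p_at, span)
    feas <- a_max >= a_min & (p_at + e_at >= span)
    if (any(feas)) {
      rows[[length(rows) + 1L]] <-
        data.frame(g = g[feas], k = k, a_min = a_min[feas],
                   a_max = a_max[feas])
      k_min <- min(k_min, k)
      break  # placements at the minimal k are all we need
    }
  }
  placements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(g = integer(), k = integer(), a_min = integer(),
               a_max = integer())
  list(gapless = gapless, k = k_min, placements = placements)
}

# exhaustive zero-mismatch M-D-M scan used by the deletion caller
.scan_single_deletion <- function(seq, text, max_deletion = 200L) {
  L <- nchar(seq)
  nt <- nchar(text)
  P <- .cpp_prefix_match_lengths(seq, text)
  E <- .cpp_suffix_match_lengths(seq, text)
  g_all <- seq_len(nt) - 1L
  for (d in seq_len(max_deletion)) {
    ends <- g_all + L + d
    ok <- ends <= nt
    if (!any(ok)) break
    g <- g_all[ok]
    e_at <- E[ends[ok] + 1L]
    p_at <- P[g + 1L]
    a_min <- pmax(1L, L - e_at)
    a_max <- pmin(p_at, L - 1L)
    feas <- a_max >= a_min
    if (any(feas)) {
      return(data.frame(g = g[feas], d = d, a_min = a_min[feas],
                        a_max = a_max[feas]))
    }
  }
  data.frame(g = integer(), d = integer(), a_min = integer(),
             a_max = integer())
}

#' Positional consistency of two hits for the same query
#'
#' Mirrors the requirement that the gapped-aligner hit and the
#' verification hit lie within `tolerance` bases of each other.
#'
#' @param hit_a,hit_b hits for the same query.
#' @param tolerance maximum start-position difference in bases.
#' @return `TRUE` iff both hits are on the same chromosome within
#'   `tolerance`.
#' @export
hits_consistent <- function(hit_a, hit_b, tolerance = 100) {
  if (!identical(hit_a$query_id, hit_b$query_id)) {
    stop("hits_consistent: hits are for different queries", call. = FALSE)
  }
  identical(hit_a$chrom, hit_b$chrom) &&
    abs(hit_a$start - hit_b$start) <= tolerance
}
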