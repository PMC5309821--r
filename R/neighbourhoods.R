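#' Filter loops to high-confidence insulated neighbourhoods
#'
#' Keeps loops with `fdr < max_fdr` AND CTCF-enriched regions contacting
#' both anchors.
#'
#' @param loops loop `data.frame` from [read_bedpe()].
#' @param max_fdr FDR cutoff (strict inequality).
#' @return filtered loops.
#' @export
filter_loops <- function(loops, max_fdr = 0.2) {
  loops[loops$fdr < max_fdr & loops$ctcf_both, , drop = FALSE]
}

#' Smallest insulated neighbourhood containing a position
#'
#' Loops can nest, so a position may fall inside several; the smallest
#' containing loop (by outer span, `[anchor1.start, anchor2.end)`) is
#' used.  Ties on span length are broken by leftmost span start, then
#' input order.
#'
#' @param chrom,position anchor to place (0-based).
#' @param loops filtered loop `data.frame`.
#' @return integer row index into `loops`, or `NA` when no loop contains
#'   the position.
#' @export
assign_smallest_loop <- function(chrom, position, loops) {
  if (nrow(loops) == 0L) return(NA_integer_)
  containing <- which(loops$chrom == chrom &
                        loops$span_start <= position &
                        position < loops$span_end)
  if (length(containing) == 0L) return(NA_integer_)
  span <- loops$span_end[containing] - loops$span_start[containing]
  ord <- order(span, loops$span_start[containing], containing)
  containing[ord[1]]
}

#' Genes sharing an insulated neighbourhood with an insertion
#'
#' Active genes whose TSS lies within the loop's outer span are assigned;
#' `contains_oncogene` reports whether any assigned gene is a catalogued
#' oncogene.
#'
#' @param key serialized variant key (identifies the insertion).
#' @param loop_idx loop row index from [assign_smallest_loop()] (`NA`
#'   allowed).
#' @param loops filtered loop `data.frame`.
#' @param genes gene `data.frame` with `name`, `chrom`, `tss`, `strand`,
#'   `active`, `oncogene`.
#' @return list with `key`, `loop` (row index or `NA`), `genes`
#'   (character vector), `contains_oncogene`.
#' @export
assign_genes <- function(key, loop_idx, loops, genes) {
  if (is.na(loop_idx)) {
    return(list(key = key, loop = NA_integer_, genes = character(),
                contains_oncogene = FALSE))
  }
  lp <- loops[loop_idx, , drop = FALSE]
  in_loop <- genes$active & genes$chrom == lp$chrom &
    genes$tss >= lp$span_start & genes$tss < lp$span_end
  list(key = key, loop = loop_idx, genes = genes$name[in_loop],
       contains_oncogene = any(genes$oncogene[in_loop]))
}

#' Assign every catalogue entry to its insulated neighbourhood
#'
#' @param catalogue catalogue `data.frame`.
#' @param loops loop `data.frame` (filtered with [filter_loops()]).
#' @param genes gene `data.frame`.
#' @return `data.frame` with `key`, `loop`, `genes` (comma-separated),
#'   `contains_oncogene`.
#' @export
assign_catalogue <- function(catalogue, loops, genes) {
  rows <- lapply(seq_len(nrow(catalogue)), function(i) {
    li <- assign_smallest_loop(catalogue$chrom[i], catalogue$position[i],
                               loops)
    g <- assign_genes(catalogue$key[i], li, loops, genes)
    data.frame(key = g$key, loop = g$loop,
               genes = paste(g$genes, collapse = ","),
               contains_oncogene = g$contains_oncogene,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(key = character(), loop = integer(),
                      genes = character(), contains_oncogene = logical(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Mark genes active by promoter-proximal H3K27ac
#'
#' A helper criterion for the `active` flag: a gene is active iff an
#' H3K27ac peak overlaps a window (default +/- 1 kb) around its TSS.
#'
#' @param genes gene `data.frame`.
#' @param peaks H3K27ac peaks `data.frame`.
#' @param window half-width of the promoter window in bases.
#' @return `genes` with the `active` column set.
#' @export
mark_active_genes <- function(genes, peaks, window = 1000) {
  if (nrow(genes) == 0L) { genes$active <- logical(0); return(genes) }
  q <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$tss - window + 1L), genes$tss + window))
  s <- GenomicRanges::GRanges(peaks$chrom,
                              IRanges::IRanges(peaks$start + 1L, peaks$end))
  genes$active <- GenomicRanges::countOverlaps(q, s) > 0L
  genes
}

# per-loop oncogene flag (any active oncogene TSS in span)
.loop_onco_flags <- function(loops, genes) {
  vapply(seq_len(nrow(loops)), function(li) {
    in_loop <- genes$active & genes$chrom == loops$chrom[li] &
      genes$tss >= loops$span_start[li] & genes$tss < loops$span_end[li]
    any(genes$oncogene[in_loop])
  }, TRUE)
}

# vectorized smallest-containing-loop assignment; same tie-breaking as
# assign_smallest_loop (span length, leftmost span start, input order)
.assign_loops_vec <- function(chrom, position, loops) {
  assigned <- rep(NA_integer_, length(position))
  if (nrow(loops) == 0L) return(assigned)
  span <- loops$span_end - loops$span_start
  for (li in order(span, loops$span_start, seq_len(nrow(loops)))) {
    open <- is.na(assigned) & chrom == loops$chrom[li] &
      position >= loops$span_start[li] & position < loops$span_end[li]
    assigned[open] <- li
  }
  assigned
}

# oncogene-neighbourhood indicator for a vector of positions
.onco_indicator <- function(chrom, position, loops, genes,
                            onco_loop = .loop_onco_flags(loops, genes)) {
  li <- .assign_loops_vec(chrom, position, loops)
  out <- !is.na(li)
  out[!is.na(li)] <- onco_loop[li[!is.na(li)]]
  out
}

# uniform draw of n positions from the collapsed enhancer union
.sample_union_positions <- function(union_peaks, n) {
  widths <- union_peaks$end - union_peaks$start
  iv <- sample.int(nrow(union_peaks), n, replace = TRUE,
                   prob = widths / sum(widths))
  data.frame(chrom = union_peaks$chrom[iv],
             position = union_peaks$start[iv] +
               floor(runif(n) * widths[iv]),
             stringsAsFactors = FALSE)
}

#' Permutation test for oncogene-neighbourhood enrichment
#'
#' Observed statistic: the number of insertions whose smallest insulated
#' neighbourhood contains a catalogued oncogene.  Null: each permutation
#' re-places every insertion uniformly at random within the collapsed
#' enhancer union and recomputes the statistic.  The permutation scheme
#' (uniform re-placement within the union) is this package's
#' construction.  `p = (1 + #\{perm >= observed\}) / (1 + n_perm)`, so
#' `p >= 1 / (n_perm + 1)` always.
#'
#' @param catalogue catalogue `data.frame` (anchors to test).
#' @param loops filtered loop `data.frame`.
#' @param genes gene `data.frame`.
#' @param union_peaks collapsed enhancer union (the permutation domain).
#' @param n_perm number of permutations.
#' @param seed RNG seed (results are bit-reproducible given the seed).
#' @return list with `observed`, `n`, `perm_mean`, `p_value`.
#' @export
oncogene_enrichment_test <- function(catalogue, loops, genes, union_peaks,
                                     n_perm = 10000, seed = 1) {
  if (nrow(union_peaks) == 0L) {
    stop("empty enhancer union: no permutation domain", call. = FALSE)
  }
  onco_loop <- .loop_onco_flags(loops, genes)
  obs <- sum(.onco_indicator(catalogue$chrom, catalogue$position, loops,
                             genes, onco_loop))
  n <- nrow(catalogue)
  perm <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      draw <- .sample_union_positions(union_peaks, n)
      sum(.onco_indicator(draw$chrom, draw$position, loops, genes,
                          onco_loop))
    }, 0L)
  })
  list(observed = obs, n = n, perm_mean = mean(perm),
       p_value = (1 + sum(perm >= obs)) / (1 + n_perm))
}
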