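#' Greedy exact-overlap contig assembly
#'
#' Assembles initially unmapped reads into contigs by repeatedly merging
#' the pair with the longest exact suffix/prefix overlap at or above
#' `min_overlap`, in either orientation; contained reads are absorbed.
#' Ties between equal-length overlaps are broken by the lexicographically
#' smallest member read id, making assembly deterministic.  Contigs are
#' coverage-trimmed so that every retained base has read depth at least
#' `min_coverage`; contigs with an interior coverage dip or no qualifying
#' base are dropped.  Extends effective read length so that insertions too
#' large for a single read to bridge become callable.
#'
#' @param reads character vector of sequences (optionally named) or
#'   `data.frame` with `id`, `sequence`.
#' @param min_overlap minimum exact overlap for a merge (bases).
#' @param min_coverage minimum per-base read depth retained after trimming.
#' @return list of contigs; each is a list with `id`, `sequence`,
#'   `member_read_ids`, `coverage` (integer depth per base).
#' @export
assemble_contigs <- function(reads, min_overlap = 20, min_coverage = 5) {
  reads <- .as_reads_df(reads)
  if (nrow(reads) == 0L) return(list())
  .check_alphabet(reads$sequence, "read")
  items <- .cpp_assemble(reads$sequence, reads$id, as.integer(min_overlap))
  contigs <- list()
  for (it in items) {
    len <- nchar(it$sequence)
    depth <- integer(len)
    rlens <- nchar(reads$sequence[it$read])
    for (m in seq_along(it$read)) {
      lo <- it$offset[m] + 1L
      hi <- it$offset[m] + rlens[m]
      depth[lo:hi] <- depth[lo:hi] + 1L
    }
    ok <- depth >= min_coverage
    if (!any(ok)) next
    first <- which(ok)[1]
    last <- utils::tail(which(ok), 1)
    if (!all(ok[first:last])) next  # interior dip: not a clean contig
    seq <- substr(it$sequence, first, last)
    inside <- it$offset + 1L >= first & it$offset + rlens <= last
    members <- reads$id[it$read[inside]]
    if (length(members) == 0L) next
    if (nchar(seq) < max(nchar(reads$sequence[it$read[inside]]))) next
    contigs[[length(contigs) + 1L]] <-
      list(sequence = seq,
           member_read_ids = members,
           coverage = depth[first:last])
  }
  for (i in seq_along(contigs)) contigs[[i]]$id <- sprintf("contig%d", i)
  contigs
}

#' Truncate heterogeneous-length reads to a common prefix
#'
#' When input read lengths are inconsistent, contigs are built from the
#' first `prefix_len` bases of each read.  Reads shorter than `prefix_len`
#' are dropped with a warning.
#'
#' @param reads `data.frame` with `id`, `sequence` (or character vector).
#' @param prefix_len number of leading bases to keep.
#' @return `data.frame` of truncated reads.
#' @export
truncate_reads <- function(reads, prefix_len = 25) {
  reads <- .as_reads_df(reads)
  short <- nchar(reads$sequence) < prefix_len
  if (any(short)) {
    warning(sprintf("dropping %d read(s) shorter than %d bases",
                    sum(short), prefix_len), call. = FALSE)
    reads <- reads[!short, , drop = FALSE]
  }
  reads$sequence <- substr(reads$sequence, 1L, prefix_len)
  reads
}

#' Export contigs as FASTA with coverage in the description line
#' @param contigs list from [assemble_contigs()].
#' @param path output file.
#' @export
write_contigs_fasta <- function(contigs, path) {
  lines <- unlist(lapply(contigs, function(ct) {
    c(sprintf(">%s reads=%d min_cov=%d", ct$id,
              length(ct$member_read_ids), min(ct$coverage)),
      ct$sequence)
  }))
  writeLines(lines, path)
  invisible(path)
}
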