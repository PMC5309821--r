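#' Build per-allele custom genomes for amplicon confirmation
#'
#' The reference custom genome covers `flank` bases up to and including
#' the anchor plus `flank` bases downstream (length `2 * flank`); the
#' insertion custom genome is the same window with the predicted sequence
#' spliced in after the anchor.  Windows within `flank` of a chromosome
#' end are clipped with a warning and the actual extent recorded.
#'
#' @param genome an `enh_genome`.
#' @param key one-row key `data.frame` or serialized key.
#' @param flank bases up- and downstream of the insertion position.
#' @return list with `ref`, `alt`, `window_start`, `window_end`,
#'   `anchor_offset` (0-based anchor index inside `ref`), `ins_len`,
#'   `clipped`.
#' @export
build_confirmation_genomes <- function(genome, key, flank = 250) {
  if (is.character(key)) key <- parse_key(key)
  chrom_seq <- genome[[key$chrom]]
  if (is.null(chrom_seq)) stop("unknown chromosome: ", key$chrom,
                               call. = FALSE)
  clen <- nchar(chrom_seq)
  anchor <- key$position
  w0 <- anchor - flank + 1L
  w1 <- anchor + flank + 1L
  clipped <- w0 < 0L || w1 > clen
  if (clipped) {
    warning("confirmation window clipped at chromosome end", call. = FALSE)
  }
  w0 <- max(0L, w0)
  w1 <- min(clen, w1)
  ref <- .subseq0(chrom_seq, w0, w1)
  off <- anchor - w0
  alt <- paste0(substr(ref, 1L, off + 1L), key$sequence,
                substr(ref, off + 2L, nchar(ref)))
  list(ref = ref, alt = alt, window_start = w0, window_end = w1,
       anchor_offset = off, ins_len = nchar(key$sequence),
       clipped = clipped, key = key$key)
}

#' Call allele presence and zygosity from amplicon reads
#'
#' Amplicon reads are assembled into contigs (minimum 5x coverage per
#' retained base); each contig is aligned gaplessly with zero mismatches
#' to each per-allele custom genome.  An allele is present iff at least
#' one contig aligns uniquely to its custom genome with the alignment
#' interval strictly containing the insertion anchor (reference allele)
#' or the full inserted span (insertion allele) - a contig that does not
#' contact the predicted position contributes no evidence.  Zygosity
#' derives from the two presence flags; with no informative contigs the
#' call is `undetermined`.
#'
#' @param amplicon_reads reads `data.frame` or character vector.
#' @param genomes custom genome pair from [build_confirmation_genomes()].
#' @param min_overlap,min_coverage assembly parameters.
#' @return list with `key`, `ref_present`, `alt_present`, `zygosity`
#'   (`ref_only`, `het`, `alt_only`, `undetermined`), `n_contigs`.
#' @export
call_allele_presence <- function(amplicon_reads, genomes,
                                 min_overlap = 20, min_coverage = 5) {
  contigs <- assemble_contigs(amplicon_reads, min_overlap = min_overlap,
                              min_coverage = min_coverage)
  ref_present <- FALSE
  alt_present <- FALSE
  off <- genomes$anchor_offset
  ins_len <- genomes$ins_len
  if (length(contigs) > 0L) {
    seqs <- stats::setNames(vapply(contigs, `[[`, "", "sequence"),
                            vapply(contigs, `[[`, "", "id"))
    on_ref <- map_ungapped(seqs, as_genome(c(ref = genomes$ref)),
                           max_mismatches = 0)
    on_alt <- map_ungapped(seqs, as_genome(c(alt = genomes$alt)),
                           max_mismatches = 0)
    lens <- nchar(seqs)
    # strict containment: at least one aligned base on each side of the
    # contacted feature
    ref_contact <- on_ref$status == "unique" &
      on_ref$start < off & on_ref$start + lens > off + 1L
    alt_contact <- on_alt$status == "unique" &
      on_alt$start < off + 1L & on_alt$start + lens > off + 1L + ins_len
    ref_present <- any(ref_contact)
    alt_present <- any(alt_contact)
  }
  zygosity <- if (ref_present && alt_present) "het" else
    if (alt_present) "alt_only" else
      if (ref_present) "ref_only" else "undetermined"
  list(key = genomes$key, ref_present = ref_present,
       alt_present = alt_present, zygosity = zygosity,
       n_contigs = length(contigs))
}
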