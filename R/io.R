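#' Genome container
#'
#' A genome is held as a named character vector of uppercase A/C/G/T/N
#' chromosome sequences (class `enh_genome`).  Names must be unique and
#' sequences non-empty.
#'
#' @param x named character vector or `Biostrings::DNAStringSet`.
#' @return an `enh_genome` object.
#' @export
as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("genome sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    stop("duplicate chromosome names: ",
         names(x)[duplicated(names(x))][1], call. = FALSE)
  }
  x <- toupper(x)
  if (any(nchar(x) == 0L)) stop("empty chromosome sequence", call. = FALSE)
  .check_alphabet(x, "genome sequence")
  structure(as.character(stats::setNames(x, names(x))),
            names = names(x), class = "enh_genome")
}

#' @export
print.enh_genome <- function(x, ...) {
  cat(sprintf("<enh_genome> %d sequence(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  for (nm in utils::head(names(x), 10)) {
    cat(sprintf("  %s: %d bp\n", nm, nchar(x[[nm]])))
  }
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome an `enh_genome`.
#' @return named integer vector.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(nchar(genome), names(genome))
}

#' Read a FASTA file into a genome
#'
#' Sequences are case-folded to uppercase; duplicate record names and
#' characters outside A/C/G/T/N are errors.
#'
#' @param path FASTA file.
#' @return an `enh_genome`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  if (!startsWith(lines[1], ">")) {
    stop(sprintf("%s: line 1: expected FASTA header starting with '>'",
                 path), call. = FALSE)
  }
  bad <- which(!startsWith(lines, ">") &
                 grepl("[^ACGTNacgtn]", lines))
  if (length(bad) > 0L) {
    stop(sprintf("%s: line %d: invalid sequence characters", path, bad[1]),
         call. = FALSE)
  }
  set <- Biostrings::readDNAStringSet(path)
  names(set) <- sub("\\s.*$", "", names(set))
  as_genome(set)
}

#' Write a genome to FASTA
#' @param genome an `enh_genome` (or named character vector).
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read single-end reads from a FASTQ file
#'
#' Qualities are validated (present, same length as the sequence) but are
#' not used downstream; the pipeline treats reads as error-free calls of
#' the sequencer.
#'
#' @param path FASTQ file (4-line records).
#' @return `data.frame` with columns `id`, `sequence`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("%s: truncated FASTQ record near line %d", path,
                 length(lines)), call. = FALSE)
  }
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  seps <- lines[seq(3L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  if (any(!startsWith(ids, "@"))) {
    stop(sprintf("%s: malformed FASTQ header at record %d", path,
                 which(!startsWith(ids, "@"))[1]), call. = FALSE)
  }
  if (any(!startsWith(seps, "+"))) {
    stop(sprintf("%s: malformed FASTQ separator at record %d", path,
                 which(!startsWith(seps, "+"))[1]), call. = FALSE)
  }
  if (any(nchar(seqs) != nchar(quals))) {
    stop(sprintf("%s: sequence/quality length mismatch at record %d", path,
                 which(nchar(seqs) != nchar(quals))[1]), call. = FALSE)
  }
  .check_alphabet(seqs, "FASTQ sequence")
  data.frame(id = sub("^@", "", sub("\\s.*$", "", ids)),
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#' @param reads `data.frame` with `id` and `sequence` columns.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  out <- character(4L * nrow(reads))
  out[seq(1L, length(out), by = 4L)] <- paste0("@", reads$id)
  out[seq(2L, length(out), by = 4L)] <- reads$sequence
  out[seq(3L, length(out), by = 4L)] <- "+"
  out[seq(4L, length(out), by = 4L)] <-
    vapply(nchar(reads$sequence), function(n) strrep("I", n), "")
  writeLines(out, path)
  invisible(path)
}

#' Read enhancer peaks from a BED file
#'
#' BED intervals are 0-based half-open; only the first three columns are
#' used.
#'
#' @param path BED file.
#' @return `data.frame` with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("BED needs at least 3 columns: ", path,
                           call. = FALSE)
  peaks <- data.frame(chrom = as.character(tab[[1]]),
                      start = as.integer(tab[[2]]),
                      end = as.integer(tab[[3]]),
                      stringsAsFactors = FALSE)
  if (any(peaks$start < 0L)) stop("negative BED coordinates", call. = FALSE)
  if (any(peaks$start >= peaks$end)) {
    stop("BED interval with start >= end", call. = FALSE)
  }
  peaks
}

#' Write peaks to a BED file
#' @param peaks `data.frame` with `chrom`, `start`, `end`.
#' @param path output file.
#' @export
write_bed <- function(peaks, path) {
  write.table(peaks[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read insulated-neighbourhood loops from an extended BEDPE file
#'
#' Expected columns: `chrom1 start1 end1 chrom2 start2 end2 name fdr
#' ctcf1 ctcf2`, where `fdr` is the loop-call FDR and `ctcf1`/`ctcf2` are
#' 0/1 flags for a CTCF-enriched region at each anchor.  Loops spanning two
#' chromosomes, anchors that overlap each other, and negative coordinates
#' are errors.
#'
#' @param path BEDPE-like file.
#' @return `data.frame` of loops with derived columns `ctcf_both`,
#'   `span_start`, `span_end` (outer span, 0-based half-open).
#' @export
read_bedpe <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 10L) {
    stop("loop BEDPE needs 10 columns (2 anchors, name, fdr, 2 CTCF flags)",
         call. = FALSE)
  }
  loops <- data.frame(chrom = as.character(tab[[1]]),
                      a1_start = as.integer(tab[[2]]),
                      a1_end = as.integer(tab[[3]]),
                      a2_start = as.integer(tab[[5]]),
                      a2_end = as.integer(tab[[6]]),
                      name = as.character(tab[[7]]),
                      fdr = as.numeric(tab[[8]]),
                      ctcf1 = as.integer(tab[[9]]) != 0L,
                      ctcf2 = as.integer(tab[[10]]) != 0L,
                      stringsAsFactors = FALSE)
  if (any(tab[[1]] != tab[[4]])) {
    stop("loop anchors on different chromosomes", call. = FALSE)
  }
  .validate_loops(loops)
}

.validate_loops <- function(loops) {
  if (any(loops$a1_start < 0L)) stop("negative loop coordinates",
                                     call. = FALSE)
  if (any(loops$a1_start >= loops$a1_end | loops$a2_start >= loops$a2_end)) {
    stop("loop anchor with start >= end", call. = FALSE)
  }
  if (any(loops$a2_start < loops$a1_end)) {
    stop("loop anchors overlap or are out of order", call. = FALSE)
  }
  if (any(loops$fdr < 0 | loops$fdr > 1)) {
    stop("loop FDR outside [0, 1]", call. = FALSE)
  }
  loops$ctcf_both <- loops$ctcf1 & loops$ctcf2
  loops$span_start <- loops$a1_start
  loops$span_end <- loops$a2_end
  loops
}

#' Write loops to an extended BEDPE file
#' @param loops loop `data.frame` as from [read_bedpe()].
#' @param path output file.
#' @export
write_bedpe <- function(loops, path) {
  out <- data.frame(loops$chrom, loops$a1_start, loops$a1_end,
                    loops$chrom, loops$a2_start, loops$a2_end,
                    loops$name, loops$fdr,
                    as.integer(loops$ctcf1), as.integer(loops$ctcf2))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

CATALOGUE_COLUMNS <- c("key", "chrom", "position", "sequence", "samples",
                       "support", "source_read", "source_contig",
                       "in_dbsnp", "recurrent")

#' Write an insertion catalogue to TSV
#'
#' The catalogue is a TSV with a fixed header: one row per distinct variant
#' key, carrying the observing samples (comma-separated), read+contig
#' support and source/germline flags.
#'
#' @param entries catalogue `data.frame` (see [build_catalogue()]).
#' @param path output file.
#' @export
write_catalogue <- function(entries, path) {
  missing_cols <- setdiff(CATALOGUE_COLUMNS, names(entries))
  for (mc in missing_cols) {
    entries[[mc]] <- if (mc %in% c("in_dbsnp", "recurrent")) NA else
      stop("catalogue missing column: ", mc, call. = FALSE)
  }
  write.table(entries[, CATALOGUE_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an insertion catalogue from TSV
#' @param path catalogue file written by [write_catalogue()].
#' @return catalogue `data.frame`.
#' @export
read_catalogue <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(key = "character", chrom = "character",
                                   position = "integer",
                                   sequence = "character",
                                   samples = "character",
                                   support = "integer",
                                   source_read = "logical",
                                   source_contig = "logical",
                                   in_dbsnp = "logical",
                                   recurrent = "logical"))
  if (!identical(names(tab), CATALOGUE_COLUMNS)) {
    stop("unexpected catalogue header in ", path, call. = FALSE)
  }
  tab
}

#' Export a catalogue as VCF 4.2
#'
#' Insertions are written the VCF way: 1-based POS at the anchor base,
#' REF = anchor base, ALT = anchor base + inserted sequence.  Positions are
#' left-normalized already, matching VCF conventions.
#'
#' @param entries catalogue `data.frame`.
#' @param genome `enh_genome` providing anchor bases.
#' @param path output file.
#' @export
write_catalogue_vcf <- function(entries, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=enhins",
           paste0("##INFO=<ID=SUPPORT,Number=1,Type=Integer,",
                  "Description=\"Supporting reads plus contigs\">"),
           paste0("##INFO=<ID=SAMPLES,Number=1,Type=String,",
                  "Description=\"Samples carrying the insertion\">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  anchor_base <- vapply(seq_len(nrow(entries)), function(i) {
    substr(genome[[entries$chrom[i]]], entries$position[i] + 1L,
           entries$position[i] + 1L)
  }, "")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tSUPPORT=%d;SAMPLES=%s",
                  entries$chrom, entries$position + 1L, entries$key,
                  anchor_base, paste0(anchor_base, entries$sequence),
                  entries$support, entries$samples)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Export rescued alignments as SAM
#'
#' Minimal SAM 1.6 with `NM` tags; insertion-bearing CIGARs are preserved.
#'
#' @param hits list of alignment hits (see [map_gapped()]).
#' @param seqs named character vector of query sequences (plus-strand as
#'   aligned).
#' @param genome `enh_genome` used for the header.
#' @param path output file.
#' @export
write_sam <- function(hits, seqs, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  body <- vapply(hits, function(h) {
    flag <- if (identical(h$strand, "-")) 16L else 0L
    s <- seqs[[h$query_id]]
    if (identical(h$strand, "-")) s <- revcomp(s)
    sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
            h$query_id, flag, h$chrom, h$start + 1L, h$cigar, s,
            h$mismatches)
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}
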