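#' Generate a random reference genome
#'
#' Bases are drawn i.i.d. with the requested GC content; deterministic
#' given the seed.
#'
#' @param seed RNG seed.
#' @param n_chrom number of chromosomes.
#' @param lengths chromosome length(s) in bases (recycled).
#' @param gc GC fraction.
#' @return an `enh_genome` with chromosomes `chr1`, `chr2`, ...
#' @export
make_genome <- function(seed, n_chrom = 1, lengths = 100000, gc = 0.45) {
  lengths <- rep_len(as.integer(lengths), n_chrom)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- .with_seed(seed, {
    lapply(lengths, function(len) {
      paste0(sample(names(probs), len, replace = TRUE, prob = probs),
             collapse = "")
    })
  })
  names(seqs) <- sprintf("chr%d", seq_len(n_chrom))
  as_genome(unlist(seqs))
}

#' Place non-overlapping enhancer peaks on a genome
#'
#' @param genome an `enh_genome`.
#' @param n number of peaks.
#' @param width peak width in bases.
#' @param seed RNG seed.
#' @param margin bases kept free at each chromosome end.
#' @return peaks `data.frame` (`chrom`, `start`, `end`), sorted.
#' @export
make_peaks <- function(genome, n = 20, width = 500, seed = 1,
                       margin = 1000) {
  chrom <- names(genome)[1]
  clen <- nchar(genome[[chrom]])
  slots <- seq(margin, clen - margin - width, by = 2L * width)
  if (length(slots) < n) stop("genome too small for requested peaks",
                              call. = FALSE)
  starts <- .with_seed(seed, sort(sample(slots, n)))
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(starts + width), stringsAsFactors = FALSE)
}

# sample insertion sizes skewed towards 1 bp (geometric, truncated)
.sample_ins_sizes <- function(n, size_range) {
  sizes <- size_range[1]:size_range[2]
  probs <- 0.5^(sizes - size_range[1])
  sample(sizes, n, replace = TRUE, prob = probs / sum(probs))
}

#' Plant insertions inside enhancer peaks
#'
#' Each planted site receives a random inserted sequence at a random
#' position well inside a distinct peak, with heterozygous or homozygous
#' zygosity.  Haplotype pair: haplotype 1 carries every insertion,
#' haplotype 2 only the homozygous ones, so het sites are carried by one
#' haplotype of the pair.  Truth records serialize the left-normalized
#' key, zygosity, enclosing peak, and intended allele fraction.
#'
#' @param genome an `enh_genome`.
#' @param peaks non-overlapping peaks `data.frame`.
#' @param n number of insertions (at most one per peak).
#' @param size_range inclusive insertion size range in bases.
#' @param zygosities vector to sample zygosity from (default 75% het,
#'   mirroring the observed confirmed-zygosity mix).
#' @param seed RNG seed.
#' @param sizes optional explicit size vector overriding `size_range`
#'   sampling (length `n`).
#' @return list with `haplotypes` (see [apply_insertions()]) and `truth`
#'   `data.frame`: `key`, `chrom`, `position`, `sequence`, `zygosity`,
#'   `peak_start`, `peak_end`, `allele_fraction`.
#' @export
plant_insertions <- function(genome, peaks, n, size_range = c(1, 31),
                             zygosities = c("het", "het", "het", "hom"),
                             seed = 1, sizes = NULL) {
  if (n > nrow(peaks)) {
    stop("cannot place ", n, " insertions into ", nrow(peaks), " peaks",
         call. = FALSE)
  }
  truth <- .with_seed(seed, {
    pk <- peaks[sort(sample.int(nrow(peaks), n)), , drop = FALSE]
    sz <- if (is.null(sizes)) .sample_ins_sizes(n, size_range) else
      rep_len(as.integer(sizes), n)
    zy <- sample(zygosities, n, replace = TRUE)
    pad <- 60L  # keep anchors away from peak edges so reads can span
    anchor <- pk$start + pad +
      floor(runif(n) * (pk$end - pk$start - 2L * pad))
    seqs <- vapply(sz, function(s) {
      paste0(sample(c("A", "C", "G", "T"), s, replace = TRUE),
             collapse = "")
    }, "")
    data.frame(chrom = pk$chrom, position = as.integer(anchor),
               sequence = seqs, zygosity = zy,
               peak_start = pk$start, peak_end = pk$end,
               allele_fraction = ifelse(zy == "hom", 1.0, 0.5),
               stringsAsFactors = FALSE)
  })
  keys <- vapply(seq_len(nrow(truth)), function(i) {
    .normalized_key(genome, truth$chrom[i], truth$position[i],
                    truth$sequence[i])$key
  }, "")
  truth <- cbind(key = keys, truth, stringsAsFactors = FALSE)
  hap1 <- apply_insertions(genome, truth)                   # all insertions
  hap2 <- apply_insertions(genome,
                           truth[truth$zygosity == "hom", , drop = FALSE])
  list(haplotypes = list(hap1 = hap1, hap2 = hap2), truth = truth)
}

#' Splice insertions into a genome
#'
#' Builds the alternate haplotype carrying the given insertions, together
#' with the event table needed to map reference coordinates onto
#' haplotype coordinates.
#'
#' @param genome an `enh_genome`.
#' @param truth `data.frame` with `chrom`, `position`, `sequence`.
#' @return list with `genome` (the modified `enh_genome`) and `events`.
#' @export
apply_insertions <- function(genome, truth) {
  seqs <- unclass(genome)
  if (nrow(truth) > 0L) {
    for (chrom in unique(truth$chrom)) {
      ev <- truth[truth$chrom == chrom, , drop = FALSE]
      ev <- ev[order(ev$position), , drop = FALSE]
      parts <- character()
      prev <- 0L
      for (i in seq_len(nrow(ev))) {
        parts <- c(parts, .subseq0(seqs[[chrom]], prev, ev$position[i] + 1L),
                   ev$sequence[i])
        prev <- ev$position[i] + 1L
      }
      parts <- c(parts, .subseq0(seqs[[chrom]], prev, nchar(seqs[[chrom]])))
      seqs[[chrom]] <- paste0(parts, collapse = "")
    }
  }
  list(genome = as_genome(seqs), events = truth)
}

# map a reference coordinate onto haplotype coordinates
.ref2hap <- function(hap, chrom, pos) {
  ev <- hap$events
  if (nrow(ev) == 0L) return(pos)
  shift <- vapply(pos, function(p) {
    sum(nchar(ev$sequence[ev$chrom == chrom & ev$position < p]))
  }, 0)
  as.integer(pos + shift)
}

#' Simulate ChIP-seq-like reads from a haplotype pair
#'
#' Error-free fixed-length reads are drawn uniformly across each peak
#' (every peak base sees the same expected depth, split evenly between
#' the two haplotypes), plus optional genome-wide background; strands are
#' random.  Deterministic given the seed.
#'
#' @param haplotypes haplotype pair from [plant_insertions()].
#' @param peaks peaks `data.frame` in reference coordinates.
#' @param depth_in_peak total expected per-base depth inside peaks.
#' @param background_rate expected per-base depth outside peaks.
#' @param read_len read length in bases.
#' @param seed RNG seed.
#' @param error_rate optional uniform substitution error rate per base.
#' @return reads `data.frame` (`id`, `sequence`).
#' @export
simulate_chip_reads <- function(haplotypes, peaks, depth_in_peak = 30,
                                background_rate = 0, read_len = 40,
                                seed = 1, error_rate = 0) {
  .with_seed(seed, {
    out_id <- character()
    out_seq <- character()
    for (hname in names(haplotypes)) {
      hap <- haplotypes[[hname]]
      for (pi in seq_len(nrow(peaks))) {
        chrom <- peaks$chrom[pi]
        hseq <- hap$genome[[chrom]]
        hstart <- .ref2hap(hap, chrom, peaks$start[pi])
        hend <- .ref2hap(hap, chrom, peaks$end[pi])
        lo <- max(0L, hstart - read_len + 1L)
        hi <- min(nchar(hseq) - read_len, hend - 1L)
        if (hi < lo) next
        n_start_pos <- hend - hstart + read_len - 1L
        n <- round(depth_in_peak * n_start_pos / (2 * read_len))
        starts <- lo + floor(runif(n) * (hi - lo + 1L))
        seqs <- substring(hseq, starts + 1L, starts + read_len)
        flip <- runif(n) < 0.5
        seqs[flip] <- revcomp(seqs[flip])
        out_id <- c(out_id, sprintf("%s_peak%d_%d", hname, pi,
                                    seq_along(seqs)))
        out_seq <- c(out_seq, seqs)
      }
      if (background_rate > 0) {
        for (chrom in names(hap$genome)) {
          hseq <- hap$genome[[chrom]]
          n <- rpois(1, background_rate * nchar(hseq) / (2 * read_len))
          if (n == 0L) next
          starts <- floor(runif(n) * (nchar(hseq) - read_len + 1L))
          seqs <- substring(hseq, starts + 1L, starts + read_len)
          flip <- runif(n) < 0.5
          seqs[flip] <- revcomp(seqs[flip])
          out_id <- c(out_id, sprintf("%s_bg_%s_%d", hname, chrom,
                                      seq_len(n)))
          out_seq <- c(out_seq, seqs)
        }
      }
    }
    if (error_rate > 0) out_seq <- .add_errors(out_seq, error_rate)
    data.frame(id = out_id, sequence = out_seq, stringsAsFactors = FALSE)
  })
}

.add_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    hit <- runif(length(b)) < rate
    if (any(hit)) {
      b[hit] <- vapply(b[hit], function(x) {
        sample(setdiff(c("A", "C", "G", "T"), x), 1)
      }, "")
    }
    paste0(b, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate amplicon-sequencing reads for a confirmation locus
#'
#' Reads are drawn uniformly from the per-allele custom genomes in
#' proportion to zygosity (het = 50/50) and emitted as independent
#' single-end reads.
#'
#' @param genomes custom genome pair from
#'   [build_confirmation_genomes()].
#' @param zygosity `"het"`, `"hom"` (alt only) or `"ref"`.
#' @param depth expected per-base depth over the amplicon.
#' @param read_len read length in bases.
#' @param seed RNG seed.
#' @return reads `data.frame` (`id`, `sequence`).
#' @export
simulate_amplicon_reads <- function(genomes, zygosity = "het", depth = 50,
                                    read_len = 150, seed = 1) {
  stopifnot(depth >= 10)
  alleles <- switch(zygosity,
                    het = c(ref = 0.5, alt = 0.5),
                    hom = c(alt = 1.0),
                    ref = c(ref = 1.0),
                    stop("unknown zygosity: ", zygosity, call. = FALSE))
  .with_seed(seed, {
    out_id <- character()
    out_seq <- character()
    for (al in names(alleles)) {
      src <- genomes[[al]]
      if (nchar(src) < read_len) {
        stop("amplicon shorter than the read length", call. = FALSE)
      }
      n <- round(alleles[[al]] * depth * nchar(src) / read_len)
      starts <- floor(runif(n) * (nchar(src) - read_len + 1L))
      seqs <- substring(src, starts + 1L, starts + read_len)
      flip <- runif(n) < 0.5
      seqs[flip] <- revcomp(seqs[flip])
      out_id <- c(out_id, sprintf("amp_%s_%d", al, seq_len(n)))
      out_seq <- c(out_seq, seqs)
    }
    data.frame(id = out_id, sequence = out_seq, stringsAsFactors = FALSE)
  })
}

#' Generate a nested loop / gene / enhancer-union fixture
#'
#' Emits a set of insulated-neighbourhood loops (some nested), one gene
#' per loop with a configurable oncogene fraction, and an enhancer union
#' with one interval inside each outermost loop, for exercising the
#' neighbourhood-assignment and permutation machinery.
#'
#' @param seed RNG seed.
#' @param n_loops number of outer loops.
#' @param onco_fraction fraction of loops whose gene is an oncogene.
#' @param chrom_len chromosome length implied by the fixture.
#' @param nested_fraction fraction of outer loops that also get a nested
#'   inner loop.
#' @return list with `loops`, `genes`, `union_peaks`, `chrom_len`.
#' @export
simulate_loops_genes <- function(seed, n_loops = 20, onco_fraction = 0.3,
                                 chrom_len = 2000000,
                                 nested_fraction = 0.3) {
  .with_seed(seed, {
    slot <- floor(chrom_len / n_loops)
    span <- floor(slot * 0.8)
    loops <- data.frame(chrom = character(),
                        a1_start = integer(), a1_end = integer(),
                        a2_start = integer(), a2_end = integer(),
                        name = character(), fdr = numeric(),
                        ctcf1 = logical(), ctcf2 = logical(),
                        stringsAsFactors = FALSE)
    genes <- data.frame(name = character(), chrom = character(),
                        tss = integer(), strand = character(),
                        active = logical(), oncogene = logical(),
                        stringsAsFactors = FALSE)[0, ]
    union_peaks <- data.frame(chrom = character(), start = integer(),
                              end = integer(), stringsAsFactors = FALSE)[0, ]
    onco <- sample(rep_len(c(rep(TRUE, round(n_loops * onco_fraction)),
                             rep(FALSE, n_loops)), n_loops))
    for (i in seq_len(n_loops)) {
      s <- (i - 1L) * slot + 1000L
      e <- s + span
      loops <- rbind(loops, data.frame(
        chrom = "chrS", a1_start = s, a1_end = s + 500L,
        a2_start = e - 500L, a2_end = e, name = sprintf("loop%d", i),
        fdr = runif(1, 0, 0.15), ctcf1 = TRUE, ctcf2 = TRUE,
        stringsAsFactors = FALSE))
      if (runif(1) < nested_fraction) {
        ns <- s + 2000L
        ne <- s + floor(span / 2)
        loops <- rbind(loops, data.frame(
          chrom = "chrS", a1_start = ns, a1_end = ns + 300L,
          a2_start = ne - 300L, a2_end = ne,
          name = sprintf("loop%d_inner", i),
          fdr = runif(1, 0, 0.15), ctcf1 = TRUE, ctcf2 = TRUE,
          stringsAsFactors = FALSE))
      }
      genes <- rbind(genes, data.frame(
        name = sprintf("gene%d", i), chrom = "chrS",
        tss = as.integer(e - 2000L), strand = "+", active = TRUE,
        oncogene = onco[i], stringsAsFactors = FALSE))
      u0 <- s + 1000L
      union_peaks <- rbind(union_peaks, data.frame(
        chrom = "chrS", start = u0, end = u0 + 1000L,
        stringsAsFactors = FALSE))
    }
    list(loops = .validate_loops(loops), genes = genes,
         union_peaks = union_peaks, chrom_len = chrom_len)
  })
}
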