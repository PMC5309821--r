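test_that("call_peaks: null, enriched, and controlled windows", {
  g <- tiny_genome(201, len = 20000)
  withr::with_seed(12, {
    # uniform background only: no peaks
    bg <- data.frame(chrom = "chr1",
                     pos = sample(0:19959, 400, replace = TRUE),
                     stringsAsFactors = FALSE)
    expect_equal(nrow(call_peaks(bg, g)), 0L)

    # a 500-bp window at 10x the local rate
    enriched <- data.frame(chrom = "chr1",
                           pos = sample(5000:5499, 200, replace = TRUE),
                           stringsAsFactors = FALSE)
    pos <- rbind(bg, enriched)
    peaks <- call_peaks(pos, g)
    expect_equal(nrow(peaks), 1L)
    expect_true(peaks$start <= 5000 && peaks$end >= 5500)

    # closed-form Poisson cross-check: the enriched window's tail
    # probability under the genome-wide rate is below the threshold
    lambda <- nrow(pos) * 500 / 20000
    count_in <- sum(pos$pos >= 5000 & pos$pos < 5500)
    expect_lt(ppois(count_in - 1, lambda, lower.tail = FALSE), 1e-9)
    # and a 10%-enriched window would not pass
    expect_gt(ppois(ceiling(lambda * 1.1), lambda, lower.tail = FALSE),
              1e-9)

    # matched enriched control cancels the enrichment
    peaks_ctrl <- call_peaks(pos, g, control_positions = pos)
    expect_equal(nrow(peaks_ctrl), 0L)
  })
  expect_equal(nrow(call_peaks(NULL, g)), 0L)
})

test_that("extract_insertion does CIGAR arithmetic and keying", {
  g <- tiny_genome(202, len = 5000)
  qseq <- paste0(substr(g[["chr1"]], 1001, 1020), "TTG",
                 substr(g[["chr1"]], 1021, 1037))
  hit <- list(query_id = "q1", chrom = "chr1", start = 1000L,
              strand = "+", cigar = "20M3I17M", query_seq = qseq)
  call <- extract_insertion(hit, g, "s1")
  expect_equal(call$position + nchar(call$sequence) * 0, call$position)
  # anchor before normalization is 1019; the key may shift further left
  # only if the context allows rotation
  nn <- left_normalize_insertion(g[["chr1"]], 1019L, "TTG")
  expect_equal(call$position, nn$position)
  expect_equal(call$sequence, nn$sequence)

  # two I ops: no call
  hit2 <- list(query_id = "q2", chrom = "chr1", start = 1000L,
               strand = "+", cigar = "10M2I10M2I18M",
               query_seq = random_seq_fixed(42, 7))
  expect_null(extract_insertion(hit2, g, "s1"))

  # insertion at the read edge fails the flank requirement
  hit3 <- list(query_id = "q3", chrom = "chr1", start = 1000L,
               strand = "+", cigar = "2M3I35M",
               query_seq = paste0(substr(g[["chr1"]], 1001, 1002), "TTG",
                                  substr(g[["chr1"]], 1003, 1037)))
  expect_null(extract_insertion(hit3, g, "s1", min_flank = 5))
})

test_that("an insertion between known flanks is recovered verbatim", {
  # context CG[GT]TA: the inserted GT flanked by CG and TA
  chrom <- paste0(random_seq_fixed(500, 203), "ACCG", "TAGC",
                  random_seq_fixed(500, 204))
  g <- as_genome(c(chr1 = chrom))
  hap <- paste0(substr(chrom, 1, 504), "GT", substr(chrom, 505, 1008))
  withr::with_seed(13, {
    starts <- sample(440:500, 40, replace = TRUE)
    reads <- data.frame(id = sprintf("r%03d", seq_along(starts)),
                        sequence = substring(hap, starts, starts + 39),
                        stringsAsFactors = FALSE)
  })
  res <- rescue_unmapped(reads, g, sample = "MOLT4-like")
  expect_gt(nrow(res$calls), 0L)
  nn <- left_normalize_insertion(chrom, 503L, "GT")
  expect_true(all(res$calls$key ==
                    sprintf("chr1:%d:%s", nn$position, nn$sequence)))
})

test_that("rescue recovers planted insertions and rejects noise", {
  g <- tiny_genome(205, len = 50000)
  peaks <- make_peaks(g, n = 6, seed = 206)
  pl <- plant_insertions(g, peaks, 3, sizes = c(4, 8, 12),
                         zygosities = "het", seed = 207)
  reads <- simulate_chip_reads(pl$haplotypes, peaks, depth_in_peak = 40,
                               read_len = 40, seed = 208)
  aligned <- map_ungapped(reads, g)
  unmapped <- reads[aligned$status != "unique", , drop = FALSE]
  res <- rescue_unmapped(unmapped, g, sample = "s1")
  expect_setequal(unique(res$calls$key), pl$truth$key)

  # random reads with no genomic homology yield nothing
  withr::with_seed(14, {
    noise <- data.frame(id = sprintf("n%03d", 1:50),
                        sequence = vapply(1:50, function(i) random_seq(40),
                                          ""),
                        stringsAsFactors = FALSE)
  })
  res0 <- rescue_unmapped(noise, g, sample = "s1")
  expect_equal(nrow(res0$calls), 0L)
})

test_that("enhancer overlap filtering is half-open on the anchor", {
  peaks <- data.frame(chrom = "chr1", start = 100L, end = 200L,
                      stringsAsFactors = FALSE)
  calls <- data.frame(key = c("a", "b", "c"), chrom = "chr1",
                      position = c(150L, 200L, 99L), sequence = "A",
                      sample = "s", source = "read", query_id = "q",
                      hit_start = 0L, hit_cigar = "x",
                      stringsAsFactors = FALSE)
  kept <- filter_enhancer_overlap(calls, peaks)
  expect_equal(kept$key, "a")
  expect_equal(nrow(filter_enhancer_overlap(calls, peaks[0, ])), 0L)
})

test_that("build_catalogue groups by key and ignores input order", {
  mk_call <- function(key, sample, source = "read") {
    kk <- parse_key(key)
    data.frame(key = key, chrom = kk$chrom, position = kk$position,
               sequence = kk$sequence, sample = sample, source = source,
               query_id = "q", hit_start = 0L, hit_cigar = "x",
               stringsAsFactors = FALSE)
  }
  calls <- rbind(mk_call("chr1:500:AC", "s1"),
                 mk_call("chr1:500:AC", "s2", "contig"),
                 mk_call("chr1:500:AC", "s3"),
                 mk_call("chr1:500:AG", "s1"))
  cat <- build_catalogue(calls)
  expect_equal(nrow(cat), 2L)
  e <- cat[cat$key == "chr1:500:AC", ]
  expect_equal(e$samples, "s1,s2,s3")
  expect_equal(e$support, 3L)
  expect_true(e$source_read && e$source_contig)
  # same position, different sequence: separate entries
  expect_true("chr1:500:AG" %in% cat$key)
  # order invariance
  cat2 <- build_catalogue(calls[sample(nrow(calls)), ])
  expect_equal(cat2, cat)
  # empty input
  expect_equal(nrow(build_catalogue(calls[0, ])), 0L)
})

test_that("call_deletions accepts only clean M-D-M contigs", {
  g <- tiny_genome(209, len = 20000)
  chrom <- g[["chr1"]]
  # clean planted deletion
  del_contig <- paste0(substr(chrom, 2001, 2060), substr(chrom, 2073, 2130))
  dels <- call_deletions(list(list(id = "c1", sequence = del_contig)), g)
  expect_equal(nrow(dels), 1L)
  nn <- enhins:::.left_normalize_deletion(chrom, 2060L, 2072L)
  expect_equal(dels$start, nn$start)
  expect_equal(dels$end, nn$end)
  expect_equal(dels$end - dels$start, 12L)

  # contig whose best alignment carries an insertion: no deletion call
  ins_contig <- paste0(substr(chrom, 3001, 3060), "ACGTACGT",
                       substr(chrom, 3061, 3120))
  expect_equal(nrow(call_deletions(list(list(id = "c2",
                                             sequence = ins_contig)), g)),
               0L)

  # two deletions: no call
  two_d <- paste0(substr(chrom, 4001, 4050), substr(chrom, 4061, 4110),
                  substr(chrom, 4121, 4170))
  expect_equal(nrow(call_deletions(list(list(id = "c3",
                                             sequence = two_d)), g)),
               0L)
  expect_equal(nrow(call_deletions(list(), g)), 0L)
})

test_that("catalogue anchors always lie inside supplied peaks", {
  g <- tiny_genome(210, len = 50000)
  peaks <- make_peaks(g, n = 5, seed = 211)
  pl <- plant_insertions(g, peaks, 2, sizes = c(3, 6), zygosities = "het",
                         seed = 212)
  reads <- simulate_chip_reads(pl$haplotypes, peaks, depth_in_peak = 35,
                               read_len = 40, seed = 213)
  res <- call_sample(reads, g, sample = "s1", peaks = peaks)
  if (nrow(res$calls) > 0L) {
    inside <- vapply(seq_len(nrow(res$calls)), function(i) {
      any(peaks$chrom == res$calls$chrom[i] &
            peaks$start <= res$calls$position[i] &
            res$calls$position[i] < peaks$end)
    }, TRUE)
    expect_true(all(inside))
  }
  expect_setequal(unique(res$calls$key), pl$truth$key)
})
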