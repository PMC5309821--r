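genome2k <- tiny_genome(21, len = 2000)

test_that("map_ungapped places exact substrings uniquely", {
  r <- substr(genome2k[["chr1"]], 51, 90)
  hit <- map_ungapped(r, genome2k)
  expect_equal(hit$status, "unique")
  expect_equal(hit$start, 50L)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$strand, "+")
})

test_that("map_ungapped marks repeated sequences ambiguous", {
  dup <- substr(genome2k[["chr1"]], 101, 140)
  g <- as_genome(c(chr1 = paste0(genome2k[["chr1"]], random_seq(50), dup)))
  expect_equal(map_ungapped(dup, g)$status, "ambiguous")
})

test_that("map_ungapped agrees with the exhaustive scan oracle", {
  withr::with_seed(31, {
    for (i in 1:25) {
      # mix verbatim reads, mutated reads (1-4 mismatches), random reads
      mode <- sample(c("clean", "mut", "random"), 1)
      s <- sample(1:(2000 - 40), 1)
      r <- substr(genome2k[["chr1"]], s, s + 39)
      if (mode == "mut") {
        nmut <- sample(1:4, 1)
        at <- sample(1:40, nmut)
        rb <- strsplit(r, "")[[1]]
        rb[at] <- vapply(rb[at], function(x) {
          sample(setdiff(c("A", "C", "G", "T"), x), 1)
        }, "")
        r <- paste0(rb, collapse = "")
      } else if (mode == "random") {
        r <- random_seq(40)
      }
      if (sample(c(TRUE, FALSE), 1)) r <- revcomp(r)
      got <- map_ungapped(r, genome2k)
      want <- oracle_scan_ungapped(r, genome2k)
      expect_equal(got$status, want$status, info = paste("case", i, mode))
      if (want$status == "unique") {
        expect_equal(got$start, want$start)
        expect_equal(got$mismatches, want$mm)
        expect_equal(got$strand, want$strand)
      }
    }
  })
})

test_that("reads sampled verbatim map back to the sampling position", {
  withr::with_seed(77, {
    for (i in 1:30) {
      s <- sample(1:(2000 - 40), 1)
      r <- substr(genome2k[["chr1"]], s, s + 39)
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") r <- revcomp(r)
      hit <- map_ungapped(r, genome2k)
      if (hit$status == "unique") {
        expect_equal(hit$start, s - 1L)
        expect_equal(hit$mismatches, 0L)
        expect_equal(hit$strand, strand)
      } else {
        # only a genuinely repeated locus may be ambiguous
        expect_equal(oracle_scan_ungapped(r, genome2k)$status, "ambiguous")
      }
    }
  })
})

test_that("map_ungapped rejects non-alphabet characters", {
  expect_error(map_ungapped("ACGTRACGTACGTACGTACGT", genome2k), "A,C,G,T,N")
})

test_that("map_gapped recovers planted insertion blocks", {
  g <- tiny_genome(22, len = 5000)
  q <- paste0(substr(g[["chr1"]], 101, 120), "ACGT",
              substr(g[["chr1"]], 121, 140))
  h <- map_gapped(q, g)
  expect_equal(h$status, "mapped")
  expect_equal(h$start, 100L)
  expect_equal(h$cigar, "20M4I20M")
  expect_equal(h$mismatches, 0L)

  # exact reference substring: plain M CIGAR, no I
  q2 <- substr(g[["chr1"]], 301, 360)
  h2 <- map_gapped(q2, g)
  expect_equal(h2$cigar, "60M")
  expect_equal(h2$start, 300L)
})

test_that("strand closure: the reverse complement gives the mirrored hit", {
  g <- tiny_genome(23, len = 5000)
  withr::with_seed(5, {
    pq <- planted_query(g, qlen = 60, ins_len = 8, min_flank = 12)
  })
  h_fwd <- map_gapped(pq$seq, g)
  h_rev <- map_gapped(revcomp(pq$seq), g)
  expect_equal(h_fwd$strand, "+")
  expect_equal(h_rev$strand, "-")
  expect_equal(h_rev$start, h_fwd$start)
  expect_equal(h_rev$cigar, h_fwd$cigar)
  # the catalogue sequence is plus strand either way
  vf <- verify_hit(pq$seq, g, h_fwd)
  vr <- verify_hit(revcomp(revcomp(pq$seq)), g, h_rev)
  expect_equal(vf$insert, vr$insert)
  expect_equal(vf$anchor, vr$anchor)
})

test_that("map_gapped equals the exhaustive split-point oracle", {
  g <- tiny_genome(24, len = 5000)
  withr::with_seed(41, {
    for (i in 1:25) {
      qlen <- sample(50:80, 1)
      k <- sample(0:20, 1)
      pq <- if (k == 0) {
        s <- sample(1:(5000 - qlen), 1)
        list(seq = substr(g[["chr1"]], s, s + qlen - 1))
      } else {
        planted_query(g, qlen = qlen, ins_len = k, min_flank = 12)
      }
      h <- map_gapped(pq$seq, g)
      o <- oracle_split_align(pq$seq, g)
      if (identical(h$status, "mapped")) {
        expect_equal(length(o$placements), 1L)
        expect_equal(o$placements,
                     paste(h$chrom, h$start, h$strand, h$cigar))
        expect_equal(o$score, h$score)
      } else {
        expect_gt(length(o$placements), 1L)
      }
    }
  })
})

test_that("verify_hit enforces the acceptance rules", {
  g <- tiny_genome(25, len = 5000)
  mk_query <- function(ins_len, mism = FALSE) {
    left <- substr(g[["chr1"]], 1001, 1030)
    right <- substr(g[["chr1"]], 1031, 1060)
    if (mism) substr(right, 15, 15) <- chartr("ACGT", "GTAC",
                                              substr(right, 15, 15))
    list(seq = paste0(left, random_seq(ins_len), right))
  }
  withr::with_seed(6, {
    # a 21-bp insertion, otherwise perfect, fails the 20-bp cap
    q21 <- mk_query(21)
    h <- map_gapped(q21$seq, g)
    v <- verify_hit(q21$seq, g, h, max_insertion = 20)
    expect_false(v$accepted)
    expect_equal(v$reason, "too_long")
    # but passes the contig-route cap of 31
    v31 <- verify_hit(q21$seq, g, h, max_insertion = 31)
    expect_true(v31$accepted)

    # one mismatch outside the insertion: rejected
    qm <- mk_query(8, mism = TRUE)
    hm <- map_gapped(qm$seq, g)
    vm <- verify_hit(qm$seq, g, hm, max_insertion = 20)
    expect_false(vm$accepted)
    expect_equal(vm$reason, "mismatch")
  })
})

test_that("verify_hit canonicalizes insertions in repeats", {
  # genome with an AAAA run; inserting one more A anywhere is one event
  chrom <- paste0(substr(random_seq_fixed(60, 1), 1, 59), "C", "AAAA",
                  "G", random_seq_fixed(59, 2))
  g <- as_genome(c(chr1 = chrom))
  q <- paste0(substr(chrom, 31, 62), "A", substr(chrom, 63, 94))
  h <- map_gapped(q, g)
  v <- verify_hit(q, g, h)
  expect_true(v$accepted)
  key <- left_normalize_insertion(chrom, v$anchor, v$insert)
  # leftmost anchor: immediately before the A run (0-based index 59)
  expect_equal(key$position, 59L)
  expect_equal(key$sequence, "A")
})

test_that("accepted hits reconstruct the query exactly", {
  g <- tiny_genome(26, len = 5000)
  withr::with_seed(8, {
    for (i in 1:10) {
      pq <- planted_query(g, qlen = 64, ins_len = sample(1:20, 1),
                          min_flank = 8)
      h <- map_gapped(pq$seq, g)
      if (!identical(h$status, "mapped")) next
      v <- verify_hit(pq$seq, g, h)
      expect_true(v$accepted)
      rebuilt <- enhins:::.reconstruct_query(g[[v$hit$chrom]], v$hit$start,
                                             v$hit$cigar, v$aligned_seq)
      expect_equal(rebuilt, v$aligned_seq)
    }
  })
})

test_that("hits_consistent applies the 100-bp proximity rule", {
  mk <- function(start, chrom = "chr1", id = "q") {
    list(query_id = id, chrom = chrom, start = start)
  }
  expect_true(hits_consistent(mk(1000), mk(1100)))
  expect_true(hits_consistent(mk(1000), mk(1000)))
  expect_false(hits_consistent(mk(1000), mk(1101)))
  expect_false(hits_consistent(mk(1000), mk(1050, chrom = "chr2")))
  expect_error(hits_consistent(mk(1000, id = "a"), mk(1000, id = "b")),
               "different queries")
})
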