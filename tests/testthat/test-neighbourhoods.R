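mk_loop <- function(chrom, s, e, fdr = 0.1, ctcf1 = TRUE, ctcf2 = TRUE,
                    name = "l") {
  enhins:::.validate_loops(
    data.frame(chrom = chrom, a1_start = s, a1_end = s + 10L,
               a2_start = e - 10L, a2_end = e, name = name, fdr = fdr,
               ctcf1 = ctcf1, ctcf2 = ctcf2, stringsAsFactors = FALSE))
}

test_that("loop filtering requires FDR < 0.2 and CTCF at both anchors", {
  loops <- rbind(mk_loop("chr1", 0L, 1000L, fdr = 0.25),
                 mk_loop("chr1", 0L, 1000L, fdr = 0.1, ctcf2 = FALSE),
                 mk_loop("chr1", 0L, 1000L, fdr = 0.1))
  kept <- filter_loops(loops)
  expect_equal(nrow(kept), 1L)
  expect_true(all(kept$fdr < 0.2 & kept$ctcf_both))
  # boundary: fdr exactly 0.2 is dropped (strict inequality)
  expect_equal(nrow(filter_loops(mk_loop("chr1", 0L, 100L, fdr = 0.2))),
               0L)
})

test_that("nested loops resolve to the smallest containing span", {
  loops <- rbind(mk_loop("chr1", 0L, 100000L, name = "outer"),
                 mk_loop("chr1", 40000L, 60000L, name = "inner"))
  idx <- assign_smallest_loop("chr1", 50000L, loops)
  expect_equal(loops$name[idx], "inner")
  expect_true(is.na(assign_smallest_loop("chr1", 200000L, loops)))
  expect_true(is.na(assign_smallest_loop("chr2", 50000L, loops)))
})

test_that("smallest-loop choice equals brute force on 200 random configs", {
  brute <- function(chrom, pos, loops) {
    best <- NA_integer_
    for (li in seq_len(nrow(loops))) {
      if (loops$chrom[li] != chrom) next
      if (pos < loops$span_start[li] || pos >= loops$span_end[li]) next
      if (is.na(best)) { best <- li; next }
      sb <- loops$span_end[best] - loops$span_start[best]
      sl <- loops$span_end[li] - loops$span_start[li]
      if (sl < sb ||
          (sl == sb && loops$span_start[li] < loops$span_start[best])) {
        best <- li
      }
    }
    best
  }
  withr::with_seed(81, {
    for (i in 1:200) {
      n <- sample(1:8, 1)
      s <- sort(sample(0:5000, n))
      w <- sample(100:4000, n, replace = TRUE)
      loops <- do.call(rbind, lapply(seq_len(n), function(j) {
        mk_loop("chr1", s[j], s[j] + w[j] + 30L, name = sprintf("l%d", j))
      }))
      pos <- sample(0:9000, 1)
      got <- assign_smallest_loop("chr1", pos, loops)
      want <- brute("chr1", pos, loops)
      expect_identical(got, want, info = paste("config", i))
      # vectorized assignment agrees too
      expect_identical(enhins:::.assign_loops_vec("chr1", pos, loops),
                       want)
    }
  })
})

genes_fixture <- data.frame(
  name = c("ONC", "BODY", "OFF"),
  chrom = "chr1",
  tss = c(5000L, 20000L, 7000L),
  strand = "+",
  active = c(TRUE, TRUE, FALSE),
  oncogene = c(TRUE, FALSE, FALSE),
  stringsAsFactors = FALSE)

test_that("gene assignment uses active TSS within the loop span", {
  loops <- mk_loop("chr1", 1000L, 10000L)
  res <- assign_genes("k", 1L, loops, genes_fixture)
  # active oncogene TSS inside: assigned; inactive TSS inside: excluded;
  # TSS outside (gene body overlap notwithstanding): not assigned
  expect_equal(res$genes, "ONC")
  expect_true(res$contains_oncogene)
  res_na <- assign_genes("k", NA_integer_, loops, genes_fixture)
  expect_length(res_na$genes, 0L)
  expect_false(res_na$contains_oncogene)
})

test_that("promoter-window activity helper marks genes near peaks", {
  peaks <- data.frame(chrom = "chr1", start = 4500L, end = 4900L,
                      stringsAsFactors = FALSE)
  marked <- mark_active_genes(genes_fixture, peaks, window = 1000)
  expect_equal(marked$active, c(TRUE, FALSE, FALSE))
})

test_that("permutation test: degenerate null, bound, and null mean", {
  fx <- simulate_loops_genes(82, n_loops = 12, onco_fraction = 0.5)
  loops <- filter_loops(fx$loops)
  # degenerate: every neighbourhood contains an oncogene -> p = 1
  genes_all <- fx$genes
  genes_all$oncogene <- TRUE
  cat <- data.frame(chrom = "chrS",
                    position = fx$union_peaks$start[1:5] + 10L,
                    stringsAsFactors = FALSE)
  res <- oncogene_enrichment_test(cat, loops, genes_all, fx$union_peaks,
                                  n_perm = 200, seed = 1)
  expect_equal(res$p_value, 1)
  # estimator lower bound
  expect_gte(res$p_value, 1 / 201)
  # bit-reproducibility
  res2 <- oncogene_enrichment_test(cat, loops, fx$genes, fx$union_peaks,
                                   n_perm = 500, seed = 9)
  res3 <- oncogene_enrichment_test(cat, loops, fx$genes, fx$union_peaks,
                                   n_perm = 500, seed = 9)
  expect_identical(res2, res3)
  # under uniform placement the null mean matches the oncogene fraction
  # of the union (binomial oracle)
  onco <- enhins:::.onco_indicator(fx$union_peaks$chrom,
                                   fx$union_peaks$start + 500L,
                                   loops, fx$genes)
  frac <- mean(onco)  # intervals have equal width
  n_keys <- nrow(cat)
  # perm_mean averages 500 Binomial(n_keys, frac) draws
  expect_lt(abs(res2$perm_mean - n_keys * frac),
            4 * sqrt(n_keys * frac * (1 - frac) / 500) + 1e-9)
  expect_error(oncogene_enrichment_test(cat, loops, fx$genes,
                                        fx$union_peaks[0, ], 10, 1),
               "empty enhancer union")
})

test_that("planted 4:1 enrichment is detected", {
  fx <- simulate_loops_genes(83, n_loops = 20, onco_fraction = 0.3)
  loops <- filter_loops(fx$loops)
  onco <- enhins:::.onco_indicator(fx$union_peaks$chrom,
                                   fx$union_peaks$start + 500L,
                                   loops, fx$genes)
  onco_peaks <- fx$union_peaks[onco, ]
  other_peaks <- fx$union_peaks[!onco, ]
  hits <- 0L
  n_rep <- 10L
  withr::with_seed(84, {
    for (r in seq_len(n_rep)) {
      pick_onco <- runif(50) < 4 * nrow(onco_peaks) /
        (4 * nrow(onco_peaks) + nrow(other_peaks))
      draw_from <- function(pk, n) {
        iv <- sample.int(nrow(pk), n, replace = TRUE)
        pk$start[iv] + sample(0:999, n, replace = TRUE)
      }
      pos <- integer(50)
      pos[pick_onco] <- draw_from(onco_peaks, sum(pick_onco))
      pos[!pick_onco] <- draw_from(other_peaks, sum(!pick_onco))
      cat <- data.frame(chrom = "chrS", position = pos,
                        stringsAsFactors = FALSE)
      res <- oncogene_enrichment_test(cat, loops, fx$genes,
                                      fx$union_peaks, n_perm = 400,
                                      seed = 1000 + r)
      if (res$p_value < 0.05) hits <- hits + 1L
    }
  })
  expect_gte(hits, ceiling(0.95 * n_rep))
})
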