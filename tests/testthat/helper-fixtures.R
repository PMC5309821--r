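# shared fixture builders (all data generated in code, fixed seeds)

random_seq <- function(n, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(probs), n, replace = TRUE, prob = probs),
         collapse = "")
}

random_seq_fixed <- function(n, seed, gc = 0.5) {
  withr::with_seed(seed, random_seq(n, gc))
}

tiny_genome <- function(seed = 1, len = 2000, name = "chr1") {
  withr::with_seed(seed, as_genome(stats::setNames(random_seq(len), name)))
}

# reads tiling a source sequence uniformly
tile_reads <- function(src, read_len = 40, step = 2, prefix = "r") {
  starts <- seq(1, nchar(src) - read_len + 1, by = step)
  stats::setNames(substring(src, starts, starts + read_len - 1),
                  sprintf("%s%03d", prefix, seq_along(starts)))
}

# a query carrying a single planted insertion: genome substring with ins
# spliced in at a split point with both flanks of at least min_flank
planted_query <- function(genome, chrom = names(genome)[1], qlen = 60,
                          ins_len = 8, min_flank = 5) {
  clen <- nchar(genome[[chrom]])
  g0 <- sample.int(clen - qlen, 1)          # 1-based start
  core_len <- qlen - ins_len
  a <- sample(seq(min_flank, core_len - min_flank), 1)
  ins <- random_seq(ins_len)
  left <- substr(genome[[chrom]], g0, g0 + a - 1L)
  right <- substr(genome[[chrom]], g0 + a, g0 + core_len - 1L)
  list(seq = paste0(left, ins, right), start = g0 - 1L, a = a,
       ins = ins, chrom = chrom)
}
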