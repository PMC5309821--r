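# Independent oracles.  These deliberately share no search code with the
# package: the gapless oracle scans every offset, the gapped oracle
# enumerates every (offset, left-length, gap-length) decomposition with
# explicit mismatch counting, and normalization is re-derived from first
# principles (rotate the gap left across equal characters).

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# brute-force gapless scan: every offset, both strands, full-length
oracle_scan_ungapped <- function(read, genome, max_mm = 2) {
  hits <- data.frame(chrom = character(), start = integer(),
                     strand = character(), mm = integer(),
                     stringsAsFactors = FALSE)
  L <- nchar(read)
  for (strand in c("+", "-")) {
    q <- if (strand == "-") oracle_revcomp(read) else read
    qb <- strsplit(q, "")[[1]]
    for (chrom in names(genome)) {
      gb <- strsplit(genome[[chrom]], "")[[1]]
      if (length(gb) < L) next
      for (g in 0:(length(gb) - L)) {
        mm <- sum(qb != gb[(g + 1):(g + L)] | qb == "N")
        if (mm <= max_mm) {
          hits <- rbind(hits, data.frame(chrom = chrom, start = g,
                                         strand = strand, mm = mm,
                                         stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (nrow(hits) == 0L) return(list(status = "no_hit"))
  best <- hits[hits$mm == min(hits$mm), , drop = FALSE]
  if (nrow(best) > 1L) return(list(status = "ambiguous", n = nrow(best)))
  list(status = "unique", chrom = best$chrom, start = best$start,
       strand = best$strand, mm = best$mm)
}

# independent leftmost rotation of a single-insertion decomposition
oracle_normalize <- function(q, a, k) {
  qb <- strsplit(q, "")[[1]]
  while (a > 0L && qb[a] == qb[a + k]) a <- a - 1L
  a
}

# independent leftmost rotation of a single-deletion decomposition
oracle_normalize_del <- function(gb, g, a, d) {
  while (a > 1L && gb[g + a] == gb[g + a + d]) a <- a - 1L
  a
}

# exhaustive split-point aligner: for every genome offset, strand, and
# decomposition into (left-length a, gap-length) pieces - gapless, a
# single insertion of length k, or a single deletion of length d - score
# the gapless pieces with match +1 / mismatch -1 and the gap with
# -(len + 1).  Returns the best score and the set of distinct canonical
# placements achieving it.
oracle_split_align <- function(seq, genome, max_k = 31, max_d = 50) {
  L <- nchar(seq)
  best_score <- -Inf
  placements <- list()
  note <- function(chrom, g, strand, cig) {
    placements[[paste(chrom, g, strand, cig)]] <<- TRUE
  }
  for (strand in c("+", "-")) {
    q <- if (strand == "-") oracle_revcomp(seq) else seq
    qb <- strsplit(q, "")[[1]]
    for (chrom in names(genome)) {
      gb <- strsplit(genome[[chrom]], "")[[1]]
      G <- length(gb)
      if (G < L) next
      gvals <- 0:(G - L)
      nG <- length(gvals)
      # MMpref[a + 1, ]: mismatches of q[1..a] at 0-based offset g
      MMpref <- matrix(0L, L + 1L, nG)
      for (a in seq_len(L)) {
        MMpref[a + 1L, ] <- MMpref[a, ] +
          as.integer(qb[a] != gb[gvals + a] | qb[a] == "N")
      }
      # MMsuf[b + 1, e]: mismatches of the length-b suffix of q ending at
      # 1-based genome index e
      MMsuf <- matrix(NA_integer_, L + 1L, G)
      MMsuf[1L, ] <- 0L
      for (b in seq_len(L)) {
        idx <- b:G
        MMsuf[b + 1L, idx] <- MMsuf[b, idx] +
          as.integer(qb[L - b + 1L] != gb[idx - b + 1L] |
                       qb[L - b + 1L] == "N")
      }
      for (k in 0:min(max_k, L - 1L)) {
        span <- L - k
        gap_pen <- if (k == 0L) 0L else k + 1L
        if (span - gap_pen < best_score) break  # even perfect cannot tie
        ends <- gvals + span                    # 1-based right-segment end
        # S[a + 1, j]: total mismatches of decomposition (g = gvals[j], a)
        S <- MMpref[1:(span + 1L), , drop = FALSE] +
          MMsuf[(span + 1L):1L, ends, drop = FALSE]
        mn <- min(S)
        sc <- span - 2L * mn - gap_pen
        if (sc < best_score) next
        if (sc > best_score) {
          best_score <- sc
          placements <- list()
        }
        w <- which(S == mn, arr.ind = TRUE)
        for (r in seq_len(nrow(w))) {
          a <- w[r, 1L] - 1L
          g <- gvals[w[r, 2L]]
          a_can <- if (k > 0L) oracle_normalize(q, a, k) else a
          cig <- if (k == 0L) sprintf("%dM", L) else
            paste0(if (a_can > 0L) sprintf("%dM", a_can) else "",
                   sprintf("%dI", k),
                   if (span - a_can > 0L) sprintf("%dM", span - a_can)
                   else "")
          note(chrom, g, strand, cig)
        }
      }
      for (d in seq_len(max_d)) {
        gap_pen <- d + 1L
        if (L - gap_pen < best_score) break
        ends <- gvals + L + d
        valid <- which(ends <= G)
        if (length(valid) == 0L) break
        S <- MMpref[2:L, valid, drop = FALSE] +
          MMsuf[L:2L, ends[valid], drop = FALSE]
        mn <- min(S)
        sc <- L - 2L * mn - gap_pen
        if (sc < best_score) next
        if (sc > best_score) {
          best_score <- sc
          placements <- list()
        }
        w <- which(S == mn, arr.ind = TRUE)
        for (r in seq_len(nrow(w))) {
          a <- w[r, 1L]                      # rows are a = 1..L-1
          g <- gvals[valid[w[r, 2L]]]
          a_can <- oracle_normalize_del(gb, g, a, d)
          cig <- sprintf("%dM%dD%dM", a_can, d, L - a_can)
          note(chrom, g, strand, cig)
        }
      }
    }
  }
  list(score = best_score, placements = sort(names(placements)))
}
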