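# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (character loops, exhaustive scans, dynamic
# programming) so they share no code path with the implementation.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

# GC fraction by explicit character counting.
oracle_gc <- function(seq) {
  x <- strsplit(seq, "")[[1]]
  sum(x == "G" | x == "C") / length(x)
}

# Longest mono-/dinucleotide tandem run by exhaustive substring scan.
oracle_max_run <- function(seq) {
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  best <- 1L
  for (i in seq_len(n)) {
    # period 1
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    best <- max(best, j - i + 1L)
    # period 2, distinct letters
    if (i + 1L <= n && x[i] != x[i + 1L]) {
      j <- i + 1L
      while (j < n && x[j + 1L] == x[j - 1L]) j <- j + 1L
      best <- max(best, j - i + 1L)
    }
  }
  best
}

# Longest substring whose reverse complement occurs in the sequence:
# dynamic-programming longest common substring of seq and revcomp(seq).
oracle_selfcomp <- function(seq) {
  a <- strsplit(seq, "")[[1]]
  b <- strsplit(oracle_revcomp(seq), "")[[1]]
  n <- length(a)
  best <- 0L
  prev <- integer(n)
  for (i in seq_len(n)) {
    cur <- integer(n)
    for (j in seq_len(n)) {
      if (a[i] == b[j]) {
        cur[j] <- if (j == 1L) 1L else prev[j - 1L] + 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

# All-offsets, both-strands sliding-window scorer: matrix of genome
# characters vs probe characters, thresholded, then greedy merging of
# near-duplicate windows (same rules as the matcher contract, coded
# independently).
oracle_find_hits <- function(probe, contig, min_matches = 47L,
                             both_strands = TRUE) {
  plen <- nchar(probe)
  g <- strsplit(contig, "")[[1]]
  n_off <- length(g) - plen + 1L
  score_strand <- function(q) {
    p <- strsplit(q, "")[[1]]
    idx <- outer(0:(plen - 1L), seq_len(n_off), "+")
    counts <- colSums(matrix(g[idx], nrow = plen) == p)
    counts
  }
  strands <- c("+", if (both_strands) "-")
  rows <- NULL
  for (s in strands) {
    q <- if (s == "+") probe else oracle_revcomp(probe)
    counts <- score_strand(q)
    pos <- which(counts >= min_matches)
    if (!length(pos)) next
    # greedy cluster: windows within plen-1 of the previous kept start
    # form one locus; keep the best count (leftmost on ties)
    kept <- NULL
    cluster <- c(pos[1])
    flush <- function(cl) cl[which.max(counts[cl])]
    if (length(pos) > 1L) {
      for (k in 2:length(pos)) {
        if (pos[k] - cluster[length(cluster)] > plen - 1L) {
          kept <- c(kept, flush(cluster))
          cluster <- pos[k]
        } else cluster <- c(cluster, pos[k])
      }
    }
    kept <- c(kept, flush(cluster))
    rows <- rbind(rows, data.frame(position = kept, strand = s,
                                   matches = counts[kept],
                                   stringsAsFactors = FALSE))
  }
  if (is.null(rows)) {
    return(data.frame(position = integer(), strand = character(),
                      matches = integer(), stringsAsFactors = FALSE))
  }
  rows[order(rows$position, rows$strand), , drop = FALSE]
}

# Welch two-sample t-test from the textbook formulae.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Hypergeometric upper tail by explicit enumeration over the support.
oracle_fisher <- function(a, b, c_, d) {
  white <- a + c_; black <- b + d; draws <- a + b
  ks <- max(0, draws - black):min(draws, white)
  probs <- choose(white, ks) * choose(black, draws - ks) /
    choose(white + black, draws)
  sum(probs[ks >= a])
}

# A 60-mer with exact GC count gc60/60 that passes the repeat and
# self-complementarity filters (rejection sampling under the caller's
# seed).
seq_with_gc <- function(gc60) {
  stopifnot(gc60 >= 0, gc60 <= 60)
  bases <- c(rep(c("G", "C"), length.out = gc60),
             rep(c("A", "T"), length.out = 60 - gc60))
  repeat {
    s <- paste(sample(bases), collapse = "")
    if (max_repeat_run(s) <= 5L && self_complementarity(s) <= 15L) {
      return(s)
    }
  }
}

# Plant `probe` (or sequences) into random genome background at given
# 1-based positions.
plant_in_genome <- function(inserts, positions, total_len) {
  g <- strsplit(rand_dna(total_len), "")[[1]]
  for (k in seq_along(inserts)) {
    ins <- strsplit(inserts[k], "")[[1]]
    g[positions[k]:(positions[k] + length(ins) - 1L)] <- ins
  }
  paste(g, collapse = "")
}

# Substitute bases at `at` positions, always to a different letter.
substitute_at <- function(seq, at) {
  x <- strsplit(seq, "")[[1]]
  for (i in at) x[i] <- setdiff(c("A", "C", "G", "T"), x[i])[1]
  paste(x, collapse = "")
}
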