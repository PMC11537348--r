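# Independent brute-force oracles used to pin expected values. These share
# no code with the implementation: reverse complements via chartr, substring
# presence via direct scans over each strand string.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Matching statistics by suffix scan: for each position, test suffix lengths
# 1, 2, ... by direct substring search over every strand, keeping the longest
# present (presence is monotone in length, so the first absent length stops
# the scan).
oracle_ms <- function(read, refs) {
  strands <- gsub("N", "n", c(refs, oracle_revcomp(refs)), fixed = TRUE)
  L <- nchar(read)
  vals <- integer(L)
  for (i in seq_len(L)) {
    best <- 0L
    for (len in seq_len(i)) {
      pat <- substr(read, i - len + 1L, i)
      if (any(grepl(pat, strands, fixed = TRUE))) best <- len else break
    }
    vals[i] <- best
  }
  vals
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Per-position counting oracle for coverage depth/breadth.
oracle_coverage <- function(starts, ends, genome_length) {
  counts <- integer(genome_length)
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1L):ends[i]
    counts[idx] <- counts[idx] + 1L
  }
  list(mean_depth = sum(counts) / genome_length,
       breadth = mean(counts >= 1))
}

# Exact two-sided signed-rank P-value by enumeration of all 2^n sign
# assignments on the observed (mid)ranks.
oracle_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  t_all <- as.vector(signs %*% r)
  min(1, mean(t_all <= w_obs) + mean(t_all >= sum(r) - w_obs))
}

# Brute-force run segmenter: walk the distribution, cutting wherever the
# value fails to be previous + 1; report each segment's peak when positive.
oracle_runs <- function(values) {
  peaks <- integer()
  seg_peak <- NA_integer_
  for (i in seq_along(values)) {
    if (i == 1 || values[i] != values[i - 1] + 1) {
      if (!is.na(seg_peak) && seg_peak > 0) peaks <- c(peaks, seg_peak)
      seg_peak <- values[i]
    } else {
      seg_peak <- max(seg_peak, values[i])
    }
  }
  if (!is.na(seg_peak) && seg_peak > 0) peaks <- c(peaks, seg_peak)
  peaks
}
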