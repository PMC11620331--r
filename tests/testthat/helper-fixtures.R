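# shared builders and independent oracles for the test suite

small_genome <- function(len = 200000L, spike_len = NULL) {
  genome_spec(c(chr1 = len),
              spikein = if (is.null(spike_len)) NULL else c(spike1 = spike_len))
}

# track with explicit per-base vectors on one chromosome
vec_track <- function(plus, minus = NULL, total_reads = NULL, ...) {
  minus <- if (is.null(minus)) numeric(length(plus)) else minus
  if (is.null(total_reads)) total_reads <- sum(plus) + sum(minus)
  gs <- small_genome(length(plus))
  stranded_track(gs, plus = list(chr1 = plus), minus = list(chr1 = minus),
                 total_reads = total_reads, ...)
}

# rectangular block of signal: height h over [from, to) on the given strand
rect_track <- function(len, from, to, h, strand = "+", total_reads = 1e6) {
  v <- numeric(len)
  v[(from + 1):to] <- h
  if (strand == "+") vec_track(v, numeric(len), total_reads = total_reads)
  else vec_track(numeric(len), v, total_reads = total_reads)
}

# --- independent brute-force oracles ------------------------------------

# sliding-window resection decision, re-derived with plain nested loops
bf_sliding <- function(bins, B, bin, win_bins, trigger_below) {
  n <- length(bins)
  for (w in seq_len(max(0, n - win_bins + 1L))) {
    n_below <- 0L
    for (k in w:(w + win_bins - 1L)) if (bins[k] < B) n_below <- n_below + 1L
    if (n_below > trigger_below) {
      endpoint <- 0L
      for (k in w:(w + win_bins - 1L)) if (bins[k] > B) endpoint <- k
      if (endpoint == 0L) {
        for (k in seq_len(w - 1L)) if (bins[k] > B) endpoint <- k
      }
      return(list(length = endpoint * bin, at_limit = FALSE))
    }
  }
  list(length = n * bin, at_limit = TRUE)
}

# microhomology by exhaustive scan over all candidate lengths
bf_microhomology <- function(ref, s, e) {
  L <- nchar(ref)
  best <- 0L
  for (m in seq_len(L - e)) {
    if (substr(ref, s + 1, s + m) == substr(ref, e + 1, e + m)) best <- m
    else break
  }
  best
}

# all single deletions of ref that reproduce the read; returns start offsets
bf_deletions_matching <- function(read, ref) {
  d <- nchar(ref) - nchar(read)
  if (d <= 0) return(integer(0))
  hits <- integer(0)
  for (s in 0:(nchar(ref) - d)) {
    cand <- paste0(substr(ref, 1, s), substr(ref, s + d + 1, nchar(ref)))
    if (cand == read) hits <- c(hits, s)
  }
  hits
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
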