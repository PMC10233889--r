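# Independent oracles, deliberately naive.

# exhaustive hypergeometric upper tail: enumerate every size-n draw from a
# universe 1..N whose first K elements are the reference set
enum_hyper_upper <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# O(n * m) brute-force window count and nearest distance around point TSSs
# (0-based half-open intervals, window [tss - d, tss + d))
brute_window_count <- function(tss_chrom, tss_pos, sites, d) {
  counts <- integer(length(tss_pos))
  nearest <- rep(NA_real_, length(tss_pos))
  for (i in seq_along(tss_pos)) {
    on_chrom <- sites[sites$chrom == tss_chrom[i], , drop = FALSE]
    if (!nrow(on_chrom)) next
    lo <- tss_pos[i] - d
    hi <- tss_pos[i] + d
    counts[i] <- sum(on_chrom$start < hi & on_chrom$end > lo)
    # gap = number of bases strictly between the TSS base and the interval
    # (0 when the interval covers or directly abuts the TSS)
    gaps <- pmax(0, pmax(on_chrom$start - tss_pos[i] - 1L,
                         tss_pos[i] - on_chrom$end))
    nearest[i] <- min(gaps)
  }
  data.frame(count = counts, nearest = nearest)
}

# textbook two-sample and paired t tests via stats::t.test, row by row
tt_oracle_unpaired <- function(y1, y2) {
  t(vapply(seq_len(nrow(y1)), function(i) {
    ht <- stats::t.test(y1[i, ], y2[i, ], var.equal = TRUE)
    c(t = unname(ht$statistic), p = ht$p.value)
  }, c(t = 0, p = 0)))
}
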