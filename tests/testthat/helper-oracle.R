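# Independent brute-force digestion oracle: enumerate all substrings and
# keep those whose ends are valid cleavage boundaries and whose number of
# internal cleavage sites does not exceed the missed-cleavage allowance.
# Deliberately a different algorithm from the package's
# fragment-concatenation implementation.
oracle_digest <- function(sequence, rule = "trypsin", m = 0L,
                          min_len = 6L, max_len = Inf) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  is_site <- logical(n)
  for (i in seq_len(max(0L, n - 1L))) {
    is_site[i] <- ch[i] %in% c("K", "R") &&
      (rule == "trypsin_p" || ch[i + 1] != "P")
  }
  cum <- c(0L, cumsum(is_site))
  peptide <- character(0)
  start <- integer(0)
  for (s in seq_len(n)) {
    if (s > 1L && !is_site[s - 1L]) next
    for (e in s:n) {
      if (e < n && !is_site[e]) next
      if (cum[e] - cum[s] > m) next
      len <- e - s + 1L
      if (len >= min_len && len <= max_len) {
        peptide <- c(peptide, substr(sequence, s, e))
        start <- c(start, s - 1L)
      }
    }
  }
  out <- data.frame(peptide = peptide, start = start,
                    stringsAsFactors = FALSE)
  out[order(out$start, nchar(out$peptide)), , drop = FALSE]
}

# Random protein-like sequence with K/R enriched so cleavage sites occur.
random_seq <- function(len, p_kr = 0.12) {
  other <- setdiff(c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
                     "N", "P", "Q", "S", "T", "V", "W", "Y"), character(0))
  probs <- c(rep((1 - p_kr) / length(other), length(other)), p_kr / 2, p_kr / 2)
  paste(sample(c(other, "K", "R"), len, replace = TRUE, prob = probs),
        collapse = "")
}

random_records <- function(n, len_range = c(30, 80), prefix = "P") {
  protein_records(
    sprintf("%s%04d", prefix, seq_len(n)),
    vapply(sample(len_range[1]:len_range[2], n, replace = TRUE),
           random_seq, character(1)),
    section = "reviewed"
  )
}

expect_same_digest <- function(got, want) {
  expect_equal(got$peptide, want$peptide, ignore_attr = TRUE)
  expect_equal(got$start, want$start, ignore_attr = TRUE)
}
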