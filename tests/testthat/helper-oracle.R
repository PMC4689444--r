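# Brute-force SSR scanner used as the independent oracle: per-start,
# per-period substring comparison, no shared code with the package's
# run-length implementation.

oracle_reducible <- function(m) {
  n <- nchar(m)
  for (d in seq_len(n - 1)) {
    if (n %% d == 0 && strrep(substr(m, 1, d), n / d) == m) return(TRUE)
  }
  FALSE
}

# Returns a data.frame of loci (start 0-based, end half-open, period,
# motif, copies) for one sequence under the given copy windows.
oracle_ssrs <- function(seq, windows = gssr::ssr_copy_windows()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- list()
  for (k in seq_len(nrow(windows))) {
    p <- windows$period[k]
    for (i in seq_len(n - p + 1)) {
      motif <- substr(seq, i, i + p - 1)
      if (grepl("[^ACGT]", motif) || oracle_reducible(motif)) next
      # base-level left maximality: the repeat run must not extend left
      if (i > 1 && substr(seq, i - 1, i - 1) ==
            substr(seq, i + p - 1, i + p - 1)) next
      copies <- 1
      while (substr(seq, i + copies * p, i + (copies + 1) * p - 1) == motif) {
        copies <- copies + 1
      }
      if (copies >= windows$min_copies[k] && copies <= windows$max_copies[k]) {
        out[[length(out) + 1]] <- data.frame(
          start = i - 1L, end = i - 1L + p * copies, period = p,
          motif = motif, copies = copies)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      period = integer(), motif = character(),
                      copies = integer()))
  }
  do.call(rbind, out)
}
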