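# Low-complexity (dust) masking. Windows are scored by the classic triplet
# statistic: with c_t the count of triplet t among the window's overlapping
# triplets, S = sum c_t (c_t - 1) / 2 divided by the number of triplet
# positions. A self-repetitive window concentrates its triplet counts and
# scores high; a maximally diverse window scores 0.

# Logical mask (TRUE = masked) for one sequence. Every 64-base window
# (shorter sequences are one full-length window) whose score exceeds the
# threshold is masked whole.
dust_mask_vec <- function(seq, level = 1, window = 64L) {
  n <- nchar(seq)
  mask <- logical(n)
  if (n < 3) return(mask)
  thr <- dust_threshold(level)
  codes <- kmer_codes(dna_to_int(toupper(seq)), 3L)
  codes_i <- ifelse(is.na(codes), -1L, as.integer(codes))
  w <- min(window, n)
  nt <- w - 2L              # triplet positions per window
  counts <- integer(64)
  pairs <- 0
  for (j in seq_len(nt)) {
    t <- codes_i[j]
    if (t >= 0) { pairs <- pairs + counts[t + 1L]; counts[t + 1L] <- counts[t + 1L] + 1L }
  }
  if (pairs / nt > thr) mask[1:w] <- TRUE
  if (n > w) {
    for (i in 2:(n - w + 1L)) {
      drop <- codes_i[i - 1L]
      if (drop >= 0) { counts[drop + 1L] <- counts[drop + 1L] - 1L; pairs <- pairs - counts[drop + 1L] }
      add <- codes_i[i + nt - 1L]
      if (add >= 0) { pairs <- pairs + counts[add + 1L]; counts[add + 1L] <- counts[add + 1L] + 1L }
      if (pairs / nt > thr) mask[i:(i + w - 1L)] <- TRUE
    }
  }
  mask
}

dust_threshold <- function(level) 2 * level

#' Mask low-complexity regions of sequences
#'
#' Sliding 64-base windows are scored by the triplet-frequency statistic
#' and masked (lower-cased) when the score exceeds `2 * level`. Primer
#' candidates are not allowed to overlap masked bases; products may span
#' them.
#'
#' @param seqs Character vector of DNA sequences.
#' @param level Stringency multiplier; the score threshold is `2 * level`
#'   (default level 1).
#' @return Sequences with masked regions in lower case.
#' @export
#' @examples
#' dust_mask(strrep("AT", 32))
dust_mask <- function(seqs, level = 1) {
  vapply(seqs, function(s) {
    m <- dust_mask_vec(s, level)
    if (!any(m)) return(s)
    ch <- strsplit(s, "")[[1]]
    ch[m] <- tolower(ch[m])
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
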