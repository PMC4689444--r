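# Low-level sequence helpers shared across modules. Sequences are plain
# uppercase character vectors over {A,C,G,T,N}; Biostrings containers are
# used at the I/O boundary and for translation.

DNA_BASES <- c("A", "C", "G", "T")

.datatable.aware <- TRUE

#' Reverse complement of DNA strings
#'
#' Vectorised over a character vector; `N` complements to `N`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AANG"))
revcomp <- function(x) {
  stringr::str_to_upper(x) |>
    chartr(old = "ACGTN", new = "TGCAN") |>
    stringi::stri_reverse()
}

random_dna <- function(n_bases, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n_bases, replace = TRUE, prob = p), collapse = "")
}

# Integer encoding A=0 C=1 G=2 T=3, anything else NA.
dna_to_int <- function(seq) {
  code <- integer(256)
  code[] <- NA_integer_
  code[utf8ToInt("A") + 1L] <- 0L
  code[utf8ToInt("C") + 1L] <- 1L
  code[utf8ToInt("G") + 1L] <- 2L
  code[utf8ToInt("T") + 1L] <- 3L
  code[utf8ToInt(seq) + 1L]
}

# Rolling k-mer codes (base-4) for one integer-encoded sequence; positions
# whose window contains an ambiguous base get NA. Returns numeric vector of
# length len - k + 1 (codes fit in doubles exactly for k <= 26).
kmer_codes <- function(ints, k) {
  n <- length(ints)
  if (n < k) return(numeric(0))
  x <- as.numeric(ints)
  isna <- is.na(x)
  x[isna] <- 0
  # code[i] = sum_j x[i+j-1] * 4^(k-j)
  code <- numeric(n - k + 1)
  for (j in seq_len(k)) {
    code <- code + x[j:(n - k + j)] * 4^(k - j)
  }
  cs <- c(0, cumsum(isna))
  bad <- (cs[(k + 1):(n + 1)] - cs[seq_len(n - k + 1)]) > 0
  code[bad] <- NA_real_
  code
}

phred_to_string <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

string_to_phred <- function(s) {
  lapply(s, function(v) utf8ToInt(v) - 33L)
}

# Largest-remainder rounding of percentages to integers summing to 100.
round_percent <- function(p) {
  if (length(p) == 0) return(integer(0))
  stopifnot(abs(sum(p) - 100) < 1e-6)
  fl <- floor(p)
  rem <- p - fl
  need <- 100L - as.integer(round(sum(fl)))
  if (need > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(need)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}
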