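# Shared fixture builders; everything is generated in code at test time.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rand_protein <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

# A fragment with one SSR and clean random flanks. Flanks are rejected and
# redrawn if they accidentally extend the repeat run at the junction.
ssr_fragment <- function(motif, copies, flank = 20, gc = 0.5) {
  repeat {
    left <- rand_dna(flank, gc)
    right <- rand_dna(flank, gc)
    frag <- paste0(left, strrep(motif, copies), right)
    p <- nchar(motif)
    if (substr(frag, flank, flank) != substr(frag, flank + p, flank + p) &&
        substr(frag, flank + copies * p + 1, flank + copies * p + 1) !=
          substr(frag, flank + (copies - 1) * p + 1,
                 flank + (copies - 1) * p + 1)) {
      return(frag)
    }
  }
}

# Error-free read pair from a known fragment (both mates full-length
# subreads, Sanger Q38).
pair_from_fragment <- function(frag, read_length = 101, id = "p1") {
  q <- strrep(rawToChar(as.raw(38 + 33)), min(read_length, nchar(frag)))
  tibble::tibble(
    id = id,
    seq1 = substr(frag, 1, read_length),
    qual1 = q,
    seq2 = substr(gssr::revcomp(frag), 1, read_length),
    qual2 = q)
}
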