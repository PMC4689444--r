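# Paired-end read simulator. Fragments are drawn with truncated-normal
# lengths from a genome; mate 1 reads the fragment's 5' end, mate 2 the
# reverse complement of its 3' end. Fragments shorter than the read length
# run through into sequencing adapter on both mates. A configurable
# fraction of pairs is built as orientation artifacts whose two mates share
# an identical last-30-base tail, emulating the short-insert/ligation
# anomalies seen in real short-insert libraries.

#' Default simulated adapter
#'
#' A fixed synthetic 33-base adapter used for read-through simulation and
#' trimming; not a vendor sequence.
#' @export
default_adapter <- function() "ACGGCTAGCTTGCAGTACGAGTCCATGGACTAC"

#' Specify a read simulation
#'
#' @param read_length Read length in bases (default 101).
#' @param fragment_mean,fragment_sd Mean and standard deviation of the
#'   fragment length distribution (defaults 180 and 25); lengths are drawn
#'   from a normal truncated to `[read_length - 30, 2 * read_length]`, so
#'   both merging and non-merging pairs occur and adapter read-through
#'   never exceeds the adapter length.
#' @param n_pairs Number of read pairs.
#' @param adapter_seq Adapter sequence appended on read-through.
#' @param artifact_pair_rate Fraction of pairs built as same-tail
#'   orientation artifacts (default 0).
#' @param error_rate Per-base substitution probability (default 0).
#' @param low_qual_tail_rate Fraction of mates given a low-quality (Q2)
#'   tail of 5-20 bases so the quality trimmer is exercised (default 0).
#' @param seed Integer seed.
#' @return A `read_sim_spec` list.
#' @export
read_sim_spec <- function(n_pairs, read_length = 101L, fragment_mean = 180,
                          fragment_sd = 25, adapter_seq = default_adapter(),
                          artifact_pair_rate = 0, error_rate = 0,
                          low_qual_tail_rate = 0, seed = 1L) {
  if (n_pairs <= 0) abort("n_pairs must be positive")
  stopifnot(read_length > 0, fragment_mean > 0, fragment_sd >= 0,
            artifact_pair_rate >= 0, artifact_pair_rate <= 1,
            error_rate >= 0, error_rate <= 1,
            low_qual_tail_rate >= 0, low_qual_tail_rate <= 1)
  if (nchar(adapter_seq) < 30) {
    abort("adapter_seq must be at least 30 bases for read-through geometry")
  }
  structure(
    list(n_pairs = as.integer(n_pairs), read_length = as.integer(read_length),
         fragment_mean = fragment_mean, fragment_sd = fragment_sd,
         adapter_seq = toupper(adapter_seq),
         artifact_pair_rate = artifact_pair_rate, error_rate = error_rate,
         low_qual_tail_rate = low_qual_tail_rate, seed = as.integer(seed)),
    class = "read_sim_spec")
}

substitute_errors <- function(seqs, rate) {
  if (rate <= 0) return(list(seqs = seqs, n_err = integer(length(seqs))))
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    pos <- sample.int(lens[i], n_err[i])
    ch <- strsplit(seqs[i], "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) {
      sample(setdiff(DNA_BASES, b), 1)
    }, character(1))
    seqs[i] <- paste(ch, collapse = "")
  }
  list(seqs = seqs, n_err = n_err)
}

#' Simulate paired-end reads from a genome
#'
#' @param genome A DNA string (e.g. `make_genome()$sequence`).
#' @param spec A [read_sim_spec()].
#' @return Read-pair tibble (`id`, `seq1`, `qual1`, `seq2`, `qual2`) with a
#'   ground-truth tibble in `attr(, "truth")` recording each pair's
#'   fragment start (0-based), fragment length, artifact status and drawn
#'   error counts. Deterministic for a fixed `spec$seed`.
#' @export
simulate_reads <- function(genome, spec) {
  stopifnot(inherits(spec, "read_sim_spec"))
  glen <- nchar(genome)
  if (glen < spec$fragment_mean) {
    abort("genome shorter than fragment_mean")
  }
  rl <- spec$read_length
  lo <- max(rl - 30L, 1L)
  hi <- 2L * rl
  withr::with_seed(spec$seed, {
    n <- spec$n_pairs
    u <- runif(n, pnorm(lo - 0.5, spec$fragment_mean, spec$fragment_sd),
               pnorm(hi + 0.5, spec$fragment_mean, spec$fragment_sd))
    flen <- pmin(pmax(round(qnorm(u, spec$fragment_mean, spec$fragment_sd)),
                      lo), hi)
    flen <- pmin(flen, glen)
    start <- vapply(glen - flen, function(m) sample.int(m + 1L, 1L) - 1L,
                    integer(1))
    frag <- substring(genome, start + 1L, start + flen)
    thru <- pmax(rl - flen, 0L)
    adapter_part <- substring(spec$adapter_seq, 1L, thru)
    mate1 <- ifelse(thru > 0, paste0(frag, adapter_part),
                    substr(frag, 1L, rl))
    rcf <- revcomp(frag)
    mate2 <- ifelse(thru > 0, paste0(rcf, adapter_part),
                    substr(rcf, 1L, rl))
    e1 <- substitute_errors(mate1, spec$error_rate)
    e2 <- substitute_errors(mate2, spec$error_rate)
    mate1 <- e1$seqs; mate2 <- e2$seqs
    is_artifact <- runif(n) < spec$artifact_pair_rate
    if (any(is_artifact)) {
      ia <- which(is_artifact)
      tail1 <- substr(mate1[ia], rl - 29L, rl)
      mate2[ia] <- paste0(substr(mate2[ia], 1L, rl - 30L), tail1)
    }
    qual <- function(m) {
      q <- strrep(rawToChar(as.raw(38L + 33L)), rl)
      low <- runif(n) < spec$low_qual_tail_rate
      if (any(low)) {
        tl <- sample(5:20, n, replace = TRUE)
        qlow <- rawToChar(as.raw(2L + 33L))
        q <- ifelse(low,
                    paste0(strrep(rawToChar(as.raw(38L + 33L)), rl - tl),
                           strrep(qlow, tl)),
                    q)
      }
      q
    }
    qual1 <- qual(mate1)
    qual2 <- qual(mate2)
    pairs <- tibble(
      id = sprintf("pair%06d", seq_len(n)),
      seq1 = mate1, qual1 = qual1, seq2 = mate2, qual2 = qual2)
    attr(pairs, "truth") <- tibble(
      id = pairs$id, start = start, frag_len = flen,
      is_artifact = is_artifact, n_err1 = e1$n_err, n_err2 = e2$n_err)
    pairs
  })
}
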