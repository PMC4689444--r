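# Read cleaning and fragment reconstruction. Order of operations is fixed:
# adapter/quality trimming, then artifact-pair removal, then overlap
# merging, following how short-insert survey libraries are processed.

#' Trimming and merging configuration
#'
#' @param adapter_seqs Character vector of adapter sequences to clip.
#' @param window_size,window_qual Sliding quality window: reads are cut at
#'   the first `window_size`-base window whose mean Phred quality falls
#'   below `window_qual` (defaults 4 and 15).
#' @param min_len Minimum post-trim mate length; pairs with a shorter mate
#'   are discarded whole (default 36).
#' @param artifact_tail_len Tail length for the identical-tail artifact
#'   rule (default 30).
#' @param min_overlap Minimum overlap for merging (default 10).
#' @param max_mismatch_ratio Maximum mismatches/overlap for an accepted
#'   merge (default 0.25).
#' @param adapter_max_mm,adapter_min_seed Adapter matching: at most
#'   `adapter_max_mm` mismatches over an aligned region of at least
#'   `adapter_min_seed` bases (defaults 2 and 10).
#' @return A `trim_config` list.
#' @export
trim_config <- function(adapter_seqs = default_adapter(), window_size = 4L,
                        window_qual = 15, min_len = 36L,
                        artifact_tail_len = 30L, min_overlap = 10L,
                        max_mismatch_ratio = 0.25, adapter_max_mm = 2L,
                        adapter_min_seed = 10L) {
  stopifnot(window_size > 0, window_qual > 0, min_len > 0,
            artifact_tail_len > 0, min_overlap > 0,
            max_mismatch_ratio >= 0, max_mismatch_ratio <= 1,
            adapter_max_mm >= 0, adapter_min_seed > 0)
  structure(
    list(adapter_seqs = toupper(adapter_seqs),
         window_size = as.integer(window_size), window_qual = window_qual,
         min_len = as.integer(min_len),
         artifact_tail_len = as.integer(artifact_tail_len),
         min_overlap = as.integer(min_overlap),
         max_mismatch_ratio = max_mismatch_ratio,
         adapter_max_mm = as.integer(adapter_max_mm),
         adapter_min_seed = as.integer(adapter_min_seed)),
    class = "trim_config")
}

trim_one_side <- function(seqs, quals, cfg) {
  keep_len <- nchar(seqs)
  for (ad in cfg$adapter_seqs) {
    pos <- adapter_clip_pos(toupper(seqs), ad, cfg$adapter_max_mm,
                            cfg$adapter_min_seed)
    keep_len <- pmin(keep_len, ifelse(is.na(pos), keep_len, pos - 1L))
  }
  seqs <- substr(seqs, 1L, keep_len)
  quals <- substr(quals, 1L, keep_len)
  qlen <- qual_trim_len(quals, cfg$window_size, cfg$window_qual)
  list(seq = substr(seqs, 1L, qlen), qual = substr(quals, 1L, qlen))
}

#' Adapter- and quality-trim read pairs
#'
#' Each mate is clipped at the leftmost adapter occurrence (at most
#' `adapter_max_mm` mismatches over at least `adapter_min_seed` aligned
#' bases), then truncated at the first sliding window whose mean quality
#' drops below `window_qual`. Pairs in which either mate ends up shorter
#' than `min_len` are discarded whole.
#'
#' @param pairs Read-pair tibble (`id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @param cfg A [trim_config()].
#' @return The surviving pairs, trimmed; `attr(, "tally")` is a tibble of
#'   per-reason counts that partitions the input
#'   (`kept + mate_too_short = total`).
#' @export
trim_pairs <- function(pairs, cfg = trim_config()) {
  t1 <- trim_one_side(pairs$seq1, pairs$qual1, cfg)
  t2 <- trim_one_side(pairs$seq2, pairs$qual2, cfg)
  ok <- nchar(t1$seq) >= cfg$min_len & nchar(t2$seq) >= cfg$min_len
  out <- tibble(id = pairs$id[ok],
                seq1 = t1$seq[ok], qual1 = t1$qual[ok],
                seq2 = t2$seq[ok], qual2 = t2$qual[ok])
  attr(out, "tally") <- tibble(
    reason = c("kept", "mate_too_short"),
    n = c(sum(ok), sum(!ok)))
  out
}

#' Flag identical-tail artifact pairs
#'
#' A pair is an orientation artifact when the final `tail_len` bases of the
#' two mates are identical on the same strand -- a properly overlapping
#' pair has mate 2 tails reverse-complementary, not identical. Comparison
#' is case-insensitive and `N` matches nothing. Mates shorter than
#' `tail_len` cannot be evaluated and are not flagged (their count is
#' reported in `attr(, "n_unevaluable")`).
#'
#' @param pairs Read-pair tibble.
#' @param tail_len Tail length in bases (default 30).
#' @return `pairs` with a logical `artifact` column added.
#' @export
flag_artifact_pairs <- function(pairs, tail_len = 30L) {
  l1 <- nchar(pairs$seq1)
  l2 <- nchar(pairs$seq2)
  evaluable <- l1 >= tail_len & l2 >= tail_len
  t1 <- toupper(substr(pairs$seq1, l1 - tail_len + 1L, l1))
  t2 <- toupper(substr(pairs$seq2, l2 - tail_len + 1L, l2))
  flagged <- evaluable & t1 == t2 & !stringr::str_detect(t1, "N")
  out <- mutate(pairs, artifact = flagged)
  attr(out, "n_unevaluable") <- sum(!evaluable)
  out
}

#' Merge overlapping read pairs into reconstructed fragments
#'
#' Mate 2 is reverse-complemented and slid against mate 1 over every
#' overlap length in `[min_overlap, min(len1, len2)]`. The overlap with the
#' lowest mismatch ratio wins (ties to the longer overlap) and is accepted
#' when the ratio is at most `max_mismatch_ratio`; the merged sequence
#' takes the higher-quality base wherever the mates disagree (quality ties
#' broken at random under `seed`). Non-merging pairs emit both mates as
#' unmerged fragments -- not merging is a valid outcome, not an error.
#'
#' @param pairs Read-pair tibble that passed trimming and the artifact
#'   filter.
#' @param cfg A [trim_config()].
#' @param seed Seed for quality-tie base resolution.
#' @return Fragment tibble: `id`, `seq`, `origin` (`merged`,
#'   `unmerged_mate1`, `unmerged_mate2`), `overlap_len` (NA when
#'   unmerged), `pair_id`.
#' @export
merge_pairs <- function(pairs, cfg = trim_config(), seed = 1L) {
  n <- nrow(pairs)
  if (n == 0) {
    return(tibble(id = character(), seq = character(), origin = character(),
                  overlap_len = integer(), pair_id = character()))
  }
  s1 <- toupper(pairs$seq1)
  rc2 <- revcomp(pairs$seq2)
  bo <- best_overlap(s1, rc2, cfg$min_overlap)
  o <- bo[, 1]
  mm <- bo[, 2]
  ratio <- ifelse(o > 0, mm / o, Inf)
  mergeable <- o >= cfg$min_overlap & ratio <= cfg$max_mismatch_ratio
  l1 <- nchar(s1)
  l2 <- nchar(rc2)
  merged_seq <- character(n)
  withr::with_seed(seed, {
    for (i in which(mergeable)) {
      oi <- o[i]
      left <- substr(s1[i], 1L, l1[i] - oi)
      ov1 <- substr(s1[i], l1[i] - oi + 1L, l1[i])
      ov2 <- substr(rc2[i], 1L, oi)
      if (mm[i] == 0) {
        ov <- ov1
      } else {
        c1 <- strsplit(ov1, "")[[1]]
        c2 <- strsplit(ov2, "")[[1]]
        q1 <- utf8ToInt(substr(pairs$qual1[i], l1[i] - oi + 1L, l1[i])) - 33L
        # rc2 position j came from mate2 position l2 - j + 1
        q2 <- rev(utf8ToInt(pairs$qual2[i]))[seq_len(oi)] - 33L
        pick2 <- q2 > q1 | (q2 == q1 & runif(oi) < 0.5)
        ov <- paste(ifelse(c1 == c2, c1, ifelse(pick2, c2, c1)),
                    collapse = "")
      }
      right <- substr(rc2[i], oi + 1L, l2[i])
      merged_seq[i] <- paste0(left, ov, right)
    }
  })
  merged <- tibble(
    id = pairs$id[mergeable],
    seq = merged_seq[mergeable],
    origin = "merged",
    overlap_len = as.integer(o[mergeable]),
    pair_id = pairs$id[mergeable])
  um <- which(!mergeable)
  unmerged <- tibble(
    id = c(paste0(pairs$id[um], "/1", recycle0 = TRUE),
           paste0(pairs$id[um], "/2", recycle0 = TRUE)),
    seq = c(s1[um], toupper(pairs$seq2[um])),
    origin = rep(c("unmerged_mate1", "unmerged_mate2"),
                 each = length(um)),
    overlap_len = NA_integer_,
    pair_id = rep(pairs$id[um], 2))
  bind_rows(merged, unmerged) %>% arrange(.data$pair_id, .data$origin)
}
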