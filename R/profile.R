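# Genome content profiling from unassembled reconstructed fragments:
# GC content, fold coverage, repeat-element content against a classified
# repeat library, gene-likeness against a protein set, and best-hit
# representation of reference transcript sets.

#' GC content of a fragment set
#'
#' `100 * (G + C) / (A + C + G + T)`; `N` bases are excluded from both
#' numerator and denominator.
#'
#' @param fragments Tibble with a `seq` column (or a character vector).
#' @return GC percentage (one number for the whole set).
#' @export
#' @examples
#' gc_content(c("GGCC", "ATAT"))
gc_content <- function(fragments) {
  seqs <- if (is.data.frame(fragments)) fragments$seq else fragments
  if (length(seqs) == 0) abort("no fragments")
  seqs <- toupper(seqs)
  gc <- sum(stringr::str_count(seqs, "[GC]"))
  acgt <- sum(stringr::str_count(seqs, "[ACGT]"))
  if (acgt == 0) abort("no unambiguous bases in fragments")
  100 * gc / acgt
}

#' Fold genome coverage from total fragment bases
#'
#' @param total_bases Total bases of reconstructed fragments.
#' @param genome_size_mbp Genome size in Mbp, or `NA` when unknown (the
#'   coverage is then reported unavailable, as for a species without a
#'   cytometry estimate).
#' @return Coverage in fold depth, rounded to 2 decimals; `NA` if the
#'   genome size is unknown.
#' @export
#' @examples
#' estimate_coverage(1827e6, 695)
estimate_coverage <- function(total_bases, genome_size_mbp) {
  if (is.na(genome_size_mbp)) return(NA_real_)
  if (genome_size_mbp <= 0) abort("genome_size_mbp must be positive")
  round(total_bases / (genome_size_mbp * 1e6), 2)
}

repeat_class_of <- function(ids) {
  cls <- stringr::str_split_i(ids, stringr::fixed("#"), 2)
  dplyr::if_else(is.na(cls) | cls == "", "other", cls)
}

#' Classify fragments against a repeat-element library
#'
#' Nucleotide seed-and-extend search (exact 12-base seeds, ungapped
#' extension at +1/-2 with x-drop 12) of every fragment against a repeat
#' library whose headers carry a `#class` suffix (e.g. `rnd1#Copia`). Each
#' fragment is assigned the class of its best hit with score at least
#' `min_score`.
#'
#' @param fragments Tibble with `id`, `seq`.
#' @param repeat_library Tibble with `id` (with `#class` suffix), `seq`.
#' @param min_score Minimum alignment score for an assignment (default 30).
#' @return List with `hits` (per-fragment best hits with `class`) and
#'   `fractions` (per-class percent of fragments, plus a `total` row).
#' @export
classify_repeats <- function(fragments, repeat_library, min_score = 30L) {
  n_frag <- nrow(fragments)
  if (is.null(repeat_library) || nrow(repeat_library) == 0) {
    warn("empty repeat library; repeat fractions are all zero")
    return(list(
      hits = tibble(fragment_id = character(), subject_id = character(),
                    class = character(), score = integer(),
                    identity = double()),
      fractions = tibble(class = "total", n_fragments = 0L, percent = 0)))
  }
  hits <- nt_search(fragments, repeat_library, min_score = min_score)
  best <- hits %>%
    mutate(class = repeat_class_of(.data$subject_id)) %>%
    group_by(fragment_id = .data$query_id) %>%
    arrange(dplyr::desc(.data$score), .data$subject_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  fr <- best %>%
    count(.data$class, name = "n_fragments") %>%
    mutate(percent = 100 * .data$n_fragments / n_frag)
  fractions <- bind_rows(
    fr,
    tibble(class = "total", n_fragments = nrow(best),
           percent = 100 * nrow(best) / n_frag))
  list(hits = select(best, "fragment_id", "subject_id", "class", "score",
                     "identity"),
       fractions = fractions)
}

#' Find gene-like fragments by translated similarity search
#'
#' Fragments are translated in all six frames (stops break segments) and
#' searched against a protein set with exact 4-residue seeds, ungapped
#' BLOSUM62 extension, and Karlin-Altschul expectation values. A fragment
#' is gene-like when any hit has an expectation below `evalue_cutoff`.
#'
#' @param fragments Tibble with `id`, `seq`; fragments shorter than 3
#'   bases are skipped.
#' @param proteins Tibble with `id`, `seq` in amino-acid alphabet.
#' @param evalue_cutoff Expectation-value cutoff (default `1e-5`).
#' @return List with `hits` (fragment/protein hits passing the cutoff),
#'   `gene_like_ids` and `gene_fraction` (percent of fragments).
#' @export
find_gene_like <- function(fragments, proteins, evalue_cutoff = 1e-5) {
  stopifnot(nrow(proteins) > 0)
  segs <- six_frame_segments(fragments$seq, min_len = 5L)
  if (nrow(segs) == 0) {
    return(list(hits = tibble(), gene_like_ids = character(),
                gene_fraction = 0))
  }
  hits <- aa_search(segs, proteins) %>%
    filter(.data$evalue < evalue_cutoff) %>%
    mutate(fragment_id = fragments$id[segs$fragment_idx[.data$segment_idx]],
           frame = segs$frame[.data$segment_idx]) %>%
    group_by(.data$fragment_id, .data$protein_id) %>%
    arrange(.data$evalue, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("fragment_id", "protein_id", "frame", "score", "evalue")
  ids <- unique(hits$fragment_id)
  list(hits = hits,
       gene_like_ids = ids,
       gene_fraction = 100 * length(ids) / nrow(fragments))
}

#' Reference-gene representation of gene-like fragments
#'
#' Each gene-like fragment is assigned to its single best-scoring
#' transcript (translated-vs-translated comparison; score ties break to
#' the lexicographically lowest transcript id). The result is the percent
#' of transcripts with at least one assigned fragment.
#'
#' @param gene_like_fragments Tibble with `id`, `seq` -- the gene-like
#'   subset from [find_gene_like()].
#' @param transcripts Tibble with `id`, `seq` (nucleotide transcript set).
#' @return List with `assignments` (fragment to transcript) and
#'   `percent_represented`.
#' @export
gene_representation <- function(gene_like_fragments, transcripts) {
  if (is.null(transcripts) || nrow(transcripts) == 0) {
    abort("empty transcript set")
  }
  n_tr <- nrow(transcripts)
  if (nrow(gene_like_fragments) == 0) {
    return(list(assignments = tibble(fragment_id = character(),
                                     transcript_id = character(),
                                     score = integer()),
                percent_represented = 0))
  }
  qsegs <- six_frame_segments(gene_like_fragments$seq, min_len = 5L)
  tsegs <- six_frame_segments(transcripts$seq, min_len = 5L)
  sm <- aa_score_matrix()
  h <- seed_extend_search(qsegs$segment, tsegs$segment, 4L, sm, 20L,
                          coder = aa_kmer_codes)
  if (nrow(h) == 0) {
    return(list(assignments = tibble(fragment_id = character(),
                                     transcript_id = character(),
                                     score = integer()),
                percent_represented = 0))
  }
  assignments <- h %>%
    mutate(fragment_id = gene_like_fragments$id[qsegs$fragment_idx[.data$q]],
           transcript_id = transcripts$id[tsegs$fragment_idx[.data$s]]) %>%
    group_by(.data$fragment_id) %>%
    arrange(dplyr::desc(.data$score), .data$transcript_id,
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("fragment_id", "transcript_id", "score")
  list(assignments = assignments,
       percent_represented =
         100 * dplyr::n_distinct(assignments$transcript_id) / n_tr)
}
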