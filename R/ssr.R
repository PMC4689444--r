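# Perfect microsatellite mining. Loci are reported per repeat period under
# inclusive copy-number windows chosen for marker development: dinucleotide
# motifs at 8-40 copies, trinucleotide at 7-30, tetranucleotide at 6-20.
# Coordinates are 0-based, half-open.

#' Copy-number windows for SSR reporting
#'
#' Inclusive copy-count windows per motif period. A perfect repeat is
#' reported only if its copy number falls inside its period's window.
#'
#' @param min_copies,max_copies Integer vectors of length 3 (periods 2, 3,
#'   4), inclusive bounds.
#' @return Tibble with columns `period`, `min_copies`, `max_copies`.
#' @export
ssr_copy_windows <- function(min_copies = c(8L, 7L, 6L),
                             max_copies = c(40L, 30L, 20L)) {
  stopifnot(length(min_copies) == 3, length(max_copies) == 3,
            all(min_copies >= 2), all(max_copies >= min_copies))
  tibble(period = 2:4,
         min_copies = as.integer(min_copies),
         max_copies = as.integer(max_copies))
}

empty_loci <- function() {
  tibble(fragment_id = character(), start = integer(), end = integer(),
         period = integer(), motif = character(),
         canonical_motif = character(), copies = integer(),
         left_flank = integer(), right_flank = integer())
}

#' Find perfect microsatellites in fragments
#'
#' Scans every fragment for maximal perfect tandem repeats of period 2, 3
#' and 4. A run is maximal when it cannot be extended by one base in either
#' direction; its copy count is the number of whole motif copies, and it is
#' reported only when that count lies inside the period's inclusive window
#' (see [ssr_copy_windows()]). Runs whose repeat unit is itself a
#' repetition of a shorter unit (e.g. `ATAT`, or a homopolymer) are left to
#' the shorter period, so no locus is double-reported. `N` breaks any
#' repeat.
#'
#' @param fragments Tibble with columns `id` and `seq`.
#' @param copy_windows Tibble as returned by [ssr_copy_windows()].
#' @return Tibble of loci: `fragment_id`, `start`, `end` (0-based,
#'   half-open), `period`, `motif` (as found at the locus start),
#'   `canonical_motif`, `copies`, `left_flank`, `right_flank` (distance to
#'   the fragment ends).
#' @export
#' @examples
#' frags <- tibble::tibble(id = "f1",
#'   seq = paste0(strrep("GCTAGCCTGAAGCTAGCCTG", 1), strrep("AT", 10),
#'                "GATCGGATACCTGATCGGATA"))
#' find_perfect_ssrs(frags)
find_perfect_ssrs <- function(fragments, copy_windows = ssr_copy_windows()) {
  stopifnot(all(c("id", "seq") %in% names(fragments)))
  if (nrow(fragments) == 0) return(empty_loci())
  seqs <- toupper(fragments$seq)
  lens <- nchar(seqs)
  sep_n <- 8L
  big <- paste(seqs, collapse = strrep("N", sep_n))
  ints <- dna_to_int(big)
  offs <- cumsum(c(0L, head(lens, -1) + sep_n)) # 0-based fragment starts
  n <- length(ints)
  out <- vector("list", 3)
  for (k in seq_len(3)) {
    p <- copy_windows$period[k]
    minc <- copy_windows$min_copies[k]
    maxc <- copy_windows$max_copies[k]
    if (n <= p) next
    a <- ints[seq_len(n - p)]
    b <- ints[(p + 1):n]
    eq <- !is.na(a) & !is.na(b) & a == b
    r <- rle(eq)
    rends <- cumsum(r$lengths)
    rstarts <- rends - r$lengths + 1L
    # run of L TRUEs = repeat region of L + p bases
    cand <- which(r$values & r$lengths >= p * (minc - 1L))
    if (length(cand) == 0) next
    rs <- rstarts[cand]
    copies <- (r$lengths[cand] + p) %/% p
    motif <- substring(big, rs, rs + p - 1L)
    red <- switch(as.character(p),
      "2" = substring(motif, 1, 1) == substring(motif, 2, 2),
      "3" = substring(motif, 1, 1) == substring(motif, 2, 2) &
            substring(motif, 2, 2) == substring(motif, 3, 3),
      "4" = substring(motif, 1, 2) == substring(motif, 3, 4))
    keep <- !red & copies >= minc & copies <= maxc
    if (!any(keep)) next
    rs <- rs[keep]; copies <- copies[keep]; motif <- motif[keep]
    fi <- findInterval(rs - 1L, offs)
    start <- (rs - 1L) - offs[fi]
    out[[k]] <- tibble(
      fragment_id = fragments$id[fi],
      start = as.integer(start),
      end = as.integer(start + p * copies),
      period = as.integer(p),
      motif = motif,
      copies = as.integer(copies),
      frag_len = lens[fi])
  }
  loci <- bind_rows(out)
  if (nrow(loci) == 0) return(empty_loci())
  canon <- tibble(motif = unique(loci$motif))
  canon$canonical_motif <- canonical_motif(canon$motif)
  loci %>%
    left_join(canon, by = "motif") %>%
    mutate(left_flank = .data$start,
           right_flank = .data$frag_len - .data$end) %>%
    select("fragment_id", "start", "end", "period", "motif",
           "canonical_motif", "copies", "left_flank", "right_flank") %>%
    arrange(.data$fragment_id, .data$start, .data$period)
}

#' Flank and compound filters for SSR loci
#'
#' A locus survives only if at least `min_flank` bases of non-repetitive,
#' N-free sequence flank it on both sides within its fragment. Two loci on
#' the same fragment separated by fewer than `min_flank` non-SSR bases are
#' a compound SSR and are both removed.
#'
#' @param loci Loci tibble from [find_perfect_ssrs()].
#' @param fragments The fragment tibble the loci were mined from.
#' @param min_flank Minimum flank length in bases (default 15).
#' @return Filtered loci tibble (same columns).
#' @export
apply_flank_and_compound_filters <- function(loci, fragments, min_flank = 15L) {
  stopifnot(min_flank >= 0)
  if (nrow(loci) == 0) return(loci)
  seqs <- setNames(toupper(fragments$seq), fragments$id)
  loci %>%
    group_by(.data$fragment_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(
      gap_prev = as.numeric(.data$start) -
        dplyr::lag(as.numeric(.data$end), default = -Inf),
      gap_next = dplyr::lead(as.numeric(.data$start), default = Inf) -
        .data$end
    ) %>%
    ungroup() %>%
    filter(.data$left_flank >= min_flank,
           .data$right_flank >= min_flank,
           .data$gap_prev >= min_flank,
           .data$gap_next >= min_flank) %>%
    filter(!stringr::str_detect(
      substring(seqs[.data$fragment_id],
                .data$start - min_flank + 1L, .data$start), "N")) %>%
    filter(!stringr::str_detect(
      substring(seqs[.data$fragment_id],
                .data$end + 1L, .data$end + min_flank), "N")) %>%
    select(-"gap_prev", -"gap_next")
}

# Minimal union-find for single-linkage clustering.
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Collapse duplicate SSR loci across near-identical fragments
#'
#' Low-coverage libraries sample the same genomic locus more than once, so
#' SSR-bearing fragments are deduplicated before counting: two fragments
#' join one cluster when their best ungapped overlap alignment reaches the
#' identity threshold over at least `min_overlap` bases (single linkage).
#' The longest fragment represents each cluster and only its loci are kept.
#'
#' @param loci Filtered loci tibble.
#' @param fragments Fragment tibble (must cover all loci fragments).
#' @param identity_threshold Minimum alignment identity (default 0.95).
#' @param min_overlap Minimum aligned length in bases (default 50).
#' @return Loci tibble restricted to cluster representatives, with columns
#'   `cluster` and `cluster_size` added; the fragment-to-cluster map is in
#'   `attr(, "clusters")`.
#' @export
collapse_loci <- function(loci, fragments, identity_threshold = 0.95,
                          min_overlap = 50L) {
  if (nrow(loci) == 0) {
    return(mutate(loci, cluster = integer(), cluster_size = integer()))
  }
  ids <- unique(loci$fragment_id)
  frs <- fragments %>% filter(.data$id %in% ids)
  frs <- frs[match(ids, frs$id), ]
  stopifnot(!anyNA(frs$id))
  hits <- nt_self_hits(frs$seq, min_overlap = min_overlap,
                       min_identity = identity_threshold)
  parent <- seq_along(ids)
  if (nrow(hits) > 0) {
    for (i in seq_len(nrow(hits))) {
      a <- uf_find(parent, hits$q[i])
      b <- uf_find(parent, hits$s[i])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_along(ids), function(i) uf_find(parent, i), integer(1))
  cl <- match(root, sort(unique(root)))
  clusters <- tibble(id = ids, cluster = cl, len = nchar(frs$seq)) %>%
    group_by(.data$cluster) %>%
    mutate(cluster_size = n(),
           representative = .data$id[which.max(.data$len)]) %>%
    ungroup()
  out <- loci %>%
    inner_join(
      clusters %>%
        filter(.data$id == .data$representative) %>%
        select(fragment_id = "id", "cluster", "cluster_size"),
      by = "fragment_id")
  attr(out, "clusters") <- select(clusters, "id", "cluster", "representative")
  out
}

#' Density and motif-class frequency statistics for an SSR set
#'
#' @param loci Final loci tibble.
#' @param total_bases Total fragment bases searched (denominator for the
#'   per-Mb density).
#' @return An object of class `ssr_stats`; `tidy()` gives the per-period
#'   canonical-class frequency table (integer percentages by
#'   largest-remainder rounding, summing to 100 within each period) and
#'   `glance()` the one-row density summary.
#' @export
ssr_statistics <- function(loci, total_bases) {
  if (total_bases <= 0) abort("total_bases must be positive")
  freq <- loci %>%
    count(.data$period, class = .data$canonical_motif) %>%
    group_by(.data$period) %>%
    mutate(percent = round_percent(100 * .data$n / sum(.data$n))) %>%
    ungroup() %>%
    arrange(.data$period, dplyr::desc(.data$n), .data$class)
  structure(
    list(
      n_loci = nrow(loci),
      total_bases = total_bases,
      loci_per_mb = nrow(loci) / (total_bases / 1e6),
      frequency = freq),
    class = "ssr_stats")
}

#' @export
tidy.ssr_stats <- function(x, ...) x$frequency

#' @export
glance.ssr_stats <- function(x, ...) {
  tibble(n_loci = x$n_loci, total_bases = x$total_bases,
         loci_per_mb = x$loci_per_mb)
}

#' @export
print.ssr_stats <- function(x, ...) {
  cat("SSR statistics:", x$n_loci, "loci in",
      sprintf("%.3f Mb (%.1f loci/Mb)\n", x$total_bases / 1e6,
              x$loci_per_mb))
  print(x$frequency, n = 20)
  invisible(x)
}
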