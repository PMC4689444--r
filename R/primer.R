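# Constraint-based primer design around surviving SSR loci. Candidates are
# enumerated exhaustively in both flanks, filtered against the printed
# primer constraints, and paired under the product-size window with a
# deterministic objective, yielding potentially amplifiable loci (PALs).

#' Primer design constraints
#'
#' Defaults mirror standard microsatellite marker design settings:
#' `primer_opt_size = 20`, `primer_min_size = 18`, `primer_max_size = 25`,
#' `primer_num_ns_accepted = 0`, `primer_product_size_range = 100-200`,
#' `primer_opt_tm = 60`, `primer_min_tm = 55`, `primer_max_tm = 65`,
#' `primer_min_gc = 40`, `primer_max_gc = 60`, `primer_max_poly_x = 3`,
#' `primer_gc_clamp = 2`.
#'
#' @param opt_size,min_size,max_size Primer length (bases).
#' @param max_ns Maximum number of N bases allowed in a primer.
#' @param product_range Length-2 vector, inclusive product size window.
#' @param opt_tm,min_tm,max_tm Melting temperature (deg C).
#' @param min_gc,max_gc GC percent bounds.
#' @param max_poly_x Longest allowed single-base run.
#' @param gc_clamp Number of 3'-terminal bases required to be G or C.
#' @param dust_level Low-complexity masking stringency (see [dust_mask()]).
#' @return A `primer_constraints` list.
#' @export
primer_constraints <- function(opt_size = 20L, min_size = 18L,
                               max_size = 25L, max_ns = 0L,
                               product_range = c(100L, 200L),
                               opt_tm = 60, min_tm = 55, max_tm = 65,
                               min_gc = 40, max_gc = 60, max_poly_x = 3L,
                               gc_clamp = 2L, dust_level = 1) {
  stopifnot(min_size <= opt_size, opt_size <= max_size,
            min_tm <= opt_tm, opt_tm <= max_tm,
            product_range[1] < product_range[2], gc_clamp >= 0)
  structure(
    list(opt_size = as.integer(opt_size), min_size = as.integer(min_size),
         max_size = as.integer(max_size), max_ns = as.integer(max_ns),
         product_range = as.integer(product_range),
         opt_tm = opt_tm, min_tm = min_tm, max_tm = max_tm,
         min_gc = min_gc, max_gc = max_gc,
         max_poly_x = as.integer(max_poly_x),
         gc_clamp = as.integer(gc_clamp), dust_level = dust_level),
    class = "primer_constraints")
}

# All single-primer candidates within [lo, hi) (0-based, half-open) of the
# fragment. side = "left": primer on plus strand; side = "right": primer is
# the reverse complement of the site. Returns start/end in 0-based
# half-open plus-strand coordinates plus seq, tm, gc, cost.
primer_candidates <- function(frag, lo, hi, cons, masked, side) {
  if (hi - lo < cons$min_size) return(NULL)
  grid <- tidyr::expand_grid(
    start = lo:(hi - cons$min_size),
    len = cons$min_size:cons$max_size) %>%
    filter(.data$start + .data$len <= hi)
  if (nrow(grid) == 0) return(NULL)
  site <- substring(frag, grid$start + 1L, grid$start + grid$len)
  seq <- if (side == "left") site else revcomp(site)
  hit_mask <- vapply(seq_len(nrow(grid)), function(i) {
    any(masked[(grid$start[i] + 1L):(grid$start[i] + grid$len[i])])
  }, logical(1))
  tm <- primer_tm(seq)
  gc <- primer_gc_percent(seq)
  clamp_ok <- if (cons$gc_clamp > 0) {
    stringr::str_count(substr(seq, nchar(seq) - cons$gc_clamp + 1L,
                              nchar(seq)), "[GC]") >= cons$gc_clamp
  } else TRUE
  keep <- !hit_mask &
    stringr::str_count(seq, "N") <= cons$max_ns &
    !is.na(tm) & tm >= cons$min_tm & tm <= cons$max_tm &
    gc >= cons$min_gc & gc <= cons$max_gc &
    !has_long_homopolymer(seq, cons$max_poly_x) &
    clamp_ok
  if (!any(keep)) return(NULL)
  tibble(start = grid$start[keep], end = grid$start[keep] + grid$len[keep],
         seq = seq[keep], tm = tm[keep], gc = gc[keep],
         cost = abs(grid$len[keep] - cons$opt_size) +
           abs(tm[keep] - cons$opt_tm))
}

#' Enumerate all constraint-satisfying primer pairs for one locus
#'
#' The exhaustive candidate-pair set that [design_primers()] selects from:
#' every left/right primer combination satisfying all single-primer
#' constraints with a product size inside `cons$product_range`.
#'
#' @inheritParams design_primers
#' @return Tibble of candidate pairs (left/right coordinates, sequences,
#'   Tm, GC, `product_size`, `cost`), or `NULL` when none qualify.
#' @export
enumerate_primer_pairs <- function(frag, locus_start, locus_end,
                                   cons = primer_constraints(),
                                   masked = NULL,
                                   ssr_ranges = NULL) {
  frag <- toupper(frag)
  n <- nchar(frag)
  if (is.null(masked)) masked <- dust_mask_vec(frag, cons$dust_level)
  if (!is.null(ssr_ranges) && nrow(ssr_ranges) > 0) {
    for (i in seq_len(nrow(ssr_ranges))) {
      masked[(ssr_ranges$start[i] + 1L):ssr_ranges$end[i]] <- TRUE
    }
  } else {
    masked[(locus_start + 1L):locus_end] <- TRUE
  }
  lefts <- primer_candidates(frag, 0L, locus_start, cons, masked, "left")
  rights <- primer_candidates(frag, locus_end, n, cons, masked, "right")
  if (is.null(lefts) || is.null(rights)) return(NULL)
  # product spans [left$start, right$end); size window is inclusive
  dt_l <- data.table::as.data.table(lefts)
  dt_r <- data.table::as.data.table(rights)
  dt_l[, `:=`(re_min = dt_l$start + cons$product_range[1],
              re_max = dt_l$start + cons$product_range[2])]
  data.table::setnames(dt_r, paste0("r_", names(dt_r)))
  pairs <- dt_r[dt_l, on = .(r_end >= re_min, r_end <= re_max),
                allow.cartesian = TRUE, nomatch = NULL,
                .(l_start = i.start, l_end = i.end, l_seq = i.seq,
                  l_tm = i.tm, l_gc = i.gc, l_cost = i.cost,
                  r_start = x.r_start, r_end = x.r_end, r_seq = x.r_seq,
                  r_tm = x.r_tm, r_gc = x.r_gc, r_cost = x.r_cost)]
  if (nrow(pairs) == 0) return(NULL)
  as_tibble(pairs) %>%
    mutate(product_size = .data$r_end - .data$l_start,
           cost = .data$l_cost + .data$r_cost)
}

#' Design a primer pair around one SSR locus
#'
#' Enumerates every candidate primer in each flank with length in
#' `[min_size, max_size]`, discards candidates violating any constraint
#' (N content, GC percent, nearest-neighbor Tm, homopolymer runs, 3' GC
#' clamp, overlap with dust-masked or SSR bases), and selects the pair
#' whose product size lies inside `product_range` minimizing
#' `|len_l - opt_size| + |len_r - opt_size| + |tm_l - opt_tm| +
#' |tm_r - opt_tm|`; ties break to the smaller product, then the leftmost
#' left primer. Returns `NULL` when no pair qualifies (a flank shorter
#' than `min_size` is a normal non-result, not an error).
#'
#' @param frag Fragment sequence (one string).
#' @param locus_start,locus_end SSR coordinates, 0-based half-open.
#' @param cons A [primer_constraints()].
#' @param masked Optional logical mask (TRUE = base unavailable); computed
#'   by [dust_mask()] at `cons$dust_level` if omitted.
#' @param ssr_ranges Optional tibble of all SSR ranges on the fragment
#'   (`start`, `end`), all excluded from primers.
#' @return One-row tibble (left/right primer sequence, 0-based plus-strand
#'   site coordinates, Tm, GC, `product_size`) or `NULL`.
#' @export
design_primers <- function(frag, locus_start, locus_end,
                           cons = primer_constraints(), masked = NULL,
                           ssr_ranges = NULL) {
  pairs <- enumerate_primer_pairs(frag, locus_start, locus_end, cons,
                                  masked, ssr_ranges)
  if (is.null(pairs)) return(NULL)
  pairs %>%
    arrange(.data$cost, .data$product_size, .data$l_start, .data$r_start) %>%
    slice(1) %>%
    select(left_primer = "l_seq", left_start = "l_start",
           left_end = "l_end", left_tm = "l_tm", left_gc = "l_gc",
           right_primer = "r_seq", right_start = "r_start",
           right_end = "r_end", right_tm = "r_tm", right_gc = "r_gc",
           "product_size")
}

#' Design primers for every locus in a fragment set
#'
#' Applies dust masking once per fragment and [design_primers()] to each
#' locus, yielding the PAL (potentially amplifiable locus) table.
#'
#' @param loci Loci tibble (post-filter, typically post-collapse).
#' @param fragments Fragment tibble covering the loci.
#' @param cons A [primer_constraints()].
#' @return PAL tibble: the locus columns plus the primer-pair columns of
#'   [design_primers()].
#' @export
design_pals <- function(loci, fragments, cons = primer_constraints()) {
  seqs <- setNames(toupper(fragments$seq), fragments$id)
  out <- vector("list", nrow(loci))
  masks <- list()
  for (i in seq_len(nrow(loci))) {
    fid <- loci$fragment_id[i]
    frag <- seqs[[fid]]
    key <- paste0("m", match(fid, fragments$id))
    if (is.null(masks[[key]])) {
      masks[[key]] <- dust_mask_vec(frag, cons$dust_level)
    }
    ranges <- loci %>% filter(.data$fragment_id == fid) %>%
      select("start", "end")
    pr <- design_primers(frag, loci$start[i], loci$end[i], cons,
                         masked = masks[[key]], ssr_ranges = ranges)
    if (!is.null(pr)) out[[i]] <- bind_cols(loci[i, ], pr)
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- bind_cols(loci[0, ],
                     tibble(left_primer = character(),
                            left_start = integer(), left_end = integer(),
                            left_tm = double(), left_gc = double(),
                            right_primer = character(),
                            right_start = integer(), right_end = integer(),
                            right_tm = double(), right_gc = double(),
                            product_size = integer()))
  }
  res
}

#' PAL yield summary
#'
#' @param pals PAL tibble from [design_pals()].
#' @param loci The locus set primers were attempted for.
#' @param total_bases Total fragment bases (for the per-Mb density).
#' @return One-row tibble: `n_pals`, `pals_per_mb`, `pal_per_gssr_percent`,
#'   plus per-period PAL shares (`share_p2`, `share_p3`, `share_p4`, in
#'   percent of PALs).
#' @export
pal_statistics <- function(pals, loci, total_bases) {
  n_pal <- nrow(pals)
  share <- function(p) {
    if (n_pal == 0) return(NA_real_)
    100 * sum(pals$period == p) / n_pal
  }
  tibble(
    n_pals = n_pal,
    pals_per_mb = if (total_bases > 0) n_pal / (total_bases / 1e6) else NA_real_,
    pal_per_gssr_percent = if (nrow(loci) > 0) 100 * n_pal / nrow(loci)
                           else NA_real_,
    share_p2 = share(2L), share_p3 = share(3L), share_p4 = share(4L))
}
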