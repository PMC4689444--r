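# Canonical microsatellite motif classes. Motifs that are cyclic rotations
# of one another, or rotations of the reverse complement, describe the same
# repeat locus read from a different phase or strand, so they are merged
# into one equivalence class named by its lexicographically smallest member
# (e.g. AG, GA, CT and TC are all class "AG").

rotations <- function(m) {
  n <- nchar(m)
  vapply(seq_len(n), function(i) {
    paste0(substr(m, i, n), substr(m, 1, i - 1))
  }, character(1))
}

# TRUE if the motif is a whole-number repetition of a shorter unit
# (including homopolymers), i.e. not a genuine period-n motif.
is_reducible_motif <- function(m) {
  n <- nchar(m)
  for (d in seq_len(n - 1)) {
    if (n %% d == 0) {
      unit <- substr(m, 1, d)
      if (strrep(unit, n / d) == m) return(TRUE)
    }
  }
  FALSE
}

#' Canonical representative of a microsatellite motif
#'
#' Returns the lexicographically smallest string among all cyclic rotations
#' of the motif and of its reverse complement. Two motifs describe the same
#' repeat class iff they share a representative.
#'
#' @param motif Character vector of motifs, each 2-4 bases over `ACGT` and
#'   not a repetition of a shorter unit (homopolymers and e.g. `"ATAT"` are
#'   rejected).
#' @return Character vector of class representatives.
#' @export
#' @examples
#' canonical_motif(c("GA", "TTC", "CAT"))
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  bad <- !stringr::str_detect(motif, "^[ACGT]{2,4}$")
  if (any(bad)) {
    abort(paste0("motifs must be 2-4 bases over ACGT: ",
                 paste(unique(motif[bad]), collapse = ", ")))
  }
  vapply(motif, function(m) {
    if (is_reducible_motif(m)) {
      abort(paste0("motif '", m, "' is a repetition of a shorter unit"))
    }
    min(c(rotations(m), rotations(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

#' Enumerate canonical motif classes for a repeat period
#'
#' Enumerates all irreducible motifs of the given period and groups them by
#' [canonical_motif()]. Periods 2, 3 and 4 have exactly 4, 10 and 33
#' classes.
#'
#' @param period Motif length (2, 3 or 4).
#' @return Tibble with columns `class` (representative) and `members`
#'   (list-column of all motifs in the class).
#' @export
motif_classes <- function(period) {
  stopifnot(period %in% 2:4)
  all_motifs <- do.call(paste0, expand.grid(
    rep(list(DNA_BASES), period), stringsAsFactors = FALSE))
  keep <- !vapply(all_motifs, is_reducible_motif, logical(1))
  motifs <- sort(all_motifs[keep])
  tibble(motif = motifs, class = canonical_motif(motifs)) %>%
    group_by(.data$class) %>%
    summarise(members = list(.data$motif), .groups = "drop")
}
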