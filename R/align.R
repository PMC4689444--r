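# Minimal seeded, ungapped sequence search: exact word seeds located by a
# k-mer hash join, extended without gaps under an x-drop rule. Nucleotide
# search scores +1/-2; protein search scores with BLOSUM62 and converts
# scores to expectation values with the matrix's published ungapped
# Karlin-Altschul parameters.

# 128x128 score matrix indexed by character code.
nt_score_matrix <- function(match = 1L, mismatch = -2L) {
  m <- matrix(mismatch, 128, 128)
  for (b in DNA_BASES) {
    i <- utf8ToInt(b) + 1L
    m[i, i] <- match
  }
  n <- utf8ToInt("N") + 1L
  m[n, ] <- mismatch
  m[, n] <- mismatch
  m
}

aa_score_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  bl <- e$BLOSUM62
  m <- matrix(-4L, 128, 128)
  letters_aa <- rownames(bl)
  for (a in letters_aa) {
    for (b in letters_aa) {
      m[utf8ToInt(a) + 1L, utf8ToInt(b) + 1L] <- bl[a, b]
    }
  }
  m
}

# Ungapped Karlin-Altschul parameters for BLOSUM62 (Altschul & Gish 1996).
BLOSUM62_LAMBDA <- 0.3176
BLOSUM62_K <- 0.134

aa_to_int <- function(seq) {
  # 26-letter alphabet; '*' and unknowns -> NA (never seeds)
  ints <- utf8ToInt(seq) - utf8ToInt("A")
  ints[ints < 0 | ints > 25] <- NA_integer_
  ints
}

aa_kmer_codes <- function(seq, k) {
  ints <- aa_to_int(seq)
  n <- length(ints)
  if (n < k) return(numeric(0))
  x <- as.numeric(ints)
  isna <- is.na(x)
  x[isna] <- 0
  code <- numeric(n - k + 1)
  for (j in seq_len(k)) code <- code + x[j:(n - k + j)] * 26^(k - j)
  cs <- c(0, cumsum(isna))
  bad <- (cs[(k + 1):(n + 1)] - cs[seq_len(n - k + 1)]) > 0
  code[bad] <- NA_real_
  code
}

nt_kmer_codes <- function(seq, k) kmer_codes(dna_to_int(seq), k)

# data.table of (code, sid, pos) for a set of sequences, NA codes dropped.
kmer_table <- function(seqs, k, coder) {
  lst <- lapply(seqs, coder, k = k)
  lens <- lengths(lst)
  dt <- data.table::data.table(
    code = unlist(lst, use.names = FALSE),
    sid = rep(seq_along(seqs), lens),
    pos = unlist(lapply(lens, seq_len), use.names = FALSE))
  dt <- dt[!is.na(dt$code)]
  # one seed position per distinct word per sequence: repetitive runs would
  # otherwise contribute quadratically many equivalent seeds
  unique(dt, by = c("code", "sid"))
}

# Seed-and-extend between two sequence sets. Returns one best hit per
# (query, subject, strand) combination.
seed_extend_search <- function(qseqs, sseqs, word, score_matrix, xdrop,
                               coder = nt_kmer_codes) {
  empty <- tibble(q = integer(), s = integer(), score = integer(),
                  qstart = integer(), qend = integer(),
                  sstart = integer(), send = integer())
  if (length(qseqs) == 0 || length(sseqs) == 0) return(empty)
  qt <- kmer_table(qseqs, word, coder)
  st <- kmer_table(sseqs, word, coder)
  if (nrow(qt) == 0 || nrow(st) == 0) return(empty)
  data.table::setnames(st, c("code", "ssid", "spos"))
  data.table::setkey(st, code)
  seeds <- st[qt, on = "code", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(seeds) == 0) return(empty)
  seeds[, `:=`(diag = seeds$pos - seeds$spos)]
  seeds <- seeds[order(seeds$pos)]
  seeds <- unique(seeds, by = c("sid", "ssid", "diag"))
  ext <- xdrop_extend(qseqs, sseqs, seeds$sid, seeds$ssid,
                      seeds$pos, seeds$spos, word, score_matrix, xdrop)
  hits <- tibble(q = seeds$sid, s = seeds$ssid,
                 score = ext[, 1], qstart = ext[, 2], qend = ext[, 3],
                 sstart = ext[, 4], send = ext[, 5])
  hits %>%
    group_by(.data$q, .data$s) %>%
    arrange(dplyr::desc(.data$score), .data$qstart, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
}

#' Nucleotide similarity search (seeded, ungapped)
#'
#' Finds local ungapped alignments between query fragments and subject
#' sequences from exact 12-base word seeds, scoring +1 per match and -2 per
#' mismatch with x-drop termination. Both query strands are searched.
#'
#' @param queries,subjects Tibbles with columns `id` and `seq`.
#' @param word Exact seed length (default 12).
#' @param xdrop Extension stops when the running score falls this far below
#'   the best (default 12).
#' @param min_score Minimum alignment score to report (default 30).
#' @return Tibble of hits: `query_id`, `subject_id`, `strand`, `score`,
#'   `length` (aligned span), `identity` (fraction), plus 1-based alignment
#'   coordinates (`qstart`/`qend` on the searched strand).
#' @export
nt_search <- function(queries, subjects, word = 12L, xdrop = 12L,
                      min_score = 30L) {
  sm <- nt_score_matrix()
  run_one <- function(qs, strand) {
    h <- seed_extend_search(qs, subjects$seq, word, sm, xdrop)
    if (nrow(h) == 0) return(h)
    mutate(h, strand = strand)
  }
  fwd <- run_one(queries$seq, "+")
  rev <- run_one(revcomp(queries$seq), "-")
  hits <- bind_rows(fwd, rev)
  if (nrow(hits) == 0) {
    return(tibble(query_id = character(), subject_id = character(),
                  strand = character(), score = integer(),
                  length = integer(), identity = double(),
                  qstart = integer(), qend = integer(),
                  sstart = integer(), send = integer()))
  }
  hits %>%
    mutate(length = .data$qend - .data$qstart + 1L,
           identity = (2 * .data$length + .data$score) / (3 * .data$length),
           query_id = queries$id[.data$q],
           subject_id = subjects$id[.data$s]) %>%
    filter(.data$score >= min_score) %>%
    group_by(.data$query_id, .data$subject_id) %>%
    arrange(dplyr::desc(.data$score), .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("query_id", "subject_id", "strand", "score", "length",
           "identity", "qstart", "qend", "sstart", "send")
}

# All-vs-all nucleotide hits within one sequence set; returns index pairs
# (q < s) whose best ungapped overlap alignment reaches the identity
# threshold over min_overlap bases. Both strands are considered.
nt_self_hits <- function(seqs, min_overlap, min_identity) {
  sm <- nt_score_matrix()
  pairs_of <- function(qs) {
    h <- seed_extend_search(qs, seqs, 12L, sm, 20L)
    h %>%
      mutate(length = .data$qend - .data$qstart + 1L,
             identity = (2 * .data$length + .data$score) / (3 * .data$length))
  }
  h <- bind_rows(pairs_of(seqs), pairs_of(revcomp(seqs)))
  h %>%
    filter(.data$q != .data$s,
           .data$length >= min_overlap,
           .data$identity >= min_identity) %>%
    mutate(a = pmin(.data$q, .data$s), b = pmax(.data$q, .data$s)) %>%
    distinct(.data$a, .data$b) %>%
    select(q = "a", s = "b")
}

# Six-frame translation of fragments into stop-free peptide segments.
# Returns a tibble (fragment_idx, frame, segment) keeping segments of at
# least min_len residues. Frames are +1..+3 and -1..-3.
six_frame_segments <- function(seqs, min_len = 4L) {
  dna <- Biostrings::DNAStringSet(seqs)
  out <- list()
  for (dir in c(1L, -1L)) {
    x <- if (dir == 1L) dna else Biostrings::reverseComplement(dna)
    for (f in 1:3) {
      w <- Biostrings::width(x)
      keep <- which(w - f + 1L >= 3L)
      if (length(keep) == 0) next
      sub <- Biostrings::subseq(x[keep], start = f,
        width = ((Biostrings::width(x[keep]) - f + 1L) %/% 3L) * 3L)
      pep <- as.character(suppressWarnings(
        Biostrings::translate(sub, if.fuzzy.codon = "solve")))
      segs <- stringr::str_split(pep, stringr::fixed("*"))
      lens <- lengths(segs)
      out[[length(out) + 1]] <- tibble(
        fragment_idx = rep(keep, lens),
        frame = rep(dir * f, sum(lens)),
        segment = unlist(segs, use.names = FALSE))
    }
  }
  bind_rows(out) %>% filter(nchar(.data$segment) >= min_len)
}

# Protein-space search of peptide segments against a protein set, with
# BLOSUM62 scoring and Karlin-Altschul expectation values
# E = K * m * n * exp(-lambda * S), m the segment length and n the total
# database residues.
aa_search <- function(segments, proteins, word = 4L, xdrop = 20L) {
  sm <- aa_score_matrix()
  h <- seed_extend_search(segments$segment, proteins$seq, word, sm, xdrop,
                          coder = aa_kmer_codes)
  db_n <- sum(nchar(proteins$seq))
  if (nrow(h) == 0) {
    return(tibble(segment_idx = integer(), protein_id = character(),
                  score = integer(), evalue = double()))
  }
  h %>%
    mutate(
      segment_idx = .data$q,
      protein_id = proteins$id[.data$s],
      evalue = BLOSUM62_K * nchar(segments$segment)[.data$q] * db_n *
        exp(-BLOSUM62_LAMBDA * .data$score)) %>%
    select("segment_idx", "protein_id", "score", "evalue",
           "qstart", "qend", "sstart", "send")
}
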