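# Synthetic genome builder. Generates a random background at a target GC
# and plants three kinds of features at fixed positions: perfect SSRs,
# diverged copies of repeat-element templates, and in-frame encodings of
# protein fragments. Every planted feature is recorded in a 0-based,
# half-open feature table so downstream stages can be scored against
# ground truth.

#' Specify a synthetic genome
#'
#' @param length Genome length in bases.
#' @param gc_target Background GC fraction in `[0, 1]`.
#' @param planted_ssrs Tibble with columns `motif`, `copies`, `position`
#'   (0-based start), or `NULL`.
#' @param repeat_elements Tibble with columns `template_id`, `position`,
#'   `identity` (percent, 50-100), or `NULL`.
#' @param gene_fragments Tibble with columns `protein_id`, `position`,
#'   `frame` (positive for forward strand, negative for reverse), or
#'   `NULL`.
#' @param seed Integer seed; all randomness in [make_genome()] flows from
#'   it.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(length, gc_target = 0.35, planted_ssrs = NULL,
                        repeat_elements = NULL, gene_fragments = NULL,
                        seed = 1L) {
  stopifnot(length > 0, gc_target >= 0, gc_target <= 1)
  if (!is.null(repeat_elements) && nrow(repeat_elements) > 0) {
    if (any(repeat_elements$identity < 50 | repeat_elements$identity > 100)) {
      abort("repeat element identity must be in [50, 100] percent")
    }
  }
  structure(
    list(length = as.integer(length), gc_target = gc_target,
         planted_ssrs = planted_ssrs, repeat_elements = repeat_elements,
         gene_fragments = gene_fragments, seed = as.integer(seed)),
    class = "genome_spec")
}

CODON_TABLE <- local({
  codons <- do.call(paste0, expand.grid(
    rep(list(c("T", "C", "A", "G")), 3), stringsAsFactors = FALSE)[, 3:1])
  aa <- strsplit(Biostrings::GENETIC_CODE[codons], "")
  split(codons, unlist(aa))
})

# Reverse-translate a protein with uniformly chosen synonymous codons.
reverse_translate <- function(protein) {
  aas <- strsplit(protein, "")[[1]]
  paste(vapply(aas, function(a) {
    cods <- CODON_TABLE[[a]]
    if (is.null(cods)) abort(paste0("no codon for residue '", a, "'"))
    cods[sample.int(length(cods), 1)]
  }, character(1)), collapse = "")
}

# Mutate a sequence to an exact Hamming identity (percent).
diverge_seq <- function(seq, identity) {
  n <- nchar(seq)
  n_sub <- round((1 - identity / 100) * n)
  if (n_sub == 0) return(seq)
  pos <- sample.int(n, n_sub)
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- vapply(ch[pos], function(b) {
    sample(setdiff(DNA_BASES, b), 1)
  }, character(1))
  paste(ch, collapse = "")
}

#' Build a synthetic genome with planted features
#'
#' @param spec A [genome_spec()].
#' @param repeat_templates Tibble with `id`, `seq` for the repeat elements
#'   referenced by `spec` (headers may carry a `#class` suffix).
#' @param proteins Tibble with `id`, `seq` (amino acids) for the gene
#'   fragments referenced by `spec`.
#' @return List with `sequence` (one DNA string) and `features` (tibble
#'   `type`, `start`, `end`, `payload`; 0-based, half-open). Deterministic
#'   for a fixed `spec$seed`. Planted features must not overlap; the
#'   conflicting pair is named otherwise.
#' @export
make_genome <- function(spec, repeat_templates = NULL, proteins = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, {
    feats <- list()
    if (!is.null(spec$planted_ssrs) && nrow(spec$planted_ssrs) > 0) {
      ps <- spec$planted_ssrs
      feats[[length(feats) + 1]] <- tibble(
        type = "ssr",
        start = as.integer(ps$position),
        len = nchar(ps$motif) * as.integer(ps$copies),
        payload = paste0(ps$motif, "x", ps$copies),
        seq = strrep(toupper(ps$motif), ps$copies))
    }
    if (!is.null(spec$repeat_elements) && nrow(spec$repeat_elements) > 0) {
      re <- spec$repeat_elements
      tpl <- setNames(toupper(repeat_templates$seq), repeat_templates$id)
      if (!all(re$template_id %in% names(tpl))) {
        abort("repeat template not found in repeat_templates")
      }
      inserted <- vapply(seq_len(nrow(re)), function(i) {
        diverge_seq(tpl[[re$template_id[i]]], re$identity[i])
      }, character(1))
      feats[[length(feats) + 1]] <- tibble(
        type = "repeat",
        start = as.integer(re$position),
        len = nchar(inserted),
        payload = paste0(re$template_id, "@", re$identity),
        seq = inserted)
    }
    if (!is.null(spec$gene_fragments) && nrow(spec$gene_fragments) > 0) {
      gf <- spec$gene_fragments
      prot <- setNames(toupper(proteins$seq), proteins$id)
      if (!all(gf$protein_id %in% names(prot))) {
        abort("protein not found in proteins")
      }
      cds <- vapply(gf$protein_id, function(p) reverse_translate(prot[[p]]),
                    character(1), USE.NAMES = FALSE)
      cds <- ifelse(gf$frame < 0, revcomp(cds), cds)
      feats[[length(feats) + 1]] <- tibble(
        type = "gene",
        start = as.integer(gf$position),
        len = nchar(cds),
        payload = paste0(gf$protein_id, " frame ", gf$frame),
        seq = cds)
    }
    feats <- bind_rows(feats)
    if (nrow(feats) > 0) {
      feats <- mutate(feats, end = .data$start + .data$len)
      bad <- feats$start < 0 | feats$end > spec$length
      if (any(bad)) {
        abort(paste0("feature outside genome: ",
                     paste(feats$payload[bad], collapse = ", ")))
      }
      o <- order(feats$start)
      fo <- feats[o, ]
      if (nrow(fo) > 1) {
        clash <- which(fo$start[-1] < head(fo$end, -1))
        if (length(clash) > 0) {
          abort(paste0("planted features overlap: '",
                       fo$payload[clash[1]], "' and '",
                       fo$payload[clash[1] + 1], "'"))
        }
      }
    }
    genome <- random_dna(spec$length, spec$gc_target)
    if (nrow(feats) > 0) {
      for (i in seq_len(nrow(feats))) {
        stringr::str_sub(genome, feats$start[i] + 1L, feats$end[i]) <-
          feats$seq[i]
      }
    }
    features <- if (nrow(feats) > 0) {
      select(feats, "type", "start", "end", "payload")
    } else {
      tibble(type = character(), start = integer(), end = integer(),
             payload = character())
    }
    list(sequence = genome, features = features)
  })
}
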