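# Sequence file I/O. Tibbles are the working representation; Biostrings
# handles the on-disk formats (FASTA, 4-line Sanger FASTQ).

#' Read and write FASTA as a tibble
#'
#' `read_fasta_tbl()` returns a tibble with columns `id` (the full header up
#' to the first space) and `seq`. `write_fasta_tbl()` writes one back,
#' unwrapped, and returns the input invisibly so it can sit inside a pipe.
#'
#' Repeat libraries use a `"#class"` suffix convention in their headers
#' (e.g. `rep1#Gypsy`); the suffix is kept as part of `id` and split later
#' by [classify_repeats()].
#'
#' @param path File path.
#' @param x Tibble with columns `id` and `seq`.
#' @return A tibble (`read_fasta_tbl`) or the input, invisibly.
#' @export
read_fasta_tbl <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  tibble(
    id = stringr::str_split_i(names(ss), " ", 1),
    seq = unname(toupper(as.character(ss)))
  )
}

#' @rdname read_fasta_tbl
#' @export
write_fasta_tbl <- function(x, path) {
  ss <- Biostrings::BStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(ss, path, width = 20000L)
  invisible(x)
}

#' Read and write paired FASTQ as a read-pair tibble
#'
#' Read pairs are represented as a tibble with columns `id`, `seq1`, `qual1`,
#' `seq2`, `qual2`; qualities are Sanger Phred+33 strings, one character per
#' base. `write_fastq_pair()` writes two 4-line-record FASTQ files with `/1`
#' and `/2` mate suffixes.
#'
#' @param path1,path2 Mate 1 and mate 2 FASTQ paths.
#' @param x A read-pair tibble.
#' @return A read-pair tibble (`read_fastq_pair`) or the input, invisibly.
#' @export
read_fastq_pair <- function(path1, path2) {
  read_qss <- function(p) {
    # Biostrings warns about dropping (empty) metadata columns here
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(p))
  }
  r1 <- read_qss(path1)
  r2 <- read_qss(path2)
  stopifnot(length(r1) == length(r2))
  tibble(
    id = stringr::str_remove(stringr::str_split_i(names(r1), " ", 1), "/[12]$"),
    seq1 = as.character(r1), qual1 = as.character(Biostrings::quality(r1)),
    seq2 = as.character(r2), qual2 = as.character(Biostrings::quality(r2))
  )
}

#' @rdname read_fastq_pair
#' @export
write_fastq_pair <- function(x, path1, path2) {
  write_one <- function(ids, seqs, quals, path) {
    rec <- paste0("@", ids, "\n", seqs, "\n+\n", quals)
    writeLines(rec, path)
  }
  write_one(paste0(x$id, "/1"), x$seq1, x$qual1, path1)
  write_one(paste0(x$id, "/2"), x$seq2, x$qual2, path2)
  invisible(x)
}

write_stage_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}
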