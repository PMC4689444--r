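test_that("background composition matches the GC target", {
  g <- make_genome(genome_spec(1000, gc_target = 0.5, seed = 1))
  expect_equal(nchar(g$sequence), 1000L)
  expect_lt(abs(gc_content(g$sequence) - 50), 5)
  g35 <- make_genome(genome_spec(20000, gc_target = 0.35, seed = 2))
  expect_lt(abs(gc_content(g35$sequence) - 35), 1)
})

test_that("planted SSRs appear verbatim at their positions", {
  g <- make_genome(genome_spec(
    1000, planted_ssrs = tibble::tibble(motif = "AT", copies = 8,
                                        position = 100), seed = 1))
  expect_equal(substr(g$sequence, 101, 116), strrep("AT", 8))
  expect_equal(g$features$start, 100L)
  expect_equal(g$features$end, 116L)
  expect_equal(g$features$type, "ssr")
})

test_that("repeat insertions hit the requested divergence exactly", {
  withr::with_seed(3, {
    tpl <- tibble::tibble(id = "r1#Gypsy", seq = rand_dna(300))
    g <- make_genome(genome_spec(
      2000, repeat_elements = tibble::tibble(
        template_id = "r1#Gypsy", position = 500, identity = 85),
      seed = 4), repeat_templates = tpl)
    inserted <- substr(g$sequence, 501, 800)
    mm <- sum(strsplit(inserted, "")[[1]] != strsplit(tpl$seq, "")[[1]])
    expect_equal(mm, round(0.15 * 300))
  })
})

test_that("overlapping planted features are rejected with the pair named", {
  spec <- genome_spec(1000, planted_ssrs = tibble::tibble(
    motif = c("AT", "AG"), copies = c(10, 10), position = c(100, 110)))
  expect_error(make_genome(spec), "overlap.*ATx10.*AGx10")
  out_of_range <- genome_spec(100, planted_ssrs = tibble::tibble(
    motif = "AT", copies = 10, position = 90))
  expect_error(make_genome(out_of_range), "outside")
})

test_that("gene fragments encode their protein in the requested frame", {
  withr::with_seed(5, {
    prot <- tibble::tibble(id = "p1", seq = rand_protein(50))
    for (frame in c(1, -1)) {
      g <- make_genome(genome_spec(
        1000, gene_fragments = tibble::tibble(
          protein_id = "p1", position = 300, frame = frame), seed = 6),
        proteins = prot)
      cds <- substr(g$sequence, 301, 450)
      if (frame < 0) cds <- revcomp(cds)
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
      expect_equal(aa, prot$seq)
    }
  })
})

test_that("read pairs have the documented overlap and read-through geometry", {
  withr::with_seed(7, {
    genome <- rand_dna(5000)
    # force fragment length 180: sd 0
    pr <- simulate_reads(genome, read_sim_spec(
      n_pairs = 20, fragment_mean = 180, fragment_sd = 0, seed = 8))
    truth <- attr(pr, "truth")
    expect_true(all(truth$frag_len == 180))
    out <- merge_pairs(pr)
    expect_true(all(out$overlap_len == 22L))
    # fragment length 90 < read length: adapter read-through at cycle 91
    pr90 <- simulate_reads(genome, read_sim_spec(
      n_pairs = 10, fragment_mean = 90, fragment_sd = 0, seed = 9))
    expect_true(all(substr(pr90$seq1, 91, 101) ==
                      substr(default_adapter(), 1, 11)))
    expect_true(all(substr(pr90$seq2, 91, 101) ==
                      substr(default_adapter(), 1, 11)))
  })
})

test_that("reads map back to the genome with exactly the errors drawn", {
  withr::with_seed(10, {
    genome <- rand_dna(20000)
    pr <- simulate_reads(genome, read_sim_spec(
      n_pairs = 200, error_rate = 0.01, seed = 11))
    truth <- attr(pr, "truth")
    ok <- !truth$is_artifact & truth$frag_len >= 101
    frag <- substr(rep(genome, sum(ok)), truth$start[ok] + 1,
                   truth$start[ok] + truth$frag_len[ok])
    m1_true <- substr(frag, 1, 101)
    m2_true <- substr(revcomp(frag), 1, 101)
    mm <- function(a, b) {
      mapply(function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]),
             a, b, USE.NAMES = FALSE)
    }
    expect_equal(mm(pr$seq1[ok], m1_true), truth$n_err1[ok])
    expect_equal(mm(pr$seq2[ok], m2_true), truth$n_err2[ok])
  })
})

test_that("the artifact rate is respected and detected by the tail rule", {
  withr::with_seed(12, {
    genome <- rand_dna(50000)
    pr <- simulate_reads(genome, read_sim_spec(
      n_pairs = 10000, artifact_pair_rate = 0.1, seed = 13))
    flagged <- flag_artifact_pairs(pr)
    expect_lt(abs(mean(flagged$artifact) - 0.10), 0.01)
    expect_equal(flagged$artifact, attr(pr, "truth")$is_artifact)
  })
})

test_that("a fixed seed reproduces byte-identical FASTQ", {
  withr::with_seed(14, {
    genome <- rand_dna(10000)
    spec <- read_sim_spec(n_pairs = 50, artifact_pair_rate = 0.05,
                          low_qual_tail_rate = 0.1, error_rate = 0.01,
                          seed = 15)
    p1 <- withr::local_tempfile()
    p2 <- withr::local_tempfile()
    p3 <- withr::local_tempfile()
    p4 <- withr::local_tempfile()
    write_fastq_pair(simulate_reads(genome, spec), p1, p2)
    write_fastq_pair(simulate_reads(genome, spec), p3, p4)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p3, "raw", file.size(p3)))
    expect_identical(readBin(p2, "raw", file.size(p2)),
                     readBin(p4, "raw", file.size(p4)))
  })
})

test_that("invalid simulation parameters are rejected", {
  expect_error(read_sim_spec(n_pairs = 0), "positive")
  expect_error(read_sim_spec(n_pairs = 10, artifact_pair_rate = 1.5))
  expect_error(simulate_reads(rand_dna(50), read_sim_spec(n_pairs = 5)),
               "shorter")
})

test_that("planted SSRs are recoverable from the genome by the scanner", {
  withr::with_seed(16, {
    plants <- tibble::tibble(
      motif = c("AT", "AG", "AAT", "AAG", "ATCC"),
      copies = c(10, 9, 8, 7, 6),
      position = c(1000, 2000, 3000, 4000, 5000))
    g <- make_genome(genome_spec(10000, planted_ssrs = plants, seed = 17))
    loci <- find_perfect_ssrs(tibble::tibble(id = "g", seq = g$sequence))
    for (i in seq_len(nrow(plants))) {
      # flank bases can extend the run and shift the reported phase by up
      # to period - 1 bases in either direction
      p <- nchar(plants$motif[i])
      s <- plants$position[i]
      e <- s + p * plants$copies[i]
      hit <- loci[loci$start <= s + p & loci$end >= e - p &
                    loci$copies >= plants$copies[i], ]
      expect_equal(nrow(hit), 1L, label = plants$motif[i])
      expect_equal(hit$canonical_motif, canonical_motif(plants$motif[i]))
    }
  })
})
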