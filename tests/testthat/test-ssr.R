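test_that("copy-number windows are inclusive at the printed bounds", {
  withr::with_seed(42, {
    cases <- list(
      list("AT", 7, 0L), list("AT", 8, 1L), list("AT", 40, 1L),
      list("AT", 41, 0L),
      list("ATC", 6, 0L), list("ATC", 7, 1L), list("ATC", 30, 1L),
      list("ATC", 31, 0L),
      list("AGTC", 5, 0L), list("AGTC", 6, 1L), list("AGTC", 20, 1L),
      list("AGTC", 21, 0L))
    for (cs in cases) {
      frag <- tibble::tibble(id = "f", seq = ssr_fragment(cs[[1]], cs[[2]]))
      loci <- find_perfect_ssrs(frag)
      expect_equal(nrow(loci), cs[[3]],
                   label = paste0(cs[[1]], "x", cs[[2]]))
      if (cs[[3]] == 1L) {
        expect_equal(loci$copies, cs[[2]])
        expect_equal(loci$start, 20L)
        expect_equal(loci$end - loci$start, nchar(cs[[1]]) * cs[[2]])
      }
    }
  })
})

test_that("reported loci satisfy the locus invariants", {
  withr::with_seed(7, {
    frags <- tibble::tibble(
      id = paste0("f", 1:300),
      seq = replicate(300, rand_dna(300, gc = runif(1, 0.2, 0.6))))
    frags$seq[1:60] <- vapply(1:60, function(i) {
      paste0(rand_dna(40), strrep(sample(c("AT", "AAG", "ATCC"), 1),
                                  sample(8:12, 1)), rand_dna(40))
    }, character(1))
    loci <- find_perfect_ssrs(frags)
    expect_gt(nrow(loci), 0)
    expect_true(all(loci$end - loci$start == loci$period * loci$copies))
    win <- ssr_copy_windows()
    for (i in seq_len(nrow(loci))) {
      w <- win[win$period == loci$period[i], ]
      expect_gte(loci$copies[i], w$min_copies)
      expect_lte(loci$copies[i], w$max_copies)
      frag_seq <- frags$seq[frags$id == loci$fragment_id[i]]
      span <- substr(frag_seq, loci$start[i] + 1, loci$end[i])
      expect_equal(span, strrep(loci$motif[i], loci$copies[i]))
      expect_false(gssr:::is_reducible_motif(loci$motif[i]))
    }
  })
})

test_that("miner agrees with the brute-force per-start oracle", {
  withr::with_seed(99, {
    n_frag <- 150
    seqs <- c(
      replicate(n_frag - 30, rand_dna(300, gc = runif(1, 0.25, 0.65))),
      # adversarial: planted repeats, N breaks, junction phases
      replicate(10, paste0(rand_dna(30), strrep("TA", sample(8:41, 1)),
                           rand_dna(30))),
      replicate(10, paste0(rand_dna(20), strrep("CAT", 9), "N",
                           strrep("GA", 9), rand_dna(20))),
      replicate(10, paste0("A", strrep("AT", 10), "ATA", rand_dna(25))))
    frags <- tibble::tibble(id = paste0("f", seq_along(seqs)), seq = seqs)
    mined <- find_perfect_ssrs(frags)
    for (i in seq_along(seqs)) {
      got <- mined[mined$fragment_id == frags$id[i],
                   c("start", "end", "period", "motif", "copies")]
      want <- oracle_ssrs(seqs[i])
      got <- got[order(got$period, got$start), ]
      want <- want[order(want$period, want$start), ]
      expect_equal(as.data.frame(got), want, ignore_attr = TRUE,
                   label = paste("fragment", i))
    }
  })
})

test_that("flank filter enforces the minimum and N-free flanks", {
  withr::with_seed(1, {
    for (fl in c(10, 14, 15, 20)) {
      frag <- tibble::tibble(id = "f", seq = ssr_fragment("AT", 10, flank = fl))
      loci <- find_perfect_ssrs(frag)
      kept <- apply_flank_and_compound_filters(loci, frag, min_flank = 15)
      expect_equal(nrow(kept), as.integer(fl >= 15), label = paste("flank", fl))
    }
    # N inside an otherwise long-enough flank invalidates the locus
    frag <- tibble::tibble(id = "f", seq = ssr_fragment("AT", 10, flank = 20))
    seqN <- frag$seq
    substr(seqN, 10, 10) <- "N"
    fragN <- tibble::tibble(id = "f", seq = seqN)
    lociN <- find_perfect_ssrs(fragN)
    expect_equal(nrow(apply_flank_and_compound_filters(lociN, fragN)), 0L)
  })
})

test_that("adjacent loci with different motifs are removed as compound", {
  withr::with_seed(5, {
    mk <- function(gap) {
      tibble::tibble(id = "f", seq = paste0(
        rand_dna(30), strrep("AT", 9), rand_dna(gap), strrep("AG", 9),
        rand_dna(30)))
    }
    near <- mk(5)
    loci_near <- find_perfect_ssrs(near)
    expect_equal(nrow(loci_near), 2L)
    expect_equal(nrow(apply_flank_and_compound_filters(loci_near, near)), 0L)
    far <- mk(40)
    loci_far <- find_perfect_ssrs(far)
    expect_equal(nrow(apply_flank_and_compound_filters(loci_far, far)), 2L)
    # immediately adjacent runs: both removed
    adj <- tibble::tibble(id = "f", seq = paste0(
      rand_dna(30), strrep("AT", 9), strrep("AG", 9), rand_dna(30)))
    loci_adj <- find_perfect_ssrs(adj)
    expect_equal(nrow(apply_flank_and_compound_filters(loci_adj, adj)), 0L)
  })
})

test_that("near-identical SSR fragments collapse to one representative", {
  withr::with_seed(21, {
    base <- ssr_fragment("AAG", 9, flank = 60)  # 147 bases
    mutate_at <- function(s, k) {
      pos <- sample(seq_len(60), k)  # confine mismatches to the left flank
      ch <- strsplit(s, "")[[1]]
      ch[pos] <- vapply(ch[pos], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
      paste(ch, collapse = "")
    }
    # 2 mismatches over 147 bases: ~98.6% identity -> one cluster
    frags <- tibble::tibble(id = c("a", "b"),
                            seq = c(base, mutate_at(base, 2)))
    loci <- apply_flank_and_compound_filters(find_perfect_ssrs(frags), frags)
    got <- collapse_loci(loci, frags)
    expect_equal(nrow(got), 1L)
    expect_equal(got$cluster_size, 2L)
    # ~90% identity over the alignable span -> two clusters
    far <- tibble::tibble(id = c("a", "b"),
                          seq = c(base, mutate_at(base, 15)))
    loci2 <- apply_flank_and_compound_filters(find_perfect_ssrs(far), far)
    got2 <- collapse_loci(loci2, far)
    expect_equal(nrow(got2), 2L)
    # n identical copies -> one cluster with n members
    n <- 6
    many <- tibble::tibble(id = paste0("c", 1:n), seq = rep(base, n))
    loci3 <- apply_flank_and_compound_filters(find_perfect_ssrs(many), many)
    got3 <- collapse_loci(loci3, many)
    expect_equal(nrow(got3), 1L)
    expect_equal(got3$cluster_size, n)
  })
})

test_that("density and frequency statistics are exact", {
  loci <- tibble::tibble(
    fragment_id = paste0("f", 1:10), start = 0L, end = 20L, period = 2L,
    motif = "AT", canonical_motif = "AT", copies = 10L,
    left_flank = 20L, right_flank = 20L)
  st <- ssr_statistics(loci, 500000)
  expect_equal(glance(st)$loci_per_mb, 20)
  expect_equal(tidy(st)$percent, 100L)
  expect_error(ssr_statistics(loci, 0), "positive")
  # largest-remainder rounding: percentages sum to 100 within each period
  loci2 <- loci
  loci2$canonical_motif <- rep(c("AT", "AG", "AC"), c(4, 3, 3))
  st2 <- ssr_statistics(loci2, 1e6)
  expect_equal(sum(tidy(st2)$percent), 100L)
  # density is invariant under fragment order
  st3 <- ssr_statistics(loci[sample(1:10), ], 500000)
  expect_equal(glance(st3)$loci_per_mb, glance(st)$loci_per_mb)
})
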