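q38 <- function(n) strrep(rawToChar(as.raw(38 + 33)), n)

test_that("clean high-quality reads pass trimming unchanged", {
  withr::with_seed(2, {
    pr <- pair_from_fragment(rand_dna(180))
    out <- trim_pairs(pr)
    expect_equal(out$seq1, pr$seq1)
    expect_equal(out$seq2, pr$seq2)
    tally <- attr(out, "tally")
    expect_equal(tally$n[tally$reason == "kept"], 1L)
  })
})

test_that("adapter occurrences clip the read from the match start", {
  withr::with_seed(3, {
    ad <- default_adapter()
    read <- paste0(rand_dna(60), substr(ad, 1, 41))
    pr <- tibble::tibble(id = "p", seq1 = read, qual1 = q38(101),
                         seq2 = rand_dna(101), qual2 = q38(101))
    out <- trim_pairs(pr)
    expect_equal(nchar(out$seq1), 60L)
    # two mismatches within the adapter still clip
    ad_mm <- ad
    substr(ad_mm, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                   substr(ad_mm, 3, 3))[1]
    substr(ad_mm, 8, 8) <- setdiff(c("A", "C", "G", "T"),
                                   substr(ad_mm, 8, 8))[1]
    read2 <- paste0(rand_dna(60), substr(ad_mm, 1, 41))
    pr2 <- tibble::tibble(id = "p", seq1 = read2, qual1 = q38(101),
                          seq2 = rand_dna(101), qual2 = q38(101))
    out2 <- trim_pairs(pr2)
    expect_equal(nchar(out2$seq1), 60L)
    # a trailing adapter fragment shorter than the seed is left alone
    read3 <- paste0(rand_dna(95), substr(ad, 1, 6))
    pr3 <- tibble::tibble(id = "p", seq1 = read3, qual1 = q38(101),
                          seq2 = rand_dna(101), qual2 = q38(101))
    out3 <- trim_pairs(pr3)
    expect_equal(nchar(out3$seq1), 101L)
  })
})

test_that("sliding-window quality truncation cuts at the first bad window", {
  withr::with_seed(4, {
    # Q38 for 51 bases then Q2: a window of 4 has mean < 15 once it holds
    # at most one Q38 base, so the first bad window starts at base 51
    # (1-based) and the read keeps 50 bases
    qual <- paste0(q38(51), strrep(rawToChar(as.raw(2 + 33)), 50))
    pr <- tibble::tibble(id = "p", seq1 = rand_dna(101), qual1 = qual,
                         seq2 = rand_dna(101), qual2 = q38(101))
    out <- trim_pairs(pr)
    expect_equal(nchar(out$seq1), 50L)
    expect_equal(nchar(out$qual1), 50L)
  })
})

test_that("pairs with a mate under the minimum length are discarded whole", {
  withr::with_seed(5, {
    # mate 1 cut to 35 bases by quality -> whole pair discarded
    qual <- paste0(q38(36), strrep(rawToChar(as.raw(2 + 33)), 65))
    pr <- tibble::tibble(id = "p", seq1 = rand_dna(101), qual1 = qual,
                         seq2 = rand_dna(101), qual2 = q38(101))
    out <- trim_pairs(pr)
    expect_equal(nrow(out), 0L)
    tally <- attr(out, "tally")
    expect_equal(tally$n[tally$reason == "mate_too_short"], 1L)
    # one more high-quality base keeps 36 and the pair survives
    qual36 <- paste0(q38(37), strrep(rawToChar(as.raw(2 + 33)), 64))
    pr36 <- tibble::tibble(id = "p", seq1 = rand_dna(101), qual1 = qual36,
                           seq2 = rand_dna(101), qual2 = q38(101))
    kept <- trim_pairs(pr36)
    expect_equal(nrow(kept), 1L)
    expect_equal(nchar(kept$seq1), 36L)
  })
})

test_that("trimming never lengthens a read and tallies partition the input", {
  withr::with_seed(6, {
    g <- make_genome(genome_spec(20000, seed = 8))
    pr <- simulate_reads(g$sequence, read_sim_spec(
      n_pairs = 300, low_qual_tail_rate = 0.3, error_rate = 0.01, seed = 9))
    out <- trim_pairs(pr)
    kept <- pr[pr$id %in% out$id, ]
    expect_true(all(nchar(out$seq1) <= nchar(kept$seq1)))
    expect_true(all(nchar(out$seq2) <= nchar(kept$seq2)))
    expect_true(all(nchar(out$seq1) == nchar(out$qual1)))
    tally <- attr(out, "tally")
    expect_equal(sum(tally$n), nrow(pr))
  })
})

test_that("the identical-tail rule flags artifacts at exactly 30 bases", {
  withr::with_seed(7, {
    tail30 <- rand_dna(30)
    same <- tibble::tibble(id = "a", seq1 = paste0(rand_dna(71), tail30),
                           qual1 = q38(101),
                           seq2 = paste0(rand_dna(71), tail30),
                           qual2 = q38(101))
    expect_true(flag_artifact_pairs(same)$artifact)
    # identical over only the last 29: position -30 differs
    t1 <- paste0("A", substr(tail30, 2, 30))
    t2 <- paste0("C", substr(tail30, 2, 30))
    near <- tibble::tibble(id = "b", seq1 = paste0(rand_dna(71), t1),
                           qual1 = q38(101),
                           seq2 = paste0(rand_dna(71), t2),
                           qual2 = q38(101))
    expect_false(flag_artifact_pairs(near)$artifact)
    # a proper overlapping pair is not flagged
    proper <- pair_from_fragment(rand_dna(180), id = "c")
    expect_false(flag_artifact_pairs(proper)$artifact)
    # N in the tail matches nothing
    tailN <- paste0(substr(tail30, 1, 29), "N")
    withN <- tibble::tibble(id = "d", seq1 = paste0(rand_dna(71), tailN),
                            qual1 = q38(101),
                            seq2 = paste0(rand_dna(71), tailN),
                            qual2 = q38(101))
    expect_false(flag_artifact_pairs(withN)$artifact)
    # short mates cannot be evaluated
    short <- tibble::tibble(id = "e", seq1 = rand_dna(20), qual1 = q38(20),
                            seq2 = rand_dna(40), qual2 = q38(40))
    out <- flag_artifact_pairs(short)
    expect_false(out$artifact)
    expect_equal(attr(out, "n_unevaluable"), 1L)
  })
})

test_that("error-free mates from a 180-base fragment merge at overlap 22", {
  withr::with_seed(8, {
    frag <- rand_dna(180)
    out <- merge_pairs(pair_from_fragment(frag))
    expect_equal(nrow(out), 1L)
    expect_equal(out$origin, "merged")
    expect_equal(out$overlap_len, 22L)
    expect_equal(nchar(out$seq), 180L)
    expect_equal(out$seq, frag)
  })
})

test_that("pairs without sufficient overlap emit both mates unmerged", {
  withr::with_seed(9, {
    frag <- rand_dna(400)
    out <- merge_pairs(pair_from_fragment(frag))
    expect_equal(nrow(out), 2L)
    expect_setequal(out$origin, c("unmerged_mate1", "unmerged_mate2"))
    expect_true(all(is.na(out$overlap_len)))
  })
})

test_that("the mismatch-ratio threshold separates merge from non-merge", {
  withr::with_seed(10, {
    # fragment of 100, mates of 60: true overlap 20
    mk <- function(n_mm) {
      repeat {
        frag <- rand_dna(100)
        m1 <- substr(frag, 1, 60)
        m2rc <- substr(frag, 41, 100)
        # inject mismatches into mate2's copy of the overlap (positions
        # 41..60 of the fragment = 1..20 of m2rc)
        ch <- strsplit(m2rc, "")[[1]]
        pos <- sample(1:20, n_mm)
        ch[pos] <- vapply(ch[pos], function(b) {
          setdiff(c("A", "C", "G", "T"), b)[1]
        }, character(1))
        m2rc_mm <- paste(ch, collapse = "")
        pr <- tibble::tibble(id = "p", seq1 = m1, qual1 = q38(60),
                             seq2 = gssr::revcomp(m2rc_mm), qual2 = q38(60))
        out <- merge_pairs(pr)
        # only accept constructions where the intended overlap is the best
        if (nrow(out) == 1 && !is.na(out$overlap_len) &&
            out$overlap_len == 20L) return(out)
        if (n_mm == 6 && nrow(out) == 2) return(out)
      }
    }
    merged <- mk(4)   # ratio 0.20 <= 0.25
    expect_equal(merged$origin, "merged")
    unmerged <- mk(6) # ratio 0.30 > 0.25
    expect_equal(nrow(unmerged), 2L)
  })
})

test_that("disagreeing overlap bases resolve to the higher-quality mate", {
  withr::with_seed(40, frag <- rand_dna(100))
  m1 <- substr(frag, 1, 60)
  m2rc <- substr(frag, 41, 100)
  # corrupt position 5 of the overlap (fragment position 45) in mate 1
  ch <- strsplit(m1, "")[[1]]
  truth <- ch[45]
  ch[45] <- setdiff(c("A", "C", "G", "T"), c(truth))[1]
  m1_bad <- paste(ch, collapse = "")
  q1 <- paste0(q38(44), rawToChar(as.raw(10 + 33)), q38(15))  # low q at 45
  pr <- tibble::tibble(id = "p", seq1 = m1_bad, qual1 = q1,
                       seq2 = gssr::revcomp(m2rc), qual2 = q38(60))
  out <- merge_pairs(pr)
  expect_equal(out$origin, "merged")
  expect_equal(substr(out$seq, 45, 45), truth)
})

test_that("merged length equals len1 + len2 - overlap on simulated data", {
  withr::with_seed(11, {
    g <- make_genome(genome_spec(50000, seed = 12))
    pr <- simulate_reads(g$sequence, read_sim_spec(n_pairs = 400, seed = 13))
    tr <- trim_pairs(pr)
    fr <- merge_pairs(tr)
    m <- fr[fr$origin == "merged", ]
    lens <- tibble::tibble(id = tr$id, l1 = nchar(tr$seq1),
                           l2 = nchar(tr$seq2))
    j <- merge(m, lens, by.x = "pair_id", by.y = "id")
    expect_true(all(nchar(j$seq) == j$l1 + j$l2 - j$overlap_len))
    # merged fragments reproduce the genome fragment exactly whenever the
    # true overlap reaches min_overlap (longer fragments can only merge
    # through a chance overlap, which need not match the source)
    truth <- attr(pr, "truth")
    jt <- merge(m, truth, by.x = "pair_id", by.y = "id")
    jt <- jt[jt$frag_len <= 2 * 101 - 10, ]
    src <- substr(rep(g$sequence, nrow(jt)), jt$start + 1,
                  jt$start + jt$frag_len)
    expect_gt(nrow(jt), 100)
    expect_equal(mean(jt$seq == src), 1)
    # short-fragment geometry merges far more often than long
    long_pr <- simulate_reads(g$sequence, read_sim_spec(
      n_pairs = 400, fragment_mean = 400, fragment_sd = 25, seed = 14))
    long_fr <- merge_pairs(trim_pairs(long_pr))
    expect_gt(mean(fr$origin == "merged"),
              mean(long_fr$origin == "merged") + 0.3)
  })
})
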