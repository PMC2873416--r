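test_that("segregating sites match inspection and a per-column oracle", {
  aln <- make_aln(c("AAAA", "AAAA", "AAAA"))
  expect_equal(segregating_sites(aln, "wild")$S, 0L)

  aln <- make_aln(c("AAAA", "AAAT", "AATT"))
  ss <- segregating_sites(aln, "wild")
  expect_equal(ss$S, 2L)
  expect_equal(ss$L_eff, 4L)

  expect_error(segregating_sites(make_aln("ACGT"), "wild"),
               "insufficient-sample")

  r <- random_aln(20, 200, seed = 3, p_missing = 0.02)
  expect_equal(segregating_sites(r, "wild")$S, oracle_S(r, "wild"))
})

test_that("nucleotide diversity equals the brute-force pairwise average", {
  expect_equal(nucleotide_diversity(make_aln(c("ACGT", "ACGT")), "wild"), 0)
  aln <- make_aln(c("AAAA", "AAAT", "AATT"))
  expect_equal(nucleotide_diversity(aln, "wild"), (4 / 3) / 4,
               tolerance = 1e-12)
  for (seed in 1:4) {
    r <- random_aln(12, 150, seed = seed, p_missing = 0.03)
    expect_equal(nucleotide_diversity(r, "wild"), oracle_pi(r, "wild"),
                 tolerance = 1e-12)
  }
})

test_that("Watterson's theta follows S/(a1*L) and collapses to pi at n=2", {
  aln <- make_aln(c("AAAA", "AAAA"))
  expect_equal(watterson_theta(aln, "wild"), 0)
  # n=4, L=100, S=3
  seqs <- c(paste0(c("T", rep("A", 99)), collapse = ""),
            paste0(c("A", "T", rep("A", 98)), collapse = ""),
            paste0(c("A", "A", "T", rep("A", 97)), collapse = ""),
            paste0(rep("A", 100), collapse = ""))
  aln4 <- make_aln(seqs)
  expect_equal(watterson_theta(aln4, "wild"), 3 / ((1 + 1/2 + 1/3) * 100),
               tolerance = 1e-9)
  r <- random_aln(2, 200, seed = 9)
  expect_equal(watterson_theta(r, "wild"), nucleotide_diversity(r, "wild"),
               tolerance = 1e-12)
})

test_that("Tajima's D matches the independent constants formula", {
  aln0 <- make_aln(c("AAAA", "AAAA", "AAAA"))
  expect_true(is.na(tajimas_d(aln0, "wild")))

  seqs <- c(paste0(c("T", rep("A", 99)), collapse = ""),
            paste0(c("A", "T", rep("A", 98)), collapse = ""),
            paste0(c("A", "A", "T", rep("A", 97)), collapse = ""),
            paste0(rep("A", 100), collapse = ""))
  aln4 <- make_aln(seqs)
  d <- tajimas_d(aln4, "wild")
  expect_equal(d, oracle_tajima_d(1.5, 3, 4), tolerance = 1e-12)
  expect_equal(d, -0.754451, tolerance = 1e-5)
  expect_error(tajimas_d(make_aln(c("AC", "AG")), "wild"),
               "insufficient-sample")

  for (seed in 5:7) {
    r <- random_aln(9, 120, seed = seed, p_missing = 0.02)
    keep <- r$samples
    m <- r$seq[keep, colSums(r$seq == "-" | r$seq == "N") == 0, drop = FALSE]
    tot <- 0
    for (i in 1:8) for (j in (i + 1):9) tot <- tot + sum(m[i, ] != m[j, ])
    pi_tot <- tot / choose(9, 2)
    S <- oracle_S(r, "wild")
    expect_equal(tajimas_d(r, "wild"), oracle_tajima_d(pi_tot, S, 9),
                 tolerance = 1e-10)
  }
})

test_that("bootstrap Tajima's D test is seeded and calibrated on its null", {
  scn <- sim_scenario(n_wild = 12, n_japonica = 0, n_indica = 0, L = 800,
                      theta = 6, wild_split_time = 0, seed = 21L)
  aln <- simulate_locus(scn, include_outgroup = FALSE)$aln
  t1 <- tajima_d_test(aln, "wild", reps = 300, seed = 4)
  t2 <- tajima_d_test(aln, "wild", reps = 300, seed = 4)
  expect_identical(t1, t2)
  expect_true(t1$p_lower >= 0 && t1$p_lower <= 1)
  # a neutral draw should rarely be extreme
  expect_gt(t1$p_two, 0.001)
})

test_that("sliding windows tile correctly and match slice recomputation", {
  r <- random_aln(10, 1000, seed = 13, p_missing = 0.01)
  w1 <- sliding_windows(r, "wild", window = 1000, step = 10, stat = "pi")
  expect_equal(nrow(w1), 1L)
  w2 <- sliding_windows(r, "wild", window = 100, step = 100, stat = "pi")
  expect_equal(nrow(w2), 10L)
  expect_equal(w2$window_start, seq(1, 901, by = 100))
  expect_equal(w2$window_end, seq(100, 1000, by = 100))
  # each window value equals the full statistic on the sliced alignment
  for (k in c(1, 4, 10)) {
    sub <- locus_alignment(r$seq[, w2$window_start[k]:w2$window_end[k]],
                           samples = r$samples, populations = r$populations)
    expect_equal(w2$value[k], nucleotide_diversity(sub, "wild"),
                 tolerance = 1e-12)
  }
  expect_error(sliding_windows(r, "wild", window = 2000, step = 10),
               "config error")
  # coordinate offset shifts reported bounds
  r2 <- random_aln(4, 300, seed = 2)
  r2$coordinate_offset <- 501L
  w3 <- sliding_windows(r2, "wild", window = 100, step = 100, stat = "S")
  expect_equal(w3$window_start[1], 501)
})

test_that("haplotype typing orders types by size and computes diversity", {
  aln <- make_aln(rep("ACGTACGT", 5))
  h <- haplotype_classify(aln)
  expect_equal(h$hap_count, 1L)
  expect_equal(h$hap_div, 0)

  aln2 <- make_aln(c(x1 = "AAAA", x2 = "AAAA", y1 = "AAAT", y2 = "AAAT",
                     z1 = "ATTT"))
  h2 <- haplotype_classify(aln2)
  expect_equal(h2$hap_count, 3L)
  expect_equal(vapply(h2$types, length, 1L),
               c(type1 = 2L, type2 = 2L, type3 = 1L))
  expect_equal(h2$hap_div, 5 * (1 - (0.16 + 0.16 + 0.04)) / 4,
               tolerance = 1e-12)
  # tie between the two size-2 types broken by first occurrence
  expect_equal(sort(h2$types$type1), c("x1", "x2"))

  # permuting input order never changes the partition
  perm <- c("z1", "y2", "x1", "y1", "x2")
  aln3 <- make_aln(setNames(c("ATTT", "AAAT", "AAAA", "AAAT", "AAAA"), perm))
  h3 <- haplotype_classify(aln3)
  part2 <- vapply(h2$types, function(x) paste(sort(x), collapse = ","), "")
  part3 <- vapply(h3$types, function(x) paste(sort(x), collapse = ","), "")
  expect_true(setequal(part2, part3))
})

test_that("pi is invariant to sample order and to population pooling labels", {
  r <- random_aln(10, 200, seed = 17, p_missing = 0.02)
  ord <- sample(r$samples)
  r2 <- locus_alignment(r$seq[ord, ], samples = ord,
                        populations = r$populations[ord])
  expect_equal(nucleotide_diversity(r, "wild"),
               nucleotide_diversity(r2, "wild"), tolerance = 1e-12)
})

test_that("near-fixed differences honor the frequency threshold", {
  pops <- c(rep("japonica", 4), rep("wild", 4))
  aln <- make_aln(c("TTAA", "TTAA", "TTAA", "TTAA",
                    "GTAA", "GTAA", "GTAA", "GTAA"), pops)
  fd <- fixed_differences(aln, "japonica", "wild", freq_threshold = 1.0)
  expect_equal(fd$site, 1L)
  expect_equal(fd$allele_a, "T")
  expect_equal(fd$allele_b, "G")

  same <- make_aln(c("ACGT", "ACGT", "ACGT", "ACGT"),
                   c(rep("japonica", 2), rep("wild", 2)))
  expect_equal(nrow(fixed_differences(same, "japonica", "wild")), 0L)
  expect_error(fixed_differences(aln, "japonica", "wild",
                                 freq_threshold = 0.4), "config error")

  # threshold 0.95 with 19/20 T in A: reported iff popB T-freq <= 0.05
  seqA <- c(rep("T", 19), "G")
  for (b_t in c(0, 1, 2)) {
    seqB <- c(rep("T", b_t), rep("G", 20 - b_t))
    aln2 <- make_aln(setNames(c(seqA, seqB), sprintf("s%02d", 1:40)),
                     c(rep("japonica", 20), rep("wild", 20)))
    fd2 <- fixed_differences(aln2, "japonica", "wild", 0.95)
    expect_equal(nrow(fd2), as.integer(b_t / 20 <= 0.05))
  }
})
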