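test_that("back-translation maps aligned residues to their codons", {
  ca <- back_translate("MK", "MK", "ATGAAA", "ATGAAG", "x", "y")
  expect_equal(ca$codons_a, c("ATG", "AAA"))
  expect_equal(ca$codons_b, c("ATG", "AAG"))

  # protein gap becomes a whole-codon gap; trailing stop is trimmed
  ca2 <- back_translate("M-A", "MKA", "ATGGCT", "ATGAAAGCTTAA", "x", "y")
  expect_equal(ca2$codons_a, c("ATG", "---", "GCT"))
  expect_equal(ca2$codons_b, c("ATG", "AAA", "GCT"))

  expect_error(back_translate("MK", "MK", "ATGCTT", "ATGAAA"),
               "mismatch at residue 2")
  expect_error(back_translate("MK", "MK", "ATGAAAA", "ATGAAA"),
               "does not match")
})

test_that("codon alignments enforce their invariants", {
  expect_error(codon_alignment("a", "b", c("ATG"), c("ATG", "AAA")),
               "equal length")
  expect_error(codon_alignment("a", "b", "AT-", "ATG"), "3-mers")
  expect_error(codon_alignment("a", "b", c("---"), c("---")), "both")
  expect_error(codon_alignment("a", "b", c("TAA", "AAA"), c("AAA", "AAA")),
               "stop")
})

test_that("NG86 on identical sequences gives zero rates, undefined ratio", {
  cods <- c("ATG", "AAA", "GGG", "TTT")
  est <- ng86_kaks(codon_alignment("a", "b", cods, cods))
  expect_equal(est$Sd, 0)
  expect_equal(est$Nd, 0)
  expect_equal(est$Ka, 0)
  expect_equal(est$Ks, 0)
  expect_true(is.na(est$ratio))
  expect_equal(est$S_sites + est$N_sites, 3 * length(cods))
})

test_that("a single synonymous difference is counted against exact sites", {
  a <- c("TTT", "AAA", "GGG")
  b <- c("TTC", "AAA", "GGG")
  est <- ng86_kaks(codon_alignment("a", "b", a, b))
  orc <- oracle_ng86(a, b)
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$Ka, 0)
  expect_equal(est$S_sites, orc$S)
  expect_equal(est$Ks, -0.75 * log(1 - (4 / 3) / orc$S))
})

test_that("NG86 matches the enumeration oracle on random alignments", {
  set.seed(101)
  for (case in 1:12) {
    n <- 50L
    a <- oracle_random_codons(n)
    b <- oracle_mutate_codons(a, sample(5:25, 1))
    est <- ng86_kaks(codon_alignment("a", "b", a, b))
    orc <- oracle_ng86(a, b)
    expect_equal(est$S_sites, orc$S, tolerance = 1e-12)
    expect_equal(est$N_sites, orc$N, tolerance = 1e-12)
    expect_equal(est$Sd, orc$Sd, tolerance = 1e-12)
    expect_equal(est$Nd, orc$Nd, tolerance = 1e-12)
    expect_equal(est$Ks, orc$Ks, tolerance = 1e-12)
    expect_equal(est$Ka, orc$Ka, tolerance = 1e-12)
    # symmetry in every field
    rev <- ng86_kaks(codon_alignment("b", "a", b, a))
    expect_equal(est[c("S_sites", "N_sites", "Sd", "Nd", "Ks", "Ka", "ratio")],
                 rev[c("S_sites", "N_sites", "Sd", "Nd", "Ks", "Ka", "ratio")])
  }
})

test_that("gapped columns are excluded pairwise and saturation is an error", {
  a <- c("ATG", "---", "GGG")
  b <- c("ATG", "AAA", "GGG")
  est <- ng86_kaks(codon_alignment("a", "b", a, b))
  expect_equal(est$n_codons, 2L)

  expect_error(ng86_kaks(codon_alignment("a", "b", c("---"), c("AAA"))),
               "no gap-free")
  # saturated synonymous proportion
  sat_a <- rep("TTT", 4); sat_b <- rep("TTC", 4)
  expect_error(ng86_kaks(codon_alignment("a", "b", sat_a, sat_b)),
               "saturation")
})

test_that("sliding windows tile the alignment and match the global estimate", {
  set.seed(21)
  a <- oracle_random_codons(40)
  b <- oracle_mutate_codons(a, 10)
  aln <- codon_alignment("a", "b", a, b)

  # window covering the whole alignment reproduces the global estimate
  full <- sliding_window_kaks(aln, window_bp = 120, step_bp = 6)
  glob <- ng86_kaks(aln)
  expect_equal(nrow(full), 1L)
  expect_equal(full$Ka, glob$Ka)
  expect_equal(full$Ks, glob$Ks)

  # 60 bp alignment, 60 bp window -> exactly one window
  one <- sliding_window_kaks(codon_alignment("a", "b", a[1:20], b[1:20]),
                             window_bp = 60, step_bp = 6)
  expect_equal(nrow(one), 1L)

  expect_error(sliding_window_kaks(aln, window_bp = 61), "divisible by 3")
  expect_error(sliding_window_kaks(aln, window_bp = 300), "exceeds")
})

test_that("a planted high-omega block is located by the windowed ratio", {
  set.seed(33)
  # low-omega background with a 30-codon block evolved at high omega
  pair <- evolve_duplicate_pair(120, omega = 0.1, target_ks = 0.3, seed = 5)
  a <- nhxdiverge:::.codons(pair$cds_a$residues)
  b <- nhxdiverge:::.codons(pair$cds_b$residues)
  hot <- evolve_duplicate_pair(50, omega = 4, target_ks = 0.3, seed = 6)
  ha <- nhxdiverge:::.codons(hot$cds_a$residues)[1:30]
  hb <- nhxdiverge:::.codons(hot$cds_b$residues)[1:30]
  a[51:80] <- ha; b[51:80] <- hb
  track <- sliding_window_kaks(codon_alignment("a", "b", a, b),
                               window_bp = 60, step_bp = 6)
  best <- track[which.max(track$ratio), ]
  # the maximum windowed ratio falls inside the planted block
  expect_gte(best$end_codon, 51)
  expect_lte(best$start_codon, 80)
})

test_that("divergence dating applies T = Ks / (2 lambda)", {
  expect_equal(divergence_time(0.22, 9.1e-9), 12.09)
  expect_equal(divergence_time(0.20, 9.1e-9), 10.99)
  expect_equal(divergence_time(0), 0)
  expect_error(divergence_time(-0.1), ">= 0")
  # linear in Ks, inversely linear in lambda
  expect_equal(divergence_time(0.44, 9.1e-9), 2 * 12.09, tolerance = 1e-2)
  expect_equal(divergence_time(0.22, 2 * 9.1e-9), 12.09 / 2, tolerance = 1e-2)
})

test_that("selection classification splits at a ratio of one", {
  expect_equal(classify_selection(0.227), "purifying")
  expect_equal(classify_selection(1), "neutral")
  expect_equal(classify_selection(1.5), "positive")
  expect_equal(classify_selection(NA), "undefined")
  expect_error(classify_selection(-0.2), ">= 0")
})
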