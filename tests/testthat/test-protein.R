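sr <- function(id, res, alpha = NULL) seq_record(id, res, alphabet = alpha)

test_that("global alignment finds optimal scores (exhaustive oracle)", {
  p <- global_align(sr("a", "AAG"), sr("b", "AG"), 1, -1, -1)
  expect_equal(p$aligned_a, "AAG")
  expect_equal(p$aligned_b, "A-G")
  expect_equal(p$score, 1)

  ident <- global_align(sr("a", "ACGT"), sr("b", "ACGT"), 2, -1, -1)
  expect_equal(ident$score, 8)
  expect_false(grepl("-", paste0(ident$aligned_a, ident$aligned_b)))

  set.seed(42)
  for (case in 1:25) {
    n1 <- sample(1:7, 1); n2 <- sample(1:7, 1)
    a <- paste(sample(c("A", "C", "G", "T"), n1, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), n2, replace = TRUE), collapse = "")
    sc <- sample(list(c(1, -1, -1), c(2, 0, -1), c(3, -2, -2)), 1)[[1]]
    got <- global_align(sr("a", a), sr("b", b), sc[1], sc[2], sc[3])
    expect_equal(got$score, oracle_align_score(a, b, sc[1], sc[2], sc[3]),
                 info = paste(a, b, paste(sc, collapse = "/")))
    # removing gaps recovers the inputs; no all-gap columns
    expect_equal(gsub("-", "", got$aligned_a), a)
    expect_equal(gsub("-", "", got$aligned_b), b)
    cols_a <- strsplit(got$aligned_a, "")[[1]]
    cols_b <- strsplit(got$aligned_b, "")[[1]]
    expect_false(any(cols_a == "-" & cols_b == "-"))
  }
})

test_that("alignment rejects empty sequences and alphabet mismatches", {
  empty <- seq_record("b", "", alphabet = "dna", allow_empty = TRUE)
  expect_error(global_align(sr("a", "A", "dna"), empty), "empty")
  expect_error(global_align(sr("a", "ACGT"), sr("b", "MKVL")), "alphabet")
})

test_that("percent identity counts identical columns over alignment length", {
  p <- global_align(sr("a", "AAG"), sr("b", "AG"), 1, -1, -1)
  expect_equal(percent_identity(p), 66.7)
  self <- global_align(sr("a", "MKVLW", "protein"), sr("b", "MKVLW", "protein"))
  expect_equal(percent_identity(self), 100)

  # symmetry and the identity criterion
  set.seed(7)
  for (case in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = "")
    ab <- percent_identity(global_align(sr("a", a), sr("b", b)))
    ba <- percent_identity(global_align(sr("b", b), sr("a", a)))
    expect_equal(ab, ba)
    expect_equal(ab == 100, a == b)
  }
})

test_that("deduced protein length excludes the stop codon", {
  expect_equal(deduced_protein_length(3438), 1145L)
  expect_equal(deduced_protein_length(1635), 544L)
  expect_equal(deduced_protein_length(6), 1L)
  expect_error(deduced_protein_length(100), "divisible by 3")
  expect_error(deduced_protein_length(3), ">= 6")
})

test_that("molecular weight sums average residue masses plus one water", {
  expect_equal(molecular_weight(sr("g", "G", "protein")), 75.07, tolerance = 1e-4)
  expect_equal(molecular_weight(sr("gg", "GG", "protein")), 132.12,
               tolerance = 1e-4)
  expect_error(molecular_weight(sr("x", "GXG", "protein")), "position 2")

  # additivity: MW(s1 + s2) = MW(s1) + MW(s2) - one water
  set.seed(5)
  aas <- names(nhxdiverge:::.AA_AVG_MASS)
  for (case in 1:8) {
    s1 <- paste(sample(aas, 12, replace = TRUE), collapse = "")
    s2 <- paste(sample(aas, 9, replace = TRUE), collapse = "")
    expect_equal(molecular_weight(sr("c", paste0(s1, s2), "protein")),
                 molecular_weight(sr("a", s1, "protein")) +
                   molecular_weight(sr("b", s2, "protein")) - 18.0153,
                 tolerance = 1e-9)
  }
})

test_that("isoelectric point solves the charge balance", {
  # termini only: pI = mean of the terminal pKa values by symmetry
  expect_equal(isoelectric_point(sr("aa", "AA", "protein")), 6.1,
               tolerance = 1e-2)
  expect_lt(isoelectric_point(sr("d4", "DDDD", "protein")), 4.0)
  # residual charge below tolerance at the reported pI
  counts <- c(Nterm = 1, Cterm = 1, C = 0, D = 4, E = 0, H = 0, K = 0,
              R = 0, Y = 0)
  pI <- isoelectric_point(sr("d4", "DDDD", "protein"))
  expect_lt(abs(nhxdiverge:::.protein_charge(counts, pI,
                                             nhxdiverge:::.EMBOSS_PKA)), 1e-4)
  # adding an acidic residue never increases the pI
  set.seed(3)
  for (case in 1:6) {
    base <- paste(sample(c("A", "G", "K", "L", "S", "D", "R"), 15,
                         replace = TRUE), collapse = "")
    expect_lte(isoelectric_point(sr("x", paste0(base, "D"), "protein")),
               isoelectric_point(sr("x", base, "protein")) + 1e-6)
  }
})

test_that("hydropathy profiles are windowed Kyte-Doolittle means", {
  polyI <- sr("i", strrep("I", 25), "protein")
  prof <- hydropathy_profile(polyI, 19)
  expect_true(all(is.na(prof[1:9])))
  expect_true(all(is.na(prof[17:25])))
  expect_true(all(prof[10:16] == 4.5))

  polyR <- sr("r", strrep("R", 25), "protein")
  expect_true(all(hydropathy_profile(polyR, 19)[10:16] == -4.5))

  # alternating I/R: window means close to the residue-pair average (0)
  alt <- sr("ir", strrep("IR", 30), "protein")
  pa <- hydropathy_profile(alt, 19)
  expect_true(all(abs(pa[!is.na(pa)]) < 0.3))

  expect_error(hydropathy_profile(sr("s", "MKV", "protein"), 19), "shorter")
  expect_error(hydropathy_profile(polyI, 10), "odd")
})

test_that("TMH prediction keeps long hydrophobic runs only", {
  # all-hydrophilic protein: nothing
  none <- predict_tmh(hydropathy_profile(sr("r", strrep("RKDE", 20), "protein")))
  expect_equal(nrow(none), 0L)

  # a 10-residue hydrophobic run is below min_len
  short <- sr("s", paste0(strrep("R", 25), strrep("I", 10), strrep("R", 25)),
              "protein")
  expect_equal(nrow(predict_tmh(hydropathy_profile(short), min_len = 15)), 0L)

  # planted segments are recovered at the planted positions (window blur)
  for (seed in c(2, 9, 31)) {
    mem <- synth_membrane_protein(n_tmh = 10, seed = seed)
    seg <- predict_tmh(hydropathy_profile(mem$protein))
    expect_equal(nrow(seg), 10L)
    expect_true(all(abs(seg$start - mem$truth$segments$start) <= 9))
    expect_true(all(abs(seg$end - mem$truth$segments$end) <= 9))
  }
})

test_that("neighbor joining is exact on additive distance matrices", {
  # two taxa: a single split with equal branches
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- nj_tree(d2)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(t2$edge.length, c(0.2, 0.2))

  # four taxa from ((A:1,B:1):2,(C:1,D:1)): AB|CD split, internal edge 2
  lab <- c("A", "B", "C", "D")
  d4 <- matrix(4, 4, 4, dimnames = list(lab, lab))
  diag(d4) <- 0
  d4["A", "B"] <- d4["B", "A"] <- 2
  d4["C", "D"] <- d4["D", "C"] <- 2
  t4 <- nj_tree(d4)
  expect_equal(unname(as.matrix(stats::cophenetic(t4))[lab, lab]),
               unname(d4))

  # random additive trees up to 8 taxa are reproduced exactly
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:8, 1)
    ref <- ape::rtree(n, br = function(k) stats::runif(k, 0.2, 1.5))
    dd <- stats::cophenetic(ref)
    got <- nj_tree(dd[sort(rownames(dd)), sort(rownames(dd))])
    expect_equal(unname(as.matrix(stats::cophenetic(got))[rownames(dd), rownames(dd)]),
                 unname(dd), tolerance = 1e-8)
  }

  asym <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(nj_tree(asym), "symmetric")
})

test_that("subfamily assignment picks the nearest labelled reference", {
  lab <- c("q1", "q2", "refV", "refP")
  d <- matrix(0.5, 4, 4, dimnames = list(lab, lab))
  diag(d) <- 0
  d["q1", "refV"] <- d["refV", "q1"] <- 0
  out <- assign_subfamilies("q1", c(refV = "Vac", refP = "PM"), d)
  expect_equal(out$class, "Vac")
  expect_false(out$tie)

  # equidistant: lexicographically smaller reference wins, tie flagged
  out2 <- assign_subfamilies("q2", c(refV = "Vac", refP = "PM"), d)
  expect_equal(out2$nearest_reference, "refP")
  expect_equal(out2$class, "PM")
  expect_true(out2$tie)

  expect_error(assign_subfamilies("nope", c(refV = "Vac"), d), "missing")
})
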