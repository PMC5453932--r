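vr <- function(ctg, pos, ref, alt, gt = character(0)) {
  variant_record(ctg, pos, ref, alt, gt)
}

test_that("coding SNVs are classified by translate-and-compare", {
  g <- make_toy_gene(2, "+")
  cds_pos <- function(off) nhxdiverge:::.cds_offset_to_genomic(g$model, off)
  genome <- g$contig

  # pick a synonymous site: third position of a codon, verified via oracle
  found <- FALSE
  for (off in seq(6, 110, by = 3)) {
    p <- cds_pos(off)
    ref <- substr(genome$residues, p, p)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      if (oracle_snv_class(p, alt, g$model, genome$residues) == "synonymous") {
        cc <- classify_variant(vr("toyctg", p, ref, alt), g$model, genome)
        expect_equal(cc$category, "synonymous")
        expect_equal(cc$protein_pos, as.integer(ceiling(off / 3)))
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  expect_true(found)

  # start codon changes are start_lost regardless of the residue outcome
  p1 <- cds_pos(1L)
  ref1 <- substr(genome$residues, p1, p1)
  cc1 <- classify_variant(vr("toyctg", p1, ref1,
                             setdiff(c("A", "C", "G", "T"), ref1)[1]),
                          g$model, genome)
  expect_equal(cc1$category, "start_lost")
  expect_equal(cc1$protein_pos, 1L)
})

test_that("splice-site, frameshift and in-frame deletion rules apply", {
  g <- make_toy_gene(5, "+")
  genome <- g$contig
  introns <- nhxdiverge:::.introns(g$model)
  d1 <- introns[1, 1]  # first base of first intron (donor)
  a2 <- introns[2, 2]  # last base of second intron (acceptor)
  refd <- substr(genome$residues, d1, d1)
  cc <- classify_variant(vr("toyctg", d1, refd,
                            setdiff(c("A", "C", "G", "T"), refd)[1]),
                         g$model, genome)
  expect_equal(cc$category, "splice_site_donor")
  refa <- substr(genome$residues, a2, a2)
  cc2 <- classify_variant(vr("toyctg", a2, refa,
                             setdiff(c("A", "C", "G", "T"), refa)[1]),
                          g$model, genome)
  expect_equal(cc2$category, "splice_site_acceptor")

  # 1-bp CDS deletion -> frame shift; 3-bp -> codon deletion
  p <- g$model$cds[2, 1] + 3L   # inside second CDS segment
  ref4 <- substr(genome$residues, p, p + 3L)
  expect_equal(classify_variant(vr("toyctg", p, substr(ref4, 1, 2),
                                   substr(ref4, 1, 1)),
                                g$model, genome)$category, "frame_shift")
  expect_equal(classify_variant(vr("toyctg", p, ref4, substr(ref4, 1, 1)),
                                g$model, genome)$category, "codon_deletion")

  # a deletion running off an exon end necessarily removes donor bases and
  # takes the splice category by precedence
  b <- g$model$exons[2, 2]  # last base of exon 2; deletion runs into intron
  anchor <- b - 1L
  refx <- substr(genome$residues, anchor, anchor + 3L)
  expect_equal(classify_variant(vr("toyctg", anchor, refx,
                                   substr(refx, 1, 1)),
                                g$model, genome)$category,
               "splice_site_donor")
})

test_that("5'UTR SNVs creating an ATG are start_gained", {
  g <- make_toy_gene(7, "+")
  genome <- g$contig
  tss <- g$model$tss
  # search the 30-nt UTR for a position where one substitution makes ATG
  hit <- NULL
  for (p in tss:(tss + 27L)) {
    for (alt in c("A", "C", "G", "T")) {
      ref <- substr(genome$residues, p, p)
      if (alt == ref) next
      cc <- classify_variant(vr("toyctg", p, ref, alt), g$model, genome)
      if (cc$category == "start_gained") hit <- cc
    }
  }
  expect_false(is.null(hit))

  # a UTR SNV that does not create an ATG is non-genic
  non <- NULL
  for (p in tss:(tss + 27L)) {
    for (alt in c("C", "G")) {
      ref <- substr(genome$residues, p, p)
      if (alt == ref) next
      cc <- classify_variant(vr("toyctg", p, ref, alt), g$model, genome)
      if (cc$category == "non_genic") non <- cc
    }
  }
  expect_false(is.null(non))
})

test_that("reference mismatches and unknown contigs are errors", {
  g <- make_toy_gene(3, "+")
  p <- g$model$cds[1, 1]
  ref <- substr(g$contig$residues, p, p)
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  alt <- setdiff(c("A", "C", "G", "T"), c(ref, wrong))[1]
  expect_error(classify_variant(vr("toyctg", p, wrong, alt), g$model, g$contig),
               "mismatch")
})

test_that("exhaustive coding SNVs agree with the oracle on both strands", {
  for (strand in c("+", "-")) {
    g <- make_toy_gene(11, strand, n_codons = 30L)
    genome <- g$contig
    cds_len <- sum(g$model$cds[, 2] - g$model$cds[, 1] + 1)
    # sample a third of all coding SNVs here (the full sweep runs in the
    # acceptance suite)
    set.seed(19)
    offs <- sample(seq_len(cds_len), ceiling(cds_len / 3))
    for (off in offs) {
      p <- nhxdiverge:::.cds_offset_to_genomic(g$model, off)
      ref <- substr(genome$residues, p, p)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        got <- classify_variant(vr(g$model$contig_id, p, ref, alt),
                                g$model, genome)$category
        want <- oracle_snv_class(p, alt, g$model, genome$residues)
        if (want %in% c("synonymous", "non_synonymous", "stop_gained",
                        "start_lost")) {
          expect_equal(got, want, info = sprintf("%s %d %s>%s", strand, p,
                                                 ref, alt))
        }
      }
    }
  }
})

test_that("strand-mirrored genes yield identical category multisets", {
  plus <- make_toy_gene(13, "+")
  minus <- make_toy_gene(13, "-")
  L <- nchar(plus$contig$residues)
  cats <- function(g) {
    out <- character(0)
    span <- range(g$model$exons)
    for (p in span[1]:span[2]) {
      ref <- substr(g$contig$residues, p, p)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        out <- c(out, classify_variant(vr(g$model$contig_id, p, ref, alt),
                                       g$model, g$contig)$category)
      }
    }
    sort(table(out))
  }
  expect_equal(cats(plus), cats(minus))
})

test_that("annotation joins variants to genes and keeps intergenic calls", {
  g <- make_toy_gene(4, "+")
  p <- g$model$cds[1, 1] + 4L
  ref <- substr(g$contig$residues, p, p)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  outside <- 3L
  refo <- substr(g$contig$residues, outside, outside)
  alto <- setdiff(c("A", "C", "G", "T"), refo)[1]
  calls <- annotate_variants(
    list(vr("toyctg", p, ref, alt), vr("toyctg", outside, refo, alto)),
    list(g$model), g$contig)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$category[calls$pos == outside], "non_genic")
  expect_true(is.na(calls$gene_id[calls$pos == outside]))
  expect_equal(nrow(annotate_variants(list(), list(g$model), g$contig)), 0L)
})

test_that("gene summaries follow the printed-table arithmetic", {
  expect_equal(tmh_overlap_pct(15, 77), 19.5)
  expect_equal(tmh_overlap_pct(11, 30), 36.7)
  expect_equal(tmh_overlap_pct(0, 0), 0)
  expect_equal(variant_density_per_kb(33, 4351), 7.58)

  g <- make_toy_gene(6, "+")
  counts <- c(non_synonymous = 3, synonymous = 2, stop_gained = 1)
  sv <- synth_variants(g$model, g$contig, counts, seed = 2)
  calls <- annotate_variants(sv$variants, list(g$model), g$contig)
  tmh <- data.frame(start = 1L, end = 40L)  # whole protein "in TMH"
  s <- summarize_gene(calls, g$model, tmh = tmh)
  # synonymous calls are excluded from the total
  expect_equal(s$total, 4L)
  expect_equal(unname(s$counts["synonymous"]), 2L)
  expect_equal(s$tmh_count, 4L)  # all counted calls have coding positions
  expect_equal(s$tmh_pct, 100)
  expect_lte(s$tmh_count, s$total)
  span <- range(g$model$exons)
  expect_equal(s$density_per_kb,
               round(1000 * 4 / (span[2] - span[1] + 1), 2))
  # zero calls
  s0 <- summarize_gene(calls[0, ], g$model)
  expect_equal(s0$total, 0L)
  expect_equal(s0$tmh_pct, 0)
})

test_that("allele frequencies use called alleles only", {
  expect_equal(allele_frequency(vr("c", 1, "A", "T", rep("0/0", 4))), 0)
  expect_equal(allele_frequency(vr("c", 1, "A", "T",
                                   c("0/1", rep("0/0", 4)))), 0.1)
  # missing genotypes drop out of the denominator entirely
  expect_equal(allele_frequency(vr("c", 1, "A", "T", c("0/1", "./."))), 0.5)
  expect_equal(allele_frequency(vr("c", 1, "A", "T",
                                   c("0/1", "0/0", "./."))), 0.25)
  expect_error(allele_frequency(vr("c", 1, "A", "T", c("./.", "./."))),
               "missing")
  # permutation invariance and range
  set.seed(29)
  gts <- sample(c("0/0", "0/1", "1/1", "./."), 12, replace = TRUE,
                prob = c(.4, .3, .2, .1))
  f <- allele_frequency(vr("c", 1, "A", "T", gts))
  expect_equal(allele_frequency(vr("c", 1, "A", "T", sample(gts))), f)
  expect_gte(f, 0); expect_lte(f, 1)
})

test_that("protein positions map ceil(cds_offset / 3)", {
  g <- make_toy_gene(8, "-")
  for (off in c(1L, 6L, 47L)) {
    p <- nhxdiverge:::.cds_offset_to_genomic(g$model, off)
    ref <- substr(g$contig$residues, p, p)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    expect_equal(protein_position(vr("toyctg", p, ref, alt), g$model),
                 as.integer(ceiling(off / 3)))
  }
  expect_error(protein_position(vr("toyctg", 1, "A", "T"), g$model), "CDS")
})
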