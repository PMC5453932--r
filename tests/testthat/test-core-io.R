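test_that("read_fasta normalizes case and line breaks and keeps order", {
  recs <- read_fasta(">g1\nacgT\n")
  expect_length(recs, 1L)
  expect_equal(recs[[1L]]$id, "g1")
  expect_equal(recs[[1L]]$residues, "ACGT")
  expect_equal(recs[[1L]]$alphabet, "dna")

  two <- read_fasta(">a\nAC\n>b\nGT\n")
  expect_equal(vapply(two, function(r) r$id, character(1L)), c("a", "b"))
})

test_that("read_fasta rejects empty input and duplicate ids", {
  expect_error(read_fasta(""), "FASTA")
  expect_error(read_fasta(">a\nAC\n>a\nGT\n"), "duplicate.*'a'")
})

test_that("fasta write/read round-trips normalized records", {
  set.seed(11)
  recs <- lapply(1:5, function(i) {
    seq_record(paste0("s", i),
               paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                     collapse = ""))
  })
  back <- read_fasta(write_fasta(recs))
  expect_equal(back, recs)
})

test_that("gene models apply the strand convention for TSS and exon order", {
  plus <- read_gene_models(toy_gff3(strand = "+"))[[1L]]
  expect_equal(plus$tss, 101L)
  expect_equal(plus$exons[, 1L], c(101L, 301L))

  minus <- read_gene_models(toy_gff3(strand = "-"))[[1L]]
  expect_equal(minus$tss, 400L)
  # transcription order is reversed on the minus strand
  expect_equal(unname(minus$exons[1L, ]), c(301L, 400L))
  expect_equal(unname(minus$exons[2L, ]), c(101L, 200L))
})

test_that("invalid gene models are rejected", {
  # CDS total 100 nt, not divisible by 3
  bad <- gsub("301\t349", "301\t350", toy_gff3())
  expect_error(read_gene_models(bad), "divisible by 3")
  # exon outside the gene span
  bad2 <- gsub("exon\t101\t200", "exon\t50\t200", toy_gff3())
  expect_error(read_gene_models(bad2), "outside gene span")
  expect_error(gene_model("g", "c", "+", rbind(c(1, 100)),
                          rbind(c(10, 30), c(20, 60))), "overlap")
})

test_that("intron structure and phases follow cumulative CDS length", {
  m <- read_gene_models(toy_gff3())[[1L]]
  s <- gene_structure_summary(m)
  expect_equal(s$exon_count, 2L)
  expect_equal(s$intron_count, 1L)
  expect_equal(s$intron_phases, 50L %% 3L)  # 50 coding bases before intron

  # two CDS exons of 10 and 20 bp -> phase 10 %% 3 = 1
  m2 <- gene_model("g2", "c", "+", rbind(c(1, 15), c(100, 125)),
                   rbind(c(6, 15), c(100, 119)))
  expect_equal(gene_structure_summary(m2)$intron_phases, 1L)

  # single-exon gene
  m3 <- gene_model("g3", "c", "+", rbind(c(1, 100)), rbind(c(11, 40)))
  s3 <- gene_structure_summary(m3)
  expect_equal(s3$exon_count, 1L)
  expect_equal(s3$intron_count, 0L)
  expect_equal(s3$intron_phases, integer(0))

  # a 14-exon model has 13 introns
  ex <- cbind(seq(1, by = 50, length.out = 14),
              seq(30, by = 50, length.out = 14))
  m4 <- gene_model("g4", "c", "+", ex, ex)
  expect_equal(gene_structure_summary(m4)$intron_count, 13L)
})

test_that("intron phases are invariant under strand mirroring", {
  for (seed in 1:5) {
    plus <- make_toy_gene(seed, "+")
    minus <- make_toy_gene(seed, "-")
    expect_equal(gene_structure_summary(plus$model),
                 gene_structure_summary(minus$model))
  }
})

test_that("intron lengths complement exon lengths within the gene span", {
  g <- make_toy_gene(3, "+")$model
  span <- max(g$exons) - min(g$exons) + 1L
  exon_len <- sum(g$exons[, 2L] - g$exons[, 1L] + 1L)
  intr <- nhxdiverge:::.introns(g)
  expect_equal(sum(intr[, 2L] - intr[, 1L] + 1L), span - exon_len)
})

test_that("promoter extraction follows the -upstream..+downstream window", {
  genome <- seq_record("c", paste(rep("ACGT", 1500), collapse = ""))
  m <- gene_model("g", "c", "+", rbind(c(2000, 2600)), rbind(c(2100, 2399)))
  p <- extract_promoter(m, genome, 1500, 500)
  expect_equal(nchar(p$residues), 2000L)
  expect_equal(p$residues, substr(genome$residues, 500, 2499))
  expect_false(attr(p, "truncated"))
  expect_equal(attr(p, "tss_index"), 1501L)

  m2 <- gene_model("g", "c", "-", rbind(c(1500, 2000)), rbind(c(1600, 1899)))
  p2 <- extract_promoter(m2, genome, 1500, 500)
  expect_equal(p2$residues, revcomp_chr(substr(genome$residues, 1501, 3500)))

  # TSS near the contig edge: truncated upstream, flagged
  m3 <- gene_model("g", "c", "+", rbind(c(100, 700)), rbind(c(200, 499)))
  p3 <- extract_promoter(m3, genome, 1500, 500)
  expect_true(attr(p3, "truncated"))
  expect_equal(nchar(p3$residues), 99L + 500L)

  # window entirely off the contig (model coordinates beyond its end)
  m4 <- gene_model("g", "c", "+", rbind(c(9000, 9599)), rbind(c(9100, 9399)))
  expect_error(extract_promoter(m4, genome, 500, 100), "off contig")
})

test_that("promoter length equals upstream+downstream when not truncated", {
  genome <- seq_record("c", paste(rep("ACGT", 2000), collapse = ""))
  for (seed in 1:6) {
    set.seed(seed)
    up <- sample(100:1500, 1)
    down <- sample(10:500, 1)
    strand <- sample(c("+", "-"), 1)
    m <- gene_model("g", "c", strand, rbind(c(3000, 3600)),
                    rbind(c(3100, 3399)))
    p <- extract_promoter(m, genome, up, down)
    expect_false(attr(p, "truncated"))
    expect_equal(nchar(p$residues), up + down)
  }
})

test_that("read_vcf parses genotypes and normalizes phasing", {
  v <- read_vcf(toy_vcf("chr1\t5\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0|1"))
  expect_length(v, 1L)
  expect_equal(v[[1L]]$pos, 5L)
  expect_equal(v[[1L]]$ref, "A")
  expect_equal(v[[1L]]$alt, "T")
  expect_equal(v[[1L]]$genotypes, c("0/0", "0/1"))
})

test_that("read_vcf rejects multi-allelic rows and missing GT", {
  expect_error(read_vcf(toy_vcf("chr1\t5\t.\tA\tT,G\t.\tPASS\t.\tGT\t0/0\t0/1")),
               "multi-allelic.*split")
  expect_error(read_vcf(toy_vcf("chr1\t5\t.\tA\tT\t.\tPASS\t.\tDP\t4\t7")),
               "GT")
})

test_that("expression matrices load with labels and strict validation", {
  txt <- "gene\tc1\tc2\tc3\ng1\t1\t2\t3\ng2\t4\t5\t6\n"
  m <- read_expression_matrix(txt)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(rownames(m), c("g1", "g2"))
  expect_equal(colnames(m), c("c1", "c2", "c3"))
  expect_equal(unname(m["g2", "c3"]), 6)

  expect_error(read_expression_matrix("gene\tc1\ng1\tNA\n"),
               "non-numeric.*'g1'.*'c1'")
  expect_error(read_expression_matrix("gene\tc1\ng1\t-2\n"), "negative")
  expect_error(read_expression_matrix("gene\tc1\ng1\t1\ng1\t2\n"),
               "duplicated gene id")
})
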