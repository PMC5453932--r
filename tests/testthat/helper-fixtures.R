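# fixture builders (constructed in code at test time)

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna_no_atg <- function(n) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    if (!grepl("ATG", s, fixed = TRUE)) return(s)
  }
}

# a 5-exon toy gene (ATG start, TAA stop, 30-nt UTRs, 20-nt introns) on a
# small contig; strand "-" mirrors the whole layout
make_toy_gene <- function(seed = 1L, strand = "+", n_codons = 40L,
                          gene_id = "toy", contig_id = "toyctg") {
  set.seed(seed)
  cds <- paste0("ATG", paste(oracle_random_codons(n_codons - 2L), collapse = ""),
                "TAA")
  n_ex <- 5L
  len <- nchar(cds)
  base <- len %/% n_ex
  sizes <- rep(base, n_ex)
  sizes[n_ex] <- sizes[n_ex] + (len - base * n_ex)
  chunk_start <- cumsum(c(1L, sizes[-n_ex]))
  chunks <- substring(cds, chunk_start, chunk_start + sizes - 1L)
  utr5 <- random_dna_no_atg(30L)
  utr3 <- random_dna_no_atg(30L)
  flank <- random_dna_no_atg(25L)

  pieces <- flank
  pos <- nchar(flank)
  tss <- pos + 1L
  exons <- NULL; cds_iv <- NULL
  pieces <- c(pieces, utr5, chunks[[1L]])
  exons <- rbind(exons, c(tss, pos + 30L + sizes[[1L]]))
  cds_iv <- rbind(cds_iv, c(pos + 31L, pos + 30L + sizes[[1L]]))
  pos <- pos + 30L + sizes[[1L]]
  for (i in 2:n_ex) {
    intron <- paste0("GT", random_dna_no_atg(16L), "AG")
    pieces <- c(pieces, intron)
    pos <- pos + 20L
    last <- i == n_ex
    exon_seq <- if (last) paste0(chunks[[i]], utr3) else chunks[[i]]
    pieces <- c(pieces, exon_seq)
    exons <- rbind(exons, c(pos + 1L, pos + nchar(exon_seq)))
    cds_iv <- rbind(cds_iv, c(pos + 1L, pos + sizes[[i]]))
    pos <- pos + nchar(exon_seq)
  }
  pieces <- c(pieces, flank)
  contig <- paste(pieces, collapse = "")
  L <- nchar(contig)
  if (strand == "-") {
    contig <- revcomp_chr(contig)
    flip <- function(m) cbind(L - m[, 2L] + 1L, L - m[, 1L] + 1L)
    exons <- flip(exons)
    cds_iv <- flip(cds_iv)
  }
  list(model = gene_model(gene_id, contig_id, strand, exons, cds_iv),
       contig = seq_record(contig_id, contig, "dna"),
       cds = cds)
}

# simple GFF3 text for a single-transcript gene
toy_gff3 <- function(contig = "chr1", strand = "+") {
  paste(
    "##gff-version 3",
    sprintf("%s\tsrc\tgene\t101\t400\t.\t%s\t.\tID=gA", contig, strand),
    sprintf("%s\tsrc\tmRNA\t101\t400\t.\t%s\t.\tID=gA.1;Parent=gA", contig, strand),
    sprintf("%s\tsrc\texon\t101\t200\t.\t%s\t.\tParent=gA.1", contig, strand),
    sprintf("%s\tsrc\texon\t301\t400\t.\t%s\t.\tParent=gA.1", contig, strand),
    sprintf("%s\tsrc\tCDS\t151\t200\t.\t%s\t.\tParent=gA.1", contig, strand),
    sprintf("%s\tsrc\tCDS\t301\t349\t.\t%s\t.\tParent=gA.1", contig, strand),
    sep = "\n")
}

# minimal VCF text
toy_vcf <- function(rows, samples = c("S1", "S2")) {
  paste(c("##fileformat=VCFv4.2",
          "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
          paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                  "INFO", "FORMAT", samples), collapse = "\t"),
          rows), collapse = "\n")
}
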