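#' Gene models
#'
#' A `gene_model` describes one transcript's strand-aware exon/CDS structure
#' on a contig, using 1-based closed genomic intervals throughout. Exons and
#' CDS segments are stored in transcription order (5' to 3' of the mRNA), so
#' for minus-strand genes the first exon is the one with the largest genomic
#' coordinate. The TSS is the transcription-start coordinate of the first
#' exon.
#'
#' @param gene_id,contig_id Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds Two-column matrices of 1-based closed `(start, end)`
#'   genomic intervals. May be given in any order; they are sorted into
#'   transcription order. CDS total length must be divisible by 3.
#' @return An object of class `gene_model` with elements `gene_id`,
#'   `contig_id`, `strand`, `tss`, `exons`, `cds`.
#' @export
gene_model <- function(gene_id, contig_id, strand, exons, cds) {
  if (!strand %in% c("+", "-")) .stopf("strand must be '+' or '-'")
  exons <- .as_interval_matrix(exons, "exons")
  cds <- .as_interval_matrix(cds, "cds_segments")
  # sort into transcription order
  ord <- order(exons[, 1L], decreasing = (strand == "-"))
  exons <- exons[ord, , drop = FALSE]
  ord <- order(cds[, 1L], decreasing = (strand == "-"))
  cds <- cds[ord, , drop = FALSE]
  # overlap check (genomic order)
  for (m in list(exons, cds)) {
    g <- m[order(m[, 1L]), , drop = FALSE]
    if (nrow(g) > 1L && any(g[-1L, 1L] <= g[-nrow(g), 2L])) {
      .stopf("gene '%s': overlapping intervals", gene_id)
    }
  }
  # each CDS segment must lie inside an exon
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds[i, 1L] >= exons[, 1L] & cds[i, 2L] <= exons[, 2L])
    if (!inside) .stopf("gene '%s': CDS segment outside exons", gene_id)
  }
  cds_len <- sum(cds[, 2L] - cds[, 1L] + 1L)
  if (cds_len %% 3L != 0L) {
    .stopf("gene '%s': CDS length %d not divisible by 3", gene_id, cds_len)
  }
  tss <- unname(if (strand == "+") exons[1L, 1L] else exons[1L, 2L])
  structure(list(gene_id = gene_id, contig_id = contig_id, strand = strand,
                 tss = tss, exons = exons, cds = cds),
            class = "gene_model")
}

.as_interval_matrix <- function(x, what) {
  if (is.null(dim(x))) x <- matrix(as.integer(x), ncol = 2L, byrow = TRUE)
  x <- matrix(as.integer(x), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  if (nrow(x) == 0L) .stopf("%s must contain at least one interval", what)
  if (any(is.na(x)) || any(x < 1L) || any(x[, 2L] < x[, 1L])) {
    .stopf("%s must be 1-based closed intervals with start <= end", what)
  }
  x
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s on %s(%s), tss=%d, %d exon(s), CDS %d bp>\n",
              x$gene_id, x$contig_id, x$strand, x$tss, nrow(x$exons),
              sum(x$cds[, 2L] - x$cds[, 1L] + 1L)))
  invisible(x)
}

# gene span (genomic min/max over exons)
.gene_span <- function(model) {
  c(min(model$exons[, 1L]), max(model$exons[, 2L]))
}

# introns in transcription order, genomic coordinates (start <= end)
.introns <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2L) return(matrix(integer(0), ncol = 2L,
                            dimnames = list(NULL, c("start", "end"))))
  if (model$strand == "+") {
    cbind(start = ex[-n, 2L] + 1L, end = ex[-1L, 1L] - 1L)
  } else {
    cbind(start = ex[-1L, 2L] + 1L, end = ex[-n, 1L] - 1L)
  }
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 subset with `gene`, `mRNA`, `exon` and `CDS` rows (one mRNA
#' per gene) into a list of [gene_model]s. Coordinates follow the GFF3
#' convention of 1-based closed intervals.
#'
#' @param gff3_text GFF3 text or a file path.
#' @return Named list of [gene_model]s, in input gene order.
#' @export
read_gene_models <- function(gff3_text) {
  path <- .as_file(gff3_text, ".gff3")
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) .stopf("malformed GFF3: %s", conditionMessage(e)))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1L))
  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) .stopf("no gene rows in GFF3 input")
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- g$ID
    mrna <- df[df$type == "mRNA" & df$Parent %in% gid, , drop = FALSE]
    if (nrow(mrna) != 1L) {
      .stopf("gene '%s' must have exactly one mRNA (found %d)", gid, nrow(mrna))
    }
    kids <- df[df$Parent %in% mrna$ID, , drop = FALSE]
    exons <- kids[kids$type == "exon", c("start", "end"), drop = FALSE]
    cds <- kids[kids$type == "CDS", c("start", "end"), drop = FALSE]
    if (nrow(exons) == 0L) .stopf("gene '%s' has no exon rows", gid)
    if (nrow(cds) == 0L) .stopf("gene '%s' has no CDS rows", gid)
    if (any(exons$start < g$start | exons$end > g$end) ||
        any(cds$start < g$start | cds$end > g$end)) {
      .stopf("gene '%s': exon/CDS outside gene span", gid)
    }
    out[[gid]] <- gene_model(gid, as.character(g$seqnames),
                             as.character(g$strand),
                             as.matrix(exons), as.matrix(cds))
  }
  out
}

#' Summarize exon/intron structure
#'
#' Counts exons and introns and computes intron phases for the introns that
#' interrupt the CDS. The phase of the intron falling after cumulative CDS
#' length `L` (in transcription order) is `L %% 3`: phase 0 introns sit
#' between codons, phase 1/2 introns split a codon after its first/second
#' base.
#'
#' @param model A [gene_model].
#' @return List with `exon_count`, `intron_count` and `intron_phases`
#'   (integer vector, one entry per CDS-interrupting intron, 5' to 3').
#' @export
gene_structure_summary <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  n_ex <- nrow(model$exons)
  cds <- model$cds
  cds_total <- sum(cds[, 2L] - cds[, 1L] + 1L)
  phases <- integer(0)
  if (n_ex > 1L) {
    # cumulative CDS length upstream of the intron after exon i
    for (i in seq_len(n_ex - 1L)) {
      ex_sofar <- model$exons[seq_len(i), , drop = FALSE]
      L <- 0L
      for (j in seq_len(nrow(cds))) {
        ov <- .interval_overlap(cds[j, ], ex_sofar)
        L <- L + ov
      }
      if (L > 0L && L < cds_total) phases <- c(phases, L %% 3L)
    }
  }
  list(exon_count = n_ex, intron_count = n_ex - 1L,
       intron_phases = as.integer(phases))
}

# total overlap (bp) of closed interval `iv` with rows of matrix `m`
.interval_overlap <- function(iv, m) {
  ov <- pmin(iv[2L], m[, 2L]) - pmax(iv[1L], m[, 1L]) + 1L
  sum(pmax(ov, 0L))
}

#' Extract a promoter sequence around the TSS
#'
#' Returns the transcription-sense sequence covering `upstream` bases before
#' the TSS plus `downstream` bases starting at the TSS (the TSS itself is
#' position +1; there is no position 0). Minus-strand promoters are
#' reverse-complemented. Windows running off the contig are truncated and
#' flagged rather than fatal; a window entirely off the contig is an error.
#'
#' @param model A [gene_model].
#' @param genome [seq_record] for the gene's contig.
#' @param upstream,downstream Window extents in bases (defaults 1500/500,
#'   i.e. the classical -1500..+500 promoter window).
#' @return A [seq_record] (id `<gene_id>_promoter`) carrying attributes
#'   `gene_id`, `upstream` and `downstream` (the extents actually obtained),
#'   `tss_index` (string index of the TSS base) and `truncated`.
#' @export
extract_promoter <- function(model, genome, upstream = 1500L,
                             downstream = 500L) {
  stopifnot(inherits(model, "gene_model"), inherits(genome, "seq_record"))
  if (model$contig_id != genome$id) {
    .stopf("contig mismatch: model on '%s', genome is '%s'",
           model$contig_id, genome$id)
  }
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  if (upstream < 0L || downstream < 1L) {
    .stopf("upstream must be >= 0 and downstream >= 1")
  }
  clen <- nchar(genome$residues)
  tss <- model$tss
  if (model$strand == "+") {
    gstart <- tss - upstream; gend <- tss + downstream - 1L
  } else {
    gstart <- tss - downstream + 1L; gend <- tss + upstream
  }
  if (gend < 1L || gstart > clen) .stopf("promoter window entirely off contig")
  cs <- max(gstart, 1L); ce <- min(gend, clen)
  slice <- substr(genome$residues, cs, ce)
  if (model$strand == "+") {
    act_up <- tss - cs; act_down <- ce - tss + 1L
    seqres <- slice
  } else {
    act_up <- ce - tss; act_down <- tss - cs + 1L
    seqres <- .revcomp(slice)
  }
  rec <- seq_record(paste0(model$gene_id, "_promoter"), seqres, "dna")
  attr(rec, "gene_id") <- model$gene_id
  attr(rec, "upstream") <- act_up
  attr(rec, "downstream") <- act_down
  attr(rec, "tss_index") <- act_up + 1L
  attr(rec, "truncated") <- (act_up < upstream) || (act_down < downstream)
  rec
}

# spliced CDS in transcription sense
.gene_cds_sequence <- function(model, genome) {
  stopifnot(model$contig_id == genome$id)
  parts <- vapply(seq_len(nrow(model$cds)), function(i) {
    substr(genome$residues, model$cds[i, 1L], model$cds[i, 2L])
  }, character(1L))
  if (model$strand == "+") {
    paste(parts, collapse = "")
  } else {
    paste(vapply(parts, .revcomp, character(1L)), collapse = "")
  }
}

# 1-based offset within the spliced CDS (transcription sense) of genomic
# position gpos, or NA if gpos is not in the CDS
.genomic_to_cds_offset <- function(model, gpos) {
  off <- 0L
  for (i in seq_len(nrow(model$cds))) {
    s <- model$cds[i, 1L]; e <- model$cds[i, 2L]
    w <- e - s + 1L
    if (gpos >= s && gpos <= e) {
      within <- if (model$strand == "+") gpos - s + 1L else e - gpos + 1L
      return(off + within)
    }
    off <- off + w
  }
  NA_integer_
}
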