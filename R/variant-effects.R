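
# consequence categories, in classification precedence order
.CONSEQUENCE_LEVELS <- c("splice_site_donor", "splice_site_acceptor",
                         "start_lost", "frame_shift", "codon_deletion",
                         "stop_gained", "non_synonymous", "synonymous",
                         "start_gained", "non_genic")

# 1-based offset within the spliced transcript (exons, transcription sense)
.genomic_to_tx_offset <- function(model, gpos) {
  off <- 0L
  for (i in seq_len(nrow(model$exons))) {
    s <- model$exons[i, 1L]; e <- model$exons[i, 2L]
    if (gpos >= s && gpos <= e) {
      within <- if (model$strand == "+") gpos - s + 1L else e - gpos + 1L
      return(off + within)
    }
    off <- off + (e - s + 1L)
  }
  NA_integer_
}

# spliced transcript sequence (exons, transcription sense)
.gene_tx_sequence <- function(model, genome) {
  parts <- vapply(seq_len(nrow(model$exons)), function(i) {
    substr(genome$residues, model$exons[i, 1L], model$exons[i, 2L])
  }, character(1L))
  if (model$strand == "+") paste(parts, collapse = "")
  else paste(vapply(parts, .revcomp, character(1L)), collapse = "")
}

.complement_base <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[[b]]

#' Protein residue index of a coding SNV
#'
#' Maps a single-nucleotide variant inside the CDS to its 1-based residue
#' index: `ceiling(cds_offset / 3)` where `cds_offset` is the position
#' within the spliced CDS in transcription sense.
#'
#' @param v A [variant_record] (SNV).
#' @param g A [gene_model].
#' @return Integer residue index.
#' @export
protein_position <- function(v, g) {
  stopifnot(inherits(v, "variant_record"), inherits(g, "gene_model"))
  off <- .genomic_to_cds_offset(g, v$pos)
  if (is.na(off)) .stopf("variant %s:%d is not in the CDS of '%s'",
                         v$contig_id, v$pos, g$gene_id)
  as.integer(ceiling(off / 3))
}

#' Classify a variant's consequence on a gene model
#'
#' Assigns exactly one of the consequence categories `splice_site_donor`,
#' `splice_site_acceptor`, `start_lost`, `frame_shift`, `codon_deletion`,
#' `stop_gained`, `non_synonymous`, `synonymous`, `start_gained` or
#' `non_genic`, applying that precedence order (first match wins) so that
#' per-gene counts stay additive. Splice sites are the canonical 2-base
#' windows at each intron end; `start_gained` is a 5'UTR SNV creating a new
#' ATG on the sense strand; coding effects are computed on the
#' transcription-sense spliced CDS.
#'
#' @param v A [variant_record] whose ref allele matches the genome.
#' @param g A [gene_model].
#' @param genome [seq_record] of the gene's contig.
#' @param tmh Optional TMH table from [predict_tmh] for the gene's protein;
#'   used to flag coding variants inside transmembrane segments.
#' @return Object of class `consequence_call`: list with `contig_id`, `pos`,
#'   `ref`, `alt`, `gene_id`, `category`, `protein_pos` (residue index or
#'   `NA`), `ref_codon`/`alt_codon` (or `NA`), `in_tmh`.
#' @export
classify_variant <- function(v, g, genome, tmh = NULL) {
  stopifnot(inherits(v, "variant_record"), inherits(g, "gene_model"),
            inherits(genome, "seq_record"))
  if (v$contig_id != g$contig_id || g$contig_id != genome$id) {
    .stopf("contig mismatch between variant, gene and genome")
  }
  ref_len <- nchar(v$ref)
  obs <- substr(genome$residues, v$pos, v$pos + ref_len - 1L)
  if (obs != v$ref) {
    .stopf("ref allele mismatch at %s:%d (VCF '%s', genome '%s')",
           v$contig_id, v$pos, v$ref, obs)
  }
  call <- function(category, protein_pos = NA_integer_,
                   ref_codon = NA_character_, alt_codon = NA_character_) {
    in_tmh <- FALSE
    if (!is.na(protein_pos) && !is.null(tmh) && nrow(tmh) > 0L) {
      in_tmh <- any(protein_pos >= tmh$start & protein_pos <= tmh$end)
    }
    structure(list(contig_id = v$contig_id, pos = v$pos, ref = v$ref,
                   alt = v$alt, gene_id = g$gene_id, category = category,
                   protein_pos = protein_pos, ref_codon = ref_codon,
                   alt_codon = alt_codon, in_tmh = in_tmh),
              class = "consequence_call")
  }

  is_indel <- ref_len != nchar(v$alt)
  if (is_indel) {
    if (substr(v$ref, 1L, 1L) != substr(v$alt, 1L, 1L)) {
      .stopf("indel at %s:%d must share its anchor base between ref and alt",
             v$contig_id, v$pos)
    }
    if (ref_len > 1L && nchar(v$alt) > 1L) {
      .stopf("complex substitution at %s:%d is unsupported", v$contig_id, v$pos)
    }
  }
  # bases whose identity/presence changes
  affected <- if (!is_indel) {
    v$pos
  } else if (ref_len > nchar(v$alt)) {
    (v$pos + nchar(v$alt)):(v$pos + ref_len - 1L)   # deleted bases
  } else {
    v$pos                                            # insertion point
  }

  span <- .gene_span(g)
  if (max(affected) < span[[1L]] || min(affected) > span[[2L]]) {
    return(call("non_genic"))
  }
  if (min(affected) < span[[1L]] || max(affected) > span[[2L]]) {
    .stopf("variant at %s:%d spans the gene boundary; unsupported", v$contig_id, v$pos)
  }

  # 1) splice sites: first/last 2 intron bases (transcription order)
  introns <- .introns(g)
  if (nrow(introns) > 0L) {
    for (i in seq_len(nrow(introns))) {
      s <- introns[i, 1L]; e <- introns[i, 2L]
      donor <- if (g$strand == "+") c(s, min(s + 1L, e)) else c(max(e - 1L, s), e)
      accep <- if (g$strand == "+") c(max(e - 1L, s), e) else c(s, min(s + 1L, e))
      if (any(affected >= donor[[1L]] & affected <= donor[[2L]])) {
        return(call("splice_site_donor"))
      }
      if (any(affected >= accep[[1L]] & affected <= accep[[2L]])) {
        return(call("splice_site_acceptor"))
      }
    }
    # indels must not straddle exon/intron boundaries
    if (is_indel && length(affected) > 1L) {
      in_exon <- vapply(affected, function(p) {
        any(p >= g$exons[, 1L] & p <= g$exons[, 2L])
      }, logical(1L))
      if (any(in_exon) && !all(in_exon)) {
        .stopf("indel at %s:%d spans an intron/exon boundary; unsupported",
               v$contig_id, v$pos)
      }
    }
  }

  cds_off <- vapply(affected, function(p) .genomic_to_cds_offset(g, p),
                    integer(1L))
  in_cds <- !is.na(cds_off)

  # 2) start_lost: any change touching the initiator codon
  if (any(in_cds) && any(cds_off[in_cds] <= 3L)) {
    return(call("start_lost", protein_pos = 1L))
  }
  # 3/4) CDS indels: frame shift vs in-frame codon deletion
  if (is_indel) {
    if (!any(in_cds)) return(call("non_genic"))
    indel_len <- abs(ref_len - nchar(v$alt))
    if (indel_len %% 3L != 0L) return(call("frame_shift"))
    return(call("codon_deletion"))
  }
  # SNV in CDS: translate-and-compare on the affected codon
  if (in_cds) {
    cds_seq <- .gene_cds_sequence(g, genome)
    off <- cds_off[[1L]]
    res <- as.integer(ceiling(off / 3))
    codon_start <- (res - 1L) * 3L + 1L
    ref_codon <- substr(cds_seq, codon_start, codon_start + 2L)
    alt_base <- if (g$strand == "+") v$alt else .complement_base(v$alt)
    within <- off - codon_start + 1L
    alt_codon <- ref_codon
    substr(alt_codon, within, within) <- alt_base
    gc <- Biostrings::GENETIC_CODE
    ref_aa <- gc[[ref_codon]]; alt_aa <- gc[[alt_codon]]
    if (alt_aa == "*" && ref_aa != "*") {
      return(call("stop_gained", res, ref_codon, alt_codon))
    }
    if (ref_aa == alt_aa) return(call("synonymous", res, ref_codon, alt_codon))
    return(call("non_synonymous", res, ref_codon, alt_codon))
  }
  # 5'UTR SNV creating a new ATG -> start_gained
  tx_off <- .genomic_to_tx_offset(g, v$pos)
  if (!is.na(tx_off)) {
    cds_start_g <- if (g$strand == "+") g$cds[1L, 1L] else g$cds[1L, 2L]
    utr5_len <- .genomic_to_tx_offset(g, cds_start_g) - 1L
    if (tx_off <= utr5_len) {
      tx <- .gene_tx_sequence(g, genome)
      alt_base <- if (g$strand == "+") v$alt else .complement_base(v$alt)
      tx_alt <- tx
      substr(tx_alt, tx_off, tx_off) <- alt_base
      lo <- max(1L, tx_off - 2L); hi <- min(nchar(tx), tx_off + 2L)
      has_atg <- function(s) {
        any(vapply(lo:max(lo, hi - 2L), function(i) {
          substr(s, i, i + 2L) == "ATG"
        }, logical(1L)))
      }
      if (!has_atg(tx) && has_atg(tx_alt)) return(call("start_gained"))
    }
  }
  call("non_genic")
}

#' @export
print.consequence_call <- function(x, ...) {
  cat(sprintf("<consequence %s:%d %s>%s on %s: %s%s>\n", x$contig_id, x$pos,
              x$ref, x$alt, x$gene_id, x$category,
              if (!is.na(x$protein_pos)) sprintf(" (residue %d%s)",
                x$protein_pos, if (x$in_tmh) ", in TMH" else "") else ""))
  invisible(x)
}

#' Annotate a variant set against gene models
#'
#' Classifies every variant against every gene whose contig it shares:
#' variants inside a gene span get that gene's consequence call, variants
#' outside all genes are reported once as `non_genic`. Synonymous calls are
#' retained in the output (downstream summaries exclude them).
#'
#' @param variants List of [variant_record]s.
#' @param genes List of [gene_model]s.
#' @param genome [seq_record] or named list of [seq_record]s keyed by contig.
#' @param tmh Optional named list (by gene id) of TMH tables from
#'   [predict_tmh].
#' @return Data frame with one row per call: `contig_id`, `pos`, `ref`,
#'   `alt`, `gene_id` (`NA` for intergenic calls), `category`,
#'   `protein_pos`, `ref_codon`, `alt_codon`, `in_tmh`.
#' @export
annotate_variants <- function(variants, genes, genome, tmh = NULL) {
  if (inherits(genome, "seq_record")) {
    genome <- setNames(list(genome), genome$id)
  }
  rows <- list()
  for (v in variants) {
    ctg <- genome[[v$contig_id]]
    if (is.null(ctg)) .stopf("no genome sequence for contig '%s'", v$contig_id)
    hit <- FALSE
    for (g in genes) {
      if (g$contig_id != v$contig_id) next
      span <- .gene_span(g)
      if (v$pos + nchar(v$ref) - 1L < span[[1L]] || v$pos > span[[2L]]) next
      cc <- classify_variant(v, g, ctg, tmh = tmh[[g$gene_id]])
      rows[[length(rows) + 1L]] <- as.data.frame(
        cc[c("contig_id", "pos", "ref", "alt", "gene_id", "category",
             "protein_pos", "ref_codon", "alt_codon", "in_tmh")],
        stringsAsFactors = FALSE)
      hit <- TRUE
    }
    if (!hit) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = v$contig_id, pos = v$pos, ref = v$ref, alt = v$alt,
        gene_id = NA_character_, category = "non_genic",
        protein_pos = NA_integer_, ref_codon = NA_character_,
        alt_codon = NA_character_, in_tmh = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(contig_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene_id = character(0), category = character(0),
                      protein_pos = integer(0), ref_codon = character(0),
                      alt_codon = character(0), in_tmh = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Per-gene variant summary
#'
#' Tallies consequence calls for one gene into a Table-of-SNPs style
#' summary: per-category counts, a total that excludes synonymous and
#' non-genic calls (only protein-affecting variants are counted), the
#' number and percentage of counted variants whose residue falls in a
#' transmembrane segment, and variant density per kilobase of gene span.
#'
#' @param calls Data frame from [annotate_variants], already filtered or
#'   filterable to one gene.
#' @param g The [gene_model] summarized.
#' @param tmh Optional TMH table from [predict_tmh]; when supplied, TMH
#'   overlap is recomputed from `protein_pos`, otherwise the `in_tmh`
#'   column of `calls` is used.
#' @return List of class `gene_variant_summary` with `gene_id`,
#'   `gene_length_bp`, `counts` (named integer vector over all categories),
#'   `total`, `tmh_count`, `tmh_pct` (1 decimal), `density_per_kb`
#'   (2 decimals).
#' @export
summarize_gene <- function(calls, g, tmh = NULL) {
  stopifnot(inherits(g, "gene_model"))
  calls <- calls[!is.na(calls$gene_id) & calls$gene_id == g$gene_id, ,
                 drop = FALSE]
  counts <- setNames(integer(length(.CONSEQUENCE_LEVELS)), .CONSEQUENCE_LEVELS)
  tb <- table(calls$category)
  counts[names(tb)] <- as.integer(tb)
  counted <- setdiff(.CONSEQUENCE_LEVELS, c("synonymous", "non_genic"))
  total <- sum(counts[counted])
  in_tmh <- if (!is.null(tmh)) {
    !is.na(calls$protein_pos) &
      vapply(calls$protein_pos, function(p) {
        !is.na(p) && nrow(tmh) > 0L && any(p >= tmh$start & p <= tmh$end)
      }, logical(1L))
  } else calls$in_tmh
  tmh_count <- sum(in_tmh & calls$category %in% counted)
  span <- .gene_span(g)
  glen <- span[[2L]] - span[[1L]] + 1L
  structure(list(
    gene_id = g$gene_id, gene_length_bp = glen, counts = counts,
    total = as.integer(total), tmh_count = as.integer(tmh_count),
    tmh_pct = tmh_overlap_pct(tmh_count, total),
    density_per_kb = variant_density_per_kb(total, glen)),
    class = "gene_variant_summary")
}

#' TMH-overlap percentage
#'
#' `100 * tmh_count / total` to one decimal; 0 when `total` is 0.
#'
#' @param tmh_count Variants falling in transmembrane segments.
#' @param total Counted (protein-affecting) variants.
#' @export
tmh_overlap_pct <- function(tmh_count, total) {
  if (total == 0) return(0)
  round(100 * tmh_count / total, 1L)
}

#' Variant density per kilobase
#'
#' `1000 * total / gene_length_bp` to two decimals.
#'
#' @param total Counted variants.
#' @param gene_length_bp Gene span in bp.
#' @export
variant_density_per_kb <- function(total, gene_length_bp) {
  if (!(gene_length_bp > 0)) .stopf("gene length must be positive")
  round(1000 * total / gene_length_bp, 2L)
}

#' @export
print.gene_variant_summary <- function(x, ...) {
  cat(sprintf("<variant summary %s: %d counted, %d in TMH (%.1f%%), %.2f per kb>\n",
              x$gene_id, x$total, x$tmh_count, x$tmh_pct, x$density_per_kb))
  invisible(x)
}

#' Alternate-allele frequency of a variant
#'
#' Alt allele count over `2 *` the number of non-missing diploid genotypes;
#' missing calls (`./.`) are excluded from the denominator.
#'
#' @param v A [variant_record] with at least one non-missing genotype.
#' @return Frequency in `[0, 1]`.
#' @export
allele_frequency <- function(v) {
  stopifnot(inherits(v, "variant_record"))
  gt <- v$genotypes[v$genotypes != "./."]
  if (length(gt) == 0L) .stopf("all genotypes missing for %s:%d", v$contig_id, v$pos)
  alt <- sum(c(`0/0` = 0L, `0/1` = 1L, `1/1` = 2L)[gt])
  alt / (2 * length(gt))
}
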