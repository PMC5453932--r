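#' Variant records
#'
#' A `variant_record` holds one bi-allelic variant: contig, 1-based position
#' of the first affected base, ref/alt alleles, and per-sample diploid
#' genotype calls in `{0/0, 0/1, 1/1, ./.}`.
#'
#' @param contig_id,pos,ref,alt Variant coordinates and alleles.
#' @param genotypes Character vector of diploid calls; phased separators are
#'   normalized to unphased.
#' @return Object of class `variant_record`.
#' @export
variant_record <- function(contig_id, pos, ref, alt,
                           genotypes = character(0)) {
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) .stopf("variant pos must be >= 1")
  ref <- toupper(ref); alt <- toupper(alt)
  if (!nzchar(ref) || !nzchar(alt)) .stopf("ref and alt must be non-empty")
  if (ref == alt) .stopf("ref and alt must differ")
  if (grepl(",", alt, fixed = TRUE)) {
    .stopf("multi-allelic ALT '%s' at %s:%d; split into bi-allelic records first",
           alt, contig_id, pos)
  }
  genotypes <- gsub("|", "/", genotypes, fixed = TRUE)
  genotypes[genotypes %in% c(".", "./.")] <- "./."
  bad <- setdiff(unique(genotypes), c("0/0", "0/1", "1/0", "1/1", "./."))
  if (length(bad) > 0L) .stopf("unsupported genotype '%s'", bad[[1L]])
  genotypes[genotypes == "1/0"] <- "0/1"
  structure(list(contig_id = contig_id, pos = pos, ref = ref, alt = alt,
                 genotypes = genotypes),
            class = "variant_record")
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("<variant %s:%d %s>%s, %d genotype(s)>\n", x$contig_id, x$pos,
              x$ref, x$alt, length(x$genotypes)))
  invisible(x)
}

#' Read variants from VCF
#'
#' Reads a VCF v4.x subset (single ALT per row, GT in FORMAT) into a list of
#' [variant_record]s. Phased genotype separators are treated as unphased;
#' multi-allelic rows are rejected with a message advising an upstream split.
#'
#' @param text VCF text or a file path.
#' @return List of [variant_record]s in file order.
#' @export
read_vcf <- function(text) {
  path <- .as_file(text, ".vcf")
  v <- tryCatch(suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
                error = function(e) .stopf("malformed VCF: %s", conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) .stopf("VCF contains no variant rows")
  gt <- v@gt
  has_samples <- !is.null(gt) && ncol(gt) > 1L
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    genos <- character(0)
    if (has_samples) {
      fmt <- strsplit(gt[i, 1L], ":", fixed = TRUE)[[1L]]
      gt_idx <- match("GT", fmt)
      if (is.na(gt_idx)) .stopf("row %d: FORMAT has no GT field", i)
      genos <- vapply(gt[i, -1L], function(cell) {
        strsplit(cell, ":", fixed = TRUE)[[1L]][gt_idx]
      }, character(1L), USE.NAMES = FALSE)
    }
    out[[i]] <- variant_record(unname(fix[i, "CHROM"]),
                               as.integer(fix[i, "POS"]),
                               unname(fix[i, "REF"]), unname(fix[i, "ALT"]),
                               genos)
  }
  out
}

#' Write variants to VCF text
#'
#' Minimal VCF v4.2 writer for [variant_record]s sharing one sample panel.
#'
#' @param variants List of [variant_record]s.
#' @param path Optional output path; text returned when `NULL`.
#' @param sample_ids Sample names; defaults to `S1..Sn`.
#' @export
write_vcf <- function(variants, path = NULL, sample_ids = NULL) {
  n_s <- if (length(variants) > 0L) length(variants[[1L]]$genotypes) else 0L
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(n_s))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", if (n_s > 0L) c("FORMAT", sample_ids)),
                    collapse = "\t"))
  rows <- vapply(variants, function(v) {
    stopifnot(length(v$genotypes) == n_s)
    paste(c(v$contig_id, v$pos, ".", v$ref, v$alt, ".", "PASS", ".",
            if (n_s > 0L) c("GT", v$genotypes)), collapse = "\t")
  }, character(1L))
  lines <- c(header, rows)
  if (is.null(path)) return(paste0(paste(lines, collapse = "\n"), "\n"))
  writeLines(lines, path)
  invisible(path)
}
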