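#' Sequence records
#'
#' A `seq_record` is the light-weight container used throughout the package
#' for a single named sequence: a list with elements `id`, `residues`
#' (uppercase, no whitespace) and `alphabet` (`"dna"` or `"protein"`).
#'
#' @param id Sequence identifier (single string).
#' @param residues Residue string; uppercased on construction.
#' @param alphabet `"dna"`, `"protein"`, or `NULL` to infer: sequences over
#'   `{A,C,G,T,N}` are called DNA, anything else protein.
#' @param allow_empty Permit an empty residue string (used by a few
#'   intermediate operations); default `FALSE`.
#' @return An object of class `seq_record`.
#' @examples
#' seq_record("g1", "acgt")
#' @export
seq_record <- function(id, residues, alphabet = NULL, allow_empty = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    .stopf("sequence id must be a non-empty string")
  }
  if (!is.character(residues) || length(residues) != 1L) {
    .stopf("residues must be a single string")
  }
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!allow_empty && !nzchar(residues)) {
    .stopf("sequence '%s' is empty", id)
  }
  if (is.null(alphabet)) {
    alphabet <- if (grepl("^[ACGTN]*$", residues)) "dna" else "protein"
  }
  alphabet <- match.arg(alphabet, c("dna", "protein"))
  if (alphabet == "dna" && !grepl("^[ACGTN]*$", residues)) {
    .stopf("sequence '%s' declared dna but contains non-ACGTN characters", id)
  }
  structure(list(id = id, residues = residues, alphabet = alphabet),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  res <- x$residues
  shown <- if (nchar(res) > 60) paste0(substr(res, 1, 57), "...") else res
  cat(sprintf("<seq_record %s [%s, %d]> %s\n", x$id, x$alphabet,
              nchar(res), shown))
  invisible(x)
}

# is `x` likely a path rather than raw record text?
.looks_like_path <- function(x) {
  length(x) == 1L && !grepl("[\n>]", x) && file.exists(x)
}

.as_text <- function(text_or_path) {
  if (length(text_or_path) > 1L) {
    return(paste(text_or_path, collapse = "\n"))
  }
  if (.looks_like_path(text_or_path)) {
    return(paste(readLines(text_or_path, warn = FALSE), collapse = "\n"))
  }
  text_or_path
}

# materialise text input as a file so Bioconductor readers can be used
.as_file <- function(text_or_path, ext) {
  if (length(text_or_path) == 1L && .looks_like_path(text_or_path)) {
    return(text_or_path)
  }
  path <- tempfile(fileext = ext)
  writeLines(.as_text(text_or_path), path)
  path
}

#' Read FASTA sequences
#'
#' Reads FASTA text (or a file path) into a list of [seq_record]s. The header
#' token up to the first whitespace is taken as the id; residues are
#' uppercased with line breaks removed, and input order is preserved.
#'
#' @param text_or_path FASTA text (single string or character vector of
#'   lines) or a path to a FASTA file.
#' @param alphabet Optional alphabet forced onto every record; inferred per
#'   record when `NULL`.
#' @return List of [seq_record]s.
#' @examples
#' read_fasta(">g1\nacgT\n")
#' @export
read_fasta <- function(text_or_path, alphabet = NULL) {
  path <- .as_file(text_or_path, ".fa")
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) .stopf("malformed FASTA: %s", conditionMessage(e)))
  if (length(set) == 0L) .stopf("empty FASTA input")
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) .stopf("duplicate FASTA id '%s'", dup[[1L]])
  recs <- lapply(seq_along(set), function(i) {
    seq_record(ids[[i]], as.character(set[[i]]), alphabet = alphabet)
  })
  recs
}

#' Write FASTA sequences
#'
#' @param records A [seq_record] or list of them.
#' @param path Optional output path; when `NULL` the FASTA text is returned.
#' @param width Line-wrap width for residues.
#' @return The path (invisibly) when `path` is given, otherwise FASTA text.
#' @export
write_fasta <- function(records, path = NULL, width = 70L) {
  if (inherits(records, "seq_record")) records <- list(records)
  lines <- unlist(lapply(records, function(r) {
    stopifnot(inherits(r, "seq_record"))
    body <- substring(r$residues,
                      seq(1L, nchar(r$residues), by = width),
                      pmin(seq(1L, nchar(r$residues), by = width) + width - 1L,
                           nchar(r$residues)))
    c(paste0(">", r$id), body)
  }))
  if (is.null(path)) return(paste0(paste(lines, collapse = "\n"), "\n"))
  writeLines(lines, path)
  invisible(path)
}

# reverse complement of a plain DNA string
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# split a CDS string into codons; errors if length not divisible by 3
.codons <- function(x, what = "sequence") {
  n <- nchar(x)
  if (n %% 3L != 0L) .stopf("%s length %d is not divisible by 3", what, n)
  substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# translate a vector of codons with the standard code; gaps '---' -> '-'
.translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- ifelse(codons == "---", "-", unname(gc[codons]))
  if (anyNA(aa)) {
    bad <- which(is.na(aa))[[1L]]
    .stopf("cannot translate codon '%s' at codon position %d", codons[[bad]], bad)
  }
  aa
}

# translate a CDS string, trimming one trailing stop codon if present
.translate_cds <- function(cds, id = "cds", trim_stop = TRUE) {
  codons <- .codons(cds, what = id)
  aa <- .translate_codons(codons)
  if (trim_stop && length(aa) > 0L && aa[[length(aa)]] == "*") {
    aa <- aa[-length(aa)]
  }
  if (any(aa == "*")) {
    .stopf("internal stop codon at codon %d of '%s'", which(aa == "*")[[1L]], id)
  }
  paste(aa, collapse = "")
}
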