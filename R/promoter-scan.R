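
# IUPAC nucleotide code expansion
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.check_iupac <- function(consensus) {
  codes <- strsplit(toupper(consensus), "")[[1L]]
  bad <- setdiff(codes, names(.IUPAC_SETS))
  if (length(bad) > 0L) .stopf("invalid IUPAC code '%s' in '%s'", bad[[1L]], consensus)
  codes
}

# consensus -> regex of character classes
.iupac_regex <- function(consensus) {
  codes <- .check_iupac(consensus)
  paste(vapply(codes, function(cd) {
    set <- .IUPAC_SETS[[cd]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1L)), collapse = "")
}

#' Match a sequence against an IUPAC consensus
#'
#' @param consensus IUPAC consensus string.
#' @param subseq Concrete sequence of the same length over `{A,C,G,T}`.
#' @return `TRUE` iff every base belongs to the corresponding code's set.
#' @examples
#' iupac_match("AYGR", "ATGA")  # TRUE
#' @export
iupac_match <- function(consensus, subseq) {
  codes <- .check_iupac(consensus)
  bases <- strsplit(toupper(subseq), "")[[1L]]
  if (length(codes) != length(bases)) {
    .stopf("consensus and subsequence lengths differ (%d vs %d)",
           length(codes), length(bases))
  }
  all(mapply(function(cd, b) b %in% .IUPAC_SETS[[cd]], codes, bases))
}

#' Load a cis-element consensus library
#'
#' Reads a JSON element library (`{"elements": [{"name", "consensus",
#' "source_note"}, ...]}`). Without a path, the packaged default library is
#' used (ABRE, HSE, ARE, MBS, Box-W1, TC-rich consensus patterns).
#'
#' @param path Optional path to a JSON library.
#' @return Data frame with columns `name`, `consensus`, `source_note`.
#' @export
load_element_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cis_elements.json", package = "nhxdiverge")
  }
  lib <- jsonlite::fromJSON(path)$elements
  stopifnot(is.data.frame(lib), all(c("name", "consensus") %in% colnames(lib)))
  for (cons in lib$consensus) .check_iupac(cons)
  lib
}

# all (overlapping) start positions of an IUPAC consensus in sequence `s`
.scan_positions <- function(s, consensus) {
  rx <- paste0("(?=(", .iupac_regex(consensus), "))")
  m <- gregexpr(rx, s, perl = TRUE)[[1L]]
  if (m[[1L]] == -1L) integer(0) else as.integer(m)
}

#' Scan a promoter for cis-acting elements
#'
#' Reports every match of every element consensus on the requested
#' strand(s) of a promoter returned by [extract_promoter]. Minus-strand
#' matches are found by scanning the reverse complement and reported at the
#' promoter coordinate of their 5'-most base on the promoter (sense)
#' strand. Positions are TSS-relative: negative upstream, `+1` is the TSS,
#' there is no position 0.
#'
#' @param promoter [seq_record] from [extract_promoter] (carries the TSS
#'   offset metadata), or any DNA [seq_record] (then positions are
#'   string-relative with `+1` at base 1).
#' @param library Element library data frame from [load_element_library],
#'   with columns `name` and `consensus`.
#' @param strands `"both"`, `"+"` or `"-"`.
#' @return Data frame of hits: `gene_id`, `element`, `position`, `strand`,
#'   `matched`; zero rows when nothing matches.
#' @export
scan_elements <- function(promoter, library, strands = c("both", "+", "-")) {
  stopifnot(inherits(promoter, "seq_record"))
  strands <- match.arg(strands)
  if (promoter$alphabet != "dna") .stopf("promoter must be a DNA sequence")
  gene_id <- attr(promoter, "gene_id")
  if (is.null(gene_id)) gene_id <- promoter$id
  up <- attr(promoter, "upstream")
  if (is.null(up)) up <- 0L
  s <- promoter$residues
  L <- nchar(s)
  rc <- .revcomp(s)
  empty <- data.frame(gene_id = character(0), element = character(0),
                      position = integer(0), strand = character(0),
                      matched = character(0), stringsAsFactors = FALSE)
  if (is.null(library) || nrow(library) == 0L) return(empty)
  to_rel <- function(i) ifelse(i > up, i - up, i - up - 1L)
  rows <- list(empty)
  for (r in seq_len(nrow(library))) {
    cons <- toupper(library$consensus[[r]])
    w <- nchar(cons)
    if (strands %in% c("both", "+")) {
      pos <- .scan_positions(s, cons)
      if (length(pos) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gene_id, element = library$name[[r]],
          position = to_rel(pos), strand = "+",
          matched = substring(s, pos, pos + w - 1L), stringsAsFactors = FALSE)
      }
    }
    if (strands %in% c("both", "-")) {
      pos_rc <- .scan_positions(rc, cons)
      if (length(pos_rc) > 0L) {
        fivep <- L - (pos_rc + w - 1L) + 1L   # 5'-most base on sense strand
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gene_id, element = library$name[[r]],
          position = to_rel(fivep), strand = "-",
          matched = substring(rc, pos_rc, pos_rc + w - 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$element, out$position, out$strand), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Tally element hits per gene
#'
#' @param hits Hit table from [scan_elements] (possibly rbind-ed over
#'   genes).
#' @param genes Character vector of gene ids defining the table rows.
#' @param elements Character vector of element names defining the columns
#'   (defaults to those present in `hits`).
#' @return Integer matrix of counts, genes x elements.
#' @export
element_tally <- function(hits, genes, elements = NULL) {
  if (is.null(elements)) elements <- sort(unique(hits$element))
  tab <- matrix(0L, length(genes), length(elements),
                dimnames = list(genes, elements))
  if (nrow(hits) == 0L) return(tab)
  unknown <- setdiff(unique(hits$gene_id), genes)
  if (length(unknown) > 0L) {
    .stopf("hit references unknown gene '%s'", unknown[[1L]])
  }
  for (i in seq_len(nrow(hits))) {
    el <- hits$element[[i]]
    if (!el %in% elements) next
    tab[hits$gene_id[[i]], el] <- tab[hits$gene_id[[i]], el] + 1L
  }
  tab
}
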