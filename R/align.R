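#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment with match/mismatch scoring and a
#' linear gap penalty, computed via [Biostrings::pairwiseAlignment]. The
#' traceback is deterministic, so repeated calls give identical alignments.
#'
#' @param a,b [seq_record]s of the same alphabet.
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (<= 0).
#' @param gap Per-position gap penalty (< 0, linear).
#' @return An `alignment_pair`: list with `seq_a_id`, `seq_b_id`,
#'   `aligned_a`, `aligned_b` (equal-length gapped strings) and `score`.
#' @examples
#' a <- seq_record("a", "AAG"); b <- seq_record("b", "AG")
#' global_align(a, b, match = 1, mismatch = -1, gap = -1)
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  stopifnot(inherits(a, "seq_record"), inherits(b, "seq_record"))
  if (!nzchar(a$residues) || !nzchar(b$residues)) {
    .stopf("cannot align an empty sequence")
  }
  if (a$alphabet != b$alphabet) {
    .stopf("alphabet mismatch: '%s' is %s, '%s' is %s",
           a$id, a$alphabet, b$id, b$alphabet)
  }
  if (!(match > 0) || !(mismatch <= 0) || !(gap < 0)) {
    .stopf("require match > 0, mismatch <= 0, gap < 0")
  }
  letters_used <- sort(unique(strsplit(paste0(a$residues, b$residues), "")[[1L]]))
  sm <- matrix(mismatch, length(letters_used), length(letters_used),
               dimnames = list(letters_used, letters_used))
  diag(sm) <- match
  # canonicalize the argument order before aligning so that tie-breaking in
  # the traceback cannot depend on which sequence came first; the alignment
  # (and hence percent identity) is then exactly symmetric
  swapped <- (a$residues > b$residues) ||
    (a$residues == b$residues && a$id > b$id)
  x <- if (swapped) b else a
  y <- if (swapped) a else b
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::BString(x$residues), Biostrings::BString(y$residues),
    substitutionMatrix = sm, gapOpening = 0, gapExtension = -gap,
    type = "global")
  al_x <- as.character(Biostrings::alignedPattern(pa))
  al_y <- as.character(Biostrings::alignedSubject(pa))
  structure(list(seq_a_id = a$id, seq_b_id = b$id,
                 aligned_a = if (swapped) al_y else al_x,
                 aligned_b = if (swapped) al_x else al_y,
                 score = Biostrings::score(pa)),
            class = "alignment_pair")
}

#' @export
print.alignment_pair <- function(x, ...) {
  cat(sprintf("<alignment %s/%s, length %d, score %g>\n", x$seq_a_id,
              x$seq_b_id, nchar(x$aligned_a), x$score))
  invisible(x)
}

#' Percent identity of an aligned pair
#'
#' Identity is counted over all alignment columns (gapped columns count as
#' mismatches) and reported to one decimal, i.e.
#' `100 * identical columns / alignment length`.
#'
#' @param pair An `alignment_pair` from [global_align].
#' @return Percentage in `[0, 100]`, rounded to 1 decimal.
#' @export
percent_identity <- function(pair) {
  stopifnot(inherits(pair, "alignment_pair"))
  ca <- strsplit(pair$aligned_a, "")[[1L]]
  cb <- strsplit(pair$aligned_b, "")[[1L]]
  stopifnot(length(ca) == length(cb))
  ident <- sum(ca == cb & ca != "-")
  round(100 * ident / length(ca), 1L)
}

#' Pairwise identity matrix
#'
#' All-against-all [global_align] + [percent_identity] over a set of
#' sequences; the diagonal is 100.
#'
#' @param records List of [seq_record]s (same alphabet).
#' @inheritParams global_align
#' @return Symmetric numeric matrix of percent identities.
#' @export
identity_matrix <- function(records, match = 1, mismatch = -1, gap = -1) {
  ids <- vapply(records, function(r) r$id, character(1L))
  n <- length(records)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        pid <- percent_identity(global_align(records[[i]], records[[j]],
                                             match, mismatch, gap))
        m[i, j] <- pid
        m[j, i] <- pid
      }
    }
  }
  m
}
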