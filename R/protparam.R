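
# average residue masses (Da) for the 20 standard amino acids; a peptide's
# mass is the sum of residue masses plus one water (18.0153 Da)
.AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

.WATER_MASS <- 18.0153

# EMBOSS default pKa values (iep); basic groups gain a proton when pH < pKa
.EMBOSS_PKA <- c(Nterm = 8.6, Cterm = 3.6,
                 C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5,
                 Y = 10.1)

#' Deduced protein length from CDS length
#'
#' The ORF of a CDS including its stop codon encodes `cds_len_bp / 3 - 1`
#' amino acids (the stop codon is excluded).
#'
#' @param cds_len_bp CDS length in base pairs; must be divisible by 3 and
#'   at least 6.
#' @return Protein length in amino acids (integer).
#' @examples
#' deduced_protein_length(1635)  # 544 aa
#' @export
deduced_protein_length <- function(cds_len_bp) {
  cds_len_bp <- as.integer(cds_len_bp)
  if (any(is.na(cds_len_bp)) || any(cds_len_bp < 6L)) {
    .stopf("cds_len_bp must be >= 6")
  }
  if (any(cds_len_bp %% 3L != 0L)) {
    .stopf("CDS length %d is not divisible by 3",
           cds_len_bp[cds_len_bp %% 3L != 0L][[1L]])
  }
  cds_len_bp %/% 3L - 1L
}

#' Protein molecular weight (average mass)
#'
#' Sum of average residue masses plus one water mass (18.0153 Da).
#'
#' @param seq A protein [seq_record] over the 20 standard amino acids.
#' @return Mass in Daltons.
#' @export
molecular_weight <- function(seq) {
  stopifnot(inherits(seq, "seq_record"))
  if (seq$alphabet != "protein") .stopf("molecular_weight needs a protein sequence")
  aa <- strsplit(seq$residues, "")[[1L]]
  masses <- .AA_AVG_MASS[aa]
  if (anyNA(masses)) {
    bad <- which(is.na(masses))[[1L]]
    .stopf("non-standard residue '%s' at position %d of '%s'",
           aa[[bad]], bad, seq$id)
  }
  sum(masses) + .WATER_MASS
}

# net Henderson-Hasselbalch charge of a protein at a given pH
.protein_charge <- function(counts, pH, pKa) {
  pos_groups <- c("Nterm", "H", "K", "R")
  neg_groups <- c("Cterm", "C", "D", "E", "Y")
  q <- 0
  for (g in pos_groups) {
    n <- counts[[g]]
    if (n > 0) q <- q + n / (1 + 10^(pH - pKa[[g]]))
  }
  for (g in neg_groups) {
    n <- counts[[g]]
    if (n > 0) q <- q - n / (1 + 10^(pKa[[g]] - pH))
  }
  q
}

#' Isoelectric point
#'
#' The pH at which the net Henderson-Hasselbalch charge of the protein
#' (free termini assumed) crosses zero, found by bisection on `[0, 14]` to a
#' residual charge below `tol`. The charge is strictly decreasing in pH, so
#' the root is unique. pKa values default to the EMBOSS set and can be
#' overridden.
#'
#' @param seq A protein [seq_record] over the standard amino acids.
#' @param pKa Named vector of pKa values; must contain `Nterm`, `Cterm` and
#'   the ionizable residues `C, D, E, H, K, R, Y`.
#' @param tol Bisection tolerance on the absolute charge.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pKa = .EMBOSS_PKA, tol = 1e-4) {
  stopifnot(inherits(seq, "seq_record"))
  if (seq$alphabet != "protein") .stopf("isoelectric_point needs a protein sequence")
  aa <- strsplit(seq$residues, "")[[1L]]
  if (!all(aa %in% names(.AA_AVG_MASS))) {
    .stopf("non-standard residue in '%s'", seq$id)
  }
  counts <- c(Nterm = 1, Cterm = 1,
              vapply(c("C", "D", "E", "H", "K", "R", "Y"),
                     function(g) sum(aa == g), numeric(1L)))
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- .protein_charge(counts, mid, pKa)
    if (abs(q) < tol || (hi - lo) < 1e-12) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}
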