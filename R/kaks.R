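
# --- codon bookkeeping -----------------------------------------------------
# Tables used by the Nei-Gojobori (1986) estimator are built once and cached:
#  * per sense codon, the fractional number of synonymous sites (stop-codon
#    changes excluded from the per-position denominators, so each codon still
#    carries exactly 3 sites);
#  * per ordered pair of sense codons, the synonymous/nonsynonymous
#    difference counts averaged with equal weight over all minimal mutational
#    pathways, pathways passing through a stop codon excluded (unless every
#    pathway does, in which case all are used).

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.codon_tables <- function() {
  if (!is.null(.nhx_cache$codon_tables)) return(.nhx_cache$codon_tables)
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  gc <- Biostrings::GENETIC_CODE
  sense <- setdiff(all64, .STOP_CODONS)
  aa <- gc[all64]

  mutate1 <- function(codon, pos, base) {
    substr(codon, pos, pos) <- base
    codon
  }

  # synonymous site fraction per codon
  syn_sites <- vapply(sense, function(cod) {
    total <- 0
    for (pos in 1:3) {
      ref_base <- substr(cod, pos, pos)
      alts <- vapply(setdiff(bases, ref_base), mutate1, character(1L),
                     codon = cod, pos = pos)
      alts <- alts[!alts %in% .STOP_CODONS]
      if (length(alts) == 0L) next
      total <- total + sum(gc[alts] == gc[[cod]]) / length(alts)
    }
    total
  }, numeric(1L))

  # pathway-averaged difference counts for ordered sense-codon pairs
  nsense <- length(sense)
  sd_mat <- matrix(0, nsense, nsense, dimnames = list(sense, sense))
  nd_mat <- sd_mat
  perms2 <- list(c(1L, 2L), c(2L, 1L))
  perms3 <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                 c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  for (i in seq_len(nsense)) {
    for (j in seq_len(nsense)) {
      if (i == j) next
      c1 <- sense[[i]]; c2 <- sense[[j]]
      diff_pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
      k <- length(diff_pos)
      orders <- switch(k, list(1L), perms2, perms3)
      paths <- lapply(orders, function(ord) {
        cur <- c1
        steps <- matrix(character(0), ncol = 2L)
        for (p in diff_pos[ord]) {
          nxt <- mutate1(cur, p, substr(c2, p, p))
          steps <- rbind(steps, c(cur, nxt))
          cur <- nxt
        }
        steps
      })
      through_stop <- vapply(paths, function(st) {
        any(st[, 2L][-nrow(st)] %in% .STOP_CODONS)
      }, logical(1L))
      use <- if (all(through_stop)) paths else paths[!through_stop]
      sdnd <- vapply(use, function(st) {
        syn <- gc[st[, 1L]] == gc[st[, 2L]]
        c(sum(syn), sum(!syn))
      }, numeric(2L))
      sd_mat[i, j] <- mean(sdnd[1L, ])
      nd_mat[i, j] <- mean(sdnd[2L, ])
    }
  }
  .nhx_cache$codon_tables <- list(sense = sense, syn_sites = syn_sites,
                                  sd = sd_mat, nd = nd_mat)
  .nhx_cache$codon_tables
}

# --- codon alignments ------------------------------------------------------

#' Codon alignment
#'
#' Gap-aware pair of in-frame coding sequences: two equal-length codon
#' vectors over `{A,C,G,T}` 3-mers, with gaps only as whole-codon `"---"`,
#' no column gapped in both, and no internal stop codon in either ungapped
#' sequence.
#'
#' @param id_a,id_b Sequence identifiers.
#' @param codons_a,codons_b Character vectors of codons/`"---"`.
#' @return Object of class `codon_alignment`.
#' @export
codon_alignment <- function(id_a, id_b, codons_a, codons_b) {
  if (length(codons_a) != length(codons_b)) {
    .stopf("codon vectors must have equal length")
  }
  ok <- function(x) all(grepl("^([ACGT]{3}|---)$", x))
  if (!ok(codons_a) || !ok(codons_b)) {
    .stopf("codons must be ACGT 3-mers or whole-codon gaps '---'")
  }
  if (any(codons_a == "---" & codons_b == "---")) {
    .stopf("column gapped in both sequences")
  }
  for (x in list(a = codons_a, b = codons_b)) {
    real <- x[x != "---"]
    stops <- which(real %in% .STOP_CODONS)
    if (any(stops < length(real))) .stopf("internal stop codon in alignment")
  }
  structure(list(id_a = id_a, id_b = id_b,
                 codons_a = codons_a, codons_b = codons_b),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment %s/%s, %d codon columns>\n",
              x$id_a, x$id_b, length(x$codons_a)))
  invisible(x)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Maps each aligned amino-acid column onto its source codon (protein gaps
#' become `"---"`), after verifying that each ungapped protein translates
#' exactly from its CDS under the standard genetic code (one trailing stop
#' codon is allowed and trimmed). This is the conversion performed by
#' PAL2NAL-style tools.
#'
#' @param aligned_prot_a,aligned_prot_b Equal-length gapped protein strings
#'   (or `alignment_pair` from [global_align] in place of `aligned_prot_a`).
#' @param cds_a,cds_b Coding sequences ([seq_record]s or plain strings).
#' @param id_a,id_b Identifiers used when CDSs are plain strings.
#' @return A [codon_alignment].
#' @export
back_translate <- function(aligned_prot_a, aligned_prot_b, cds_a, cds_b,
                           id_a = "seq_a", id_b = "seq_b") {
  if (inherits(aligned_prot_a, "alignment_pair")) {
    pair <- aligned_prot_a
    cds_b <- cds_a; cds_a <- aligned_prot_b
    aligned_prot_a <- pair$aligned_a; aligned_prot_b <- pair$aligned_b
    id_a <- pair$seq_a_id; id_b <- pair$seq_b_id
  }
  get_cds <- function(x) if (inherits(x, "seq_record")) x$residues else toupper(x)
  get_id <- function(x, fallback) if (inherits(x, "seq_record")) x$id else fallback
  id_a <- get_id(cds_a, id_a); id_b <- get_id(cds_b, id_b)
  cds_a <- get_cds(cds_a); cds_b <- get_cds(cds_b)
  if (nchar(aligned_prot_a) != nchar(aligned_prot_b)) {
    .stopf("aligned proteins must have equal length")
  }
  one_side <- function(aligned, cds, id) {
    prot <- gsub("-", "", aligned, fixed = TRUE)
    nres <- nchar(prot)
    if (!(nchar(cds) %in% c(3L * nres, 3L * nres + 3L))) {
      .stopf("CDS '%s' length %d does not match protein length %d",
             id, nchar(cds), nres)
    }
    codons <- .codons(cds, what = id)
    aa <- .translate_codons(codons)
    if (length(aa) == nres + 1L) {
      if (aa[[length(aa)]] != "*") {
        .stopf("CDS '%s' has an extra codon that is not a stop", id)
      }
      codons <- codons[-length(codons)]
      aa <- aa[-length(aa)]
    }
    mism <- which(aa != strsplit(prot, "")[[1L]])
    if (length(mism) > 0L) {
      .stopf("CDS '%s' translation mismatch at residue %d ('%s' vs '%s')",
             id, mism[[1L]], aa[[mism[[1L]]]],
             substr(prot, mism[[1L]], mism[[1L]]))
    }
    cols <- strsplit(aligned, "")[[1L]]
    out <- character(length(cols))
    k <- 0L
    for (i in seq_along(cols)) {
      if (cols[[i]] == "-") {
        out[[i]] <- "---"
      } else {
        k <- k + 1L
        out[[i]] <- codons[[k]]
      }
    }
    out
  }
  codon_alignment(id_a, id_b,
                  one_side(aligned_prot_a, cds_a, id_a),
                  one_side(aligned_prot_b, cds_b, id_b))
}

# --- the NG86 estimator ----------------------------------------------------

#' Nei-Gojobori (1986) Ka/Ks estimate
#'
#' Counting estimator of synonymous (`Ks`) and nonsynonymous (`Ka`)
#' substitution rates on a pairwise codon alignment. Synonymous site
#' fractions are computed per codon position as the fraction of one-step
#' changes (mutations to stop codons excluded) that preserve the amino
#' acid, and averaged between the two sequences; differences are averaged
#' with equal weight over all minimal mutational pathways between differing
#' codons (pathways through stop codons excluded unless all are). The
#' proportions `pS = Sd/S` and `pN = Nd/N` are Jukes-Cantor corrected:
#' `Ks = -3/4 * log(1 - 4/3 * pS)`, likewise `Ka`. Gapped columns are
#' excluded pairwise.
#'
#' @param aln A [codon_alignment] with at least one gap-free column.
#' @return Object of class `kaks_estimate`: list with `S_sites`, `N_sites`,
#'   `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `ratio` (`NA` when `Ks` is 0) and
#'   `n_codons` (compared columns).
#' @export
ng86_kaks <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  tabs <- .codon_tables()
  keep <- aln$codons_a != "---" & aln$codons_b != "---"
  a <- aln$codons_a[keep]; b <- aln$codons_b[keep]
  if (length(a) == 0L) .stopf("no gap-free codon columns to compare")
  if (any(a %in% .STOP_CODONS) || any(b %in% .STOP_CODONS)) {
    .stopf("stop codon among compared columns")
  }
  S <- (sum(tabs$syn_sites[a]) + sum(tabs$syn_sites[b])) / 2
  N <- 3 * length(a) - S
  diff <- which(a != b)
  Sd <- 0; Nd <- 0
  if (length(diff) > 0L) {
    Sd <- sum(tabs$sd[cbind(a[diff], b[diff])])
    Nd <- sum(tabs$nd[cbind(a[diff], b[diff])])
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p, what) {
    if (p >= 0.75) {
      .stopf("%s proportion %.3f at or beyond Jukes-Cantor saturation", what, p)
    }
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(pS, "synonymous difference")
  Ka <- jc(pN, "nonsynonymous difference")
  ratio <- if (Ks > 0) Ka / Ks else NA_real_
  structure(list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, Ks = Ks, Ka = Ka, ratio = ratio,
                 n_codons = length(a)),
            class = "kaks_estimate")
}

#' @export
print.kaks_estimate <- function(x, ...) {
  cat(sprintf(paste0("<kaks_estimate over %d codons: S=%.2f N=%.2f ",
                     "Sd=%.2f Nd=%.2f Ka=%.4f Ks=%.4f Ka/Ks=%s>\n"),
              x$n_codons, x$S_sites, x$N_sites, x$Sd, x$Nd, x$Ka, x$Ks,
              if (is.na(x$ratio)) "undefined" else sprintf("%.3f", x$ratio)))
  invisible(x)
}

#' Sliding-window Ka/Ks scan
#'
#' Applies [ng86_kaks] to codon-aligned windows along the alignment. Windows
#' where the estimate is unavailable (no gap-free columns, or difference
#' proportions at Jukes-Cantor saturation) carry `NA` rates; windows with
#' `Ks = 0` carry an `NA` ratio.
#'
#' @param aln A [codon_alignment].
#' @param window_bp Window size in alignment bp, divisible by 3 (60 and 90
#'   are the conventional scan sizes).
#' @param step_bp Step in bp, divisible by 3 (default 6, i.e. 2 codons).
#' @return Data frame with `start_codon`, `end_codon`, `S`, `N`, `Sd`, `Nd`,
#'   `Ka`, `Ks`, `ratio`.
#' @export
sliding_window_kaks <- function(aln, window_bp = 60L, step_bp = 6L) {
  stopifnot(inherits(aln, "codon_alignment"))
  window_bp <- as.integer(window_bp); step_bp <- as.integer(step_bp)
  if (window_bp %% 3L != 0L || step_bp %% 3L != 0L || step_bp < 3L) {
    .stopf("window_bp and step_bp must be positive and divisible by 3")
  }
  ncod <- length(aln$codons_a)
  wc <- window_bp %/% 3L
  sc <- step_bp %/% 3L
  if (wc > ncod) .stopf("window (%d codons) exceeds alignment (%d codons)", wc, ncod)
  starts <- seq(1L, ncod - wc + 1L, by = sc)
  rows <- lapply(starts, function(s) {
    idx <- s:(s + wc - 1L)
    est <- tryCatch(
      ng86_kaks(codon_alignment(aln$id_a, aln$id_b,
                                aln$codons_a[idx], aln$codons_b[idx])),
      error = function(e) NULL)
    if (is.null(est)) {
      data.frame(start_codon = s, end_codon = s + wc - 1L, S = NA_real_,
                 N = NA_real_, Sd = NA_real_, Nd = NA_real_, Ka = NA_real_,
                 Ks = NA_real_, ratio = NA_real_)
    } else {
      data.frame(start_codon = s, end_codon = s + wc - 1L, S = est$S_sites,
                 N = est$N_sites, Sd = est$Sd, Nd = est$Nd, Ka = est$Ka,
                 Ks = est$Ks, ratio = est$ratio)
    }
  })
  do.call(rbind, rows)
}

#' Date a duplication event from synonymous divergence
#'
#' Applies the molecular-clock formula `T = Ks / (2 * lambda)` and reports
#' the age in million years (MYA) to two decimals. The default substitution
#' rate `lambda = 9.1e-9` synonymous substitutions per site per year is the
#' rate commonly used for Populus.
#'
#' @param Ks Synonymous substitutions per synonymous site (>= 0).
#' @param lambda Clock rate per site per year (> 0).
#' @return Age in MYA, rounded to 2 decimals.
#' @examples
#' divergence_time(0.22)  # 12.09 MYA
#' @export
divergence_time <- function(Ks, lambda = 9.1e-9) {
  if (any(is.na(Ks)) || any(Ks < 0)) .stopf("Ks must be >= 0")
  if (!(lambda > 0)) .stopf("lambda must be > 0")
  round(Ks / (2 * lambda) / 1e6, 2L)
}

#' Classify selection regime from a Ka/Ks ratio
#'
#' @param ratio Ka/Ks value(s), `NA` allowed for undefined ratios.
#' @return Character vector over `{"purifying", "neutral", "positive",
#'   "undefined"}`: ratios below 1 indicate purifying selection, 1 neutral
#'   evolution, above 1 positive selection.
#' @export
classify_selection <- function(ratio) {
  vapply(ratio, function(r) {
    if (is.na(r)) return("undefined")
    if (r < 0) .stopf("Ka/Ks ratio must be >= 0")
    if (r < 1) "purifying" else if (r == 1) "neutral" else "positive"
  }, character(1L))
}
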