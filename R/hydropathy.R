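
# Kyte-Doolittle hydropathy scale
.KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding-window mean of per-residue Kyte-Doolittle hydropathy values. The
#' value at residue `i` is the mean over the window centred at `i`; the
#' first and last `(window - 1) / 2` residues carry `NA`.
#'
#' @param seq A protein [seq_record].
#' @param window Odd window size in residues (default 19, the classical
#'   transmembrane-scan window).
#' @return Numeric vector of length `nchar(seq)` with `NA` at the ends.
#' @export
hydropathy_profile <- function(seq, window = 19L) {
  stopifnot(inherits(seq, "seq_record"))
  if (seq$alphabet != "protein") .stopf("hydropathy_profile needs a protein sequence")
  window <- as.integer(window)
  if (window %% 2L != 1L || window < 1L) .stopf("window must be odd and positive")
  aa <- strsplit(seq$residues, "")[[1L]]
  n <- length(aa)
  if (n < window) .stopf("sequence length %d shorter than window %d", n, window)
  vals <- .KD_SCALE[aa]
  if (anyNA(vals)) {
    .stopf("non-standard residue '%s' at position %d",
           aa[[which(is.na(vals))[[1L]]]], which(is.na(vals))[[1L]])
  }
  half <- (window - 1L) %/% 2L
  prof <- rep(NA_real_, n)
  cs <- cumsum(c(0, vals))
  centers <- seq(half + 1L, n - half)
  prof[centers] <- (cs[centers + half + 1L] - cs[centers - half]) / window
  prof
}

#' Predict transmembrane segments from a hydropathy profile
#'
#' Maximal runs of residues whose windowed hydropathy is at least
#' `threshold` are reported as transmembrane helix (TMH) candidates when
#' long enough; runs separated by fewer than 3 residues are merged first.
#'
#' @param profile Numeric profile from [hydropathy_profile].
#' @param threshold Minimum windowed hydropathy (default 1.6, the classical
#'   Kyte-Doolittle cutoff for membrane-spanning segments).
#' @param min_len Minimum run length in residues (default 15).
#' @return Data frame with columns `start`, `end` (1-based closed residue
#'   positions) and `mean_hydropathy`, sorted and non-overlapping; zero rows
#'   when nothing qualifies.
#' @export
predict_tmh <- function(profile, threshold = 1.6, min_len = 15L) {
  stopifnot(is.numeric(profile))
  hit <- !is.na(profile) & profile >= threshold
  runs <- rle(hit)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg <- data.frame(start = starts[runs$values], end = ends[runs$values])
  # merge runs separated by short (< 3 residue) dips
  if (nrow(seg) > 1L) {
    keep <- list(seg[1L, ])
    for (i in 2L:nrow(seg)) {
      last <- keep[[length(keep)]]
      if (seg$start[[i]] - last$end < 3L + 1L) {
        last$end <- seg$end[[i]]
        keep[[length(keep)]] <- last
      } else {
        keep[[length(keep) + 1L]] <- seg[i, ]
      }
    }
    seg <- do.call(rbind, keep)
  }
  seg <- seg[seg$end - seg$start + 1L >= min_len, , drop = FALSE]
  if (nrow(seg) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      mean_hydropathy = numeric(0)))
  }
  seg$mean_hydropathy <- vapply(seq_len(nrow(seg)), function(i) {
    mean(profile[seg$start[[i]]:seg$end[[i]]], na.rm = TRUE)
  }, numeric(1L))
  rownames(seg) <- NULL
  seg
}
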