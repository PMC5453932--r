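# Independent oracles used to cross-check the package implementations.
# These are written from first principles (recursive enumeration, direct
# summation) and deliberately do not reuse package internals.

# ---- exhaustive global-alignment score ------------------------------------
# maximum score over all alignments, by plain recursion (no DP reuse);
# feasible for sequences up to ~7 residues
oracle_align_score <- function(a, b, match, mismatch, gap) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1L, j - 1L) + s)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# ---- Nei-Gojobori counting oracle -----------------------------------------
oracle_stops <- c("TAA", "TAG", "TGA")
oracle_code <- local({
  # standard genetic code written out via Biostrings (table lookup only)
  as.list(Biostrings::GENETIC_CODE)
})

oracle_syn_sites_codon <- function(codon) {
  total <- 0
  for (pos in 1:3) {
    cur <- substr(codon, pos, pos)
    syn <- 0L; valid <- 0L
    for (b in c("A", "C", "G", "T")) {
      if (b == cur) next
      alt <- codon
      substr(alt, pos, pos) <- b
      if (alt %in% oracle_stops) next
      valid <- valid + 1L
      if (identical(oracle_code[[alt]], oracle_code[[codon]])) syn <- syn + 1L
    }
    if (valid > 0L) total <- total + syn / valid
  }
  total
}

# all orderings of a set, by recursion
oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1L]] <- c(v[[i]], rest)
  }
  out
}

# pathway-averaged synonymous/nonsynonymous differences for one codon pair
oracle_pair_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  if (length(pos) == 0L) return(c(sd = 0, nd = 0))
  paths <- oracle_perms(pos)
  counts <- list(); through_stop <- logical(0)
  for (ord in paths) {
    cur <- c1; sd <- 0L; nd <- 0L; stopped <- FALSE
    for (k in seq_along(ord)) {
      p <- ord[[k]]
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (k < length(ord) && nxt %in% oracle_stops) stopped <- TRUE
      if (identical(oracle_code[[cur]], oracle_code[[nxt]])) sd <- sd + 1L
      else nd <- nd + 1L
      cur <- nxt
    }
    counts[[length(counts) + 1L]] <- c(sd, nd)
    through_stop <- c(through_stop, stopped)
  }
  keep <- if (all(through_stop)) seq_along(counts) else which(!through_stop)
  m <- do.call(rbind, counts[keep])
  c(sd = mean(m[, 1L]), nd = mean(m[, 2L]))
}

# full estimate on two codon vectors (no gaps), mirroring the estimator's
# documented conventions
oracle_ng86 <- function(codons_a, codons_b) {
  stopifnot(length(codons_a) == length(codons_b))
  S <- (sum(vapply(codons_a, oracle_syn_sites_codon, numeric(1))) +
        sum(vapply(codons_b, oracle_syn_sites_codon, numeric(1)))) / 2
  N <- 3 * length(codons_a) - S
  sd <- 0; nd <- 0
  for (i in seq_along(codons_a)) {
    d <- oracle_pair_diffs(codons_a[[i]], codons_b[[i]])
    sd <- sd + d[["sd"]]; nd <- nd + d[["nd"]]
  }
  pS <- sd / S; pN <- nd / N
  list(S = S, N = N, Sd = sd, Nd = nd, pS = pS, pN = pN,
       Ks = if (pS < 0.75) -0.75 * log(1 - 4 * pS / 3) else NA_real_,
       Ka = if (pN < 0.75) -0.75 * log(1 - 4 * pN / 3) else NA_real_)
}

# random sense codons for fixtures
oracle_random_codons <- function(n) {
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(all64, oracle_stops)
  sample(sense, n, replace = TRUE)
}

# mutate a codon vector at `k` random positions, avoiding stops
oracle_mutate_codons <- function(codons, k) {
  bases <- c("A", "C", "G", "T")
  done <- 0L
  while (done < k) {
    i <- sample.int(length(codons), 1L)
    p <- sample.int(3L, 1L)
    alt <- codons[[i]]
    substr(alt, p, p) <- sample(setdiff(bases, substr(alt, p, p)), 1L)
    if (alt %in% oracle_stops) next
    codons[[i]] <- alt
    done <- done + 1L
  }
  codons
}

# ---- splice-substitute-translate-diff variant oracle ----------------------
# classifies a coding SNV by applying it to the contig, splicing the CDS on
# both alleles, translating, and diffing the proteins
oracle_snv_class <- function(pos, alt, model, genome_seq) {
  splice_cds <- function(gseq) {
    cds <- model$cds[order(model$cds[, 1L]), , drop = FALSE]
    parts <- vapply(seq_len(nrow(cds)), function(i) {
      substr(gseq, cds[i, 1L], cds[i, 2L])
    }, character(1L))
    s <- paste(parts, collapse = "")
    if (model$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }
  translate_all <- function(cds) {
    n <- nchar(cds) %/% 3L
    vapply(seq_len(n), function(i) {
      oracle_code[[substr(cds, 3L * i - 2L, 3L * i)]]
    }, character(1L))
  }
  ref_cds <- splice_cds(genome_seq)
  alt_seq <- genome_seq
  substr(alt_seq, pos, pos) <- alt
  alt_cds <- splice_cds(alt_seq)
  aa_ref <- translate_all(ref_cds)
  aa_alt <- translate_all(alt_cds)
  if (identical(aa_ref, aa_alt)) return("synonymous")
  d <- which(aa_ref != aa_alt)
  if (length(d) == 1L && d == 1L && aa_ref[[1L]] == "M") return("start_lost")
  if (any(aa_alt[d] == "*")) return("stop_gained")
  "non_synonymous"
}

# ---- hypergeometric upper tail by direct pmf summation --------------------
oracle_hyper_upper <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
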