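
# --- seeded generators with ground truth -----------------------------------
# Every generator runs under a private RNG stream (.with_seed), so the same
# seed reproduces the same bundle byte for byte and callers' RNG state is
# untouched.

.BASES <- c("A", "C", "G", "T")

# random sense codons (no stops anywhere)
.random_sense_codons <- function(n) {
  tabs <- .codon_tables()
  sample(tabs$sense, n, replace = TRUE)
}

# uniform random synonymous codon for each amino acid of a protein string
.protein_to_random_cds <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  aa <- strsplit(protein, "")[[1L]]
  bad <- setdiff(aa, names(by_aa))
  if (length(bad) > 0L) .stopf("cannot encode residue '%s'", bad[[1L]])
  vapply(aa, function(a) {
    opts <- by_aa[[a]]
    opts[[sample.int(length(opts), 1L)]]
  }, character(1L), USE.NAMES = FALSE)
}

# evolve one lineage by proposal-acceptance until the accepted synonymous
# substitution count reaches `target_syn`; returns codons plus realized
# event counts. Nonsynonymous proposals are accepted with probability
# min(omega, 1); for omega > 1 the asymmetry is applied to the synonymous
# side instead (acceptance 1/omega), which realises the same Ka/Ks ratio.
.evolve_lineage <- function(codons, omega, target_syn) {
  gc <- Biostrings::GENETIC_CODE
  n <- length(codons)
  syn_events <- 0; nonsyn_events <- 0
  p_nonsyn <- min(omega, 1)
  p_syn <- if (omega > 1) 1 / omega else 1
  while (syn_events < target_syn) {
    i <- sample.int(n, 1L)
    pos <- sample.int(3L, 1L)
    cur <- codons[[i]]
    alt_base <- sample(setdiff(.BASES, substr(cur, pos, pos)), 1L)
    cand <- cur
    substr(cand, pos, pos) <- alt_base
    if (cand %in% .STOP_CODONS) next
    if (gc[[cand]] == gc[[cur]]) {
      if (stats::runif(1L) <= p_syn) {
        codons[[i]] <- cand
        syn_events <- syn_events + 1
      }
    } else if (stats::runif(1L) <= p_nonsyn) {
      codons[[i]] <- cand
      nonsyn_events <- nonsyn_events + 1
    }
  }
  list(codons = codons, syn_events = syn_events, nonsyn_events = nonsyn_events)
}

#' Simulate a duplicated coding-sequence pair at a target divergence
#'
#' Generates a random stop-free ancestral CDS and evolves two independent
#' lineages by per-site proposal-acceptance: synonymous proposals are always
#' accepted, nonsynonymous proposals with probability `min(omega, 1)` (for
#' `omega > 1` the boost is applied on the nonsynonymous side by accepting
#' synonymous proposals with probability `1/omega` instead). Each lineage
#' accumulates accepted synonymous substitutions until it reaches
#' `target_ks / 2` per ancestral synonymous site, so the realized pairwise
#' synonymous divergence is calibrated to `target_ks`.
#'
#' @param n_codons Ancestor length in codons (>= 50).
#' @param omega Nonsynonymous/synonymous acceptance ratio (> 0).
#' @param target_ks Target pairwise synonymous substitutions per synonymous
#'   site (>= 0); 0 yields identical sequences.
#' @param seed Integer seed; same seed, same output.
#' @return List with `cds_a`, `cds_b` ([seq_record]s, ids `dup_a`/`dup_b`)
#'   and `truth`: ancestral codons, per-lineage realized substitution
#'   counts, realized Ks/Ka (substitution events per ancestral site) and
#'   the generating parameters.
#' @export
evolve_duplicate_pair <- function(n_codons, omega, target_ks, seed) {
  n_codons <- as.integer(n_codons)
  if (n_codons < 50L) .stopf("n_codons must be >= 50")
  if (!(omega > 0)) .stopf("omega must be > 0")
  if (target_ks < 0) .stopf("target_ks must be >= 0")
  .with_seed(seed, {
    tabs <- .codon_tables()
    anc <- .random_sense_codons(n_codons)
    S_anc <- sum(tabs$syn_sites[anc])
    N_anc <- 3 * n_codons - S_anc
    target_syn <- S_anc * target_ks / 2
    la <- .evolve_lineage(anc, omega, target_syn)
    lb <- .evolve_lineage(anc, omega, target_syn)
    truth <- list(
      seed = seed, n_codons = n_codons, omega = omega, target_ks = target_ks,
      ancestor = paste(anc, collapse = ""),
      syn_sites_ancestor = S_anc, nonsyn_sites_ancestor = N_anc,
      syn_events = c(a = la$syn_events, b = lb$syn_events),
      nonsyn_events = c(a = la$nonsyn_events, b = lb$nonsyn_events),
      realized_ks = (la$syn_events + lb$syn_events) / S_anc,
      realized_ka = (la$nonsyn_events + lb$nonsyn_events) / N_anc)
    list(cds_a = seq_record("dup_a", paste(la$codons, collapse = ""), "dna"),
         cds_b = seq_record("dup_b", paste(lb$codons, collapse = ""), "dna"),
         truth = truth)
  })
}

#' Simulate an expression compendium with planted co-expression modules
#'
#' Genes assigned to the same module share one latent condition profile;
#' module profiles are made mutually orthogonal (QR decomposition of a
#' random matrix) so cross-module correlations are driven by noise alone.
#' Log-scale values are `amplitude * profile + N(0, noise_sd)` on top of a
#' constant baseline and exponentiated to a non-negative expression scale.
#' Genes not named in any module receive independent random profiles.
#'
#' @param n_genes Total number of genes; ids default to `g001..`, with
#'   module genes keeping the ids used in `module_spec`.
#' @param n_conditions Number of conditions (>= 3; default 24, a
#'   tissue-compendium scale).
#' @param module_spec Named list: module name -> character vector of gene
#'   ids belonging to that module.
#' @param noise_sd Gaussian noise on the log2 scale (signal has sd 1).
#' @param seed Integer seed.
#' @param baseline Log2 baseline expression level.
#' @return List with `matrix` (genes x conditions) and `truth` (module
#'   membership, latent profiles, parameters).
#' @export
synth_expression <- function(n_genes, n_conditions = 24L, module_spec = list(),
                             noise_sd = 0.1, seed = 1L, baseline = 8) {
  n_conditions <- as.integer(n_conditions)
  if (n_conditions < 3L) .stopf("need at least 3 conditions")
  module_genes <- unlist(module_spec, use.names = FALSE)
  if (anyDuplicated(module_genes)) .stopf("a gene may belong to only one module")
  if (length(module_genes) > n_genes) .stopf("more module genes than n_genes")
  .with_seed(seed, {
    n_bg <- n_genes - length(module_genes)
    gene_ids <- c(module_genes, sprintf("g%03d", seq_len(n_bg)))
    k <- length(module_spec)
    profiles <- NULL
    if (k > 0L) {
      if (k > n_conditions) .stopf("more modules than conditions")
      q <- qr.Q(qr(matrix(stats::rnorm(n_conditions * k), n_conditions, k)))
      profiles <- q * sqrt(n_conditions)   # unit-ish sd per profile
      colnames(profiles) <- names(module_spec)
    }
    vals <- matrix(0, length(gene_ids), n_conditions,
                   dimnames = list(gene_ids,
                                   sprintf("cond%02d", seq_len(n_conditions))))
    membership <- setNames(rep(NA_character_, length(gene_ids)), gene_ids)
    for (mod in names(module_spec)) {
      for (gid in module_spec[[mod]]) {
        vals[gid, ] <- profiles[, mod]
        membership[[gid]] <- mod
      }
    }
    for (gid in setdiff(gene_ids, module_genes)) {
      vals[gid, ] <- stats::rnorm(n_conditions)
    }
    logexpr <- baseline + vals +
      matrix(stats::rnorm(length(vals), sd = noise_sd), nrow(vals), ncol(vals))
    m <- 2^logexpr
    list(matrix = m,
         truth = list(seed = seed, membership = membership,
                      profiles = profiles, noise_sd = noise_sd,
                      baseline = baseline))
  })
}

# TSS-relative offset -> string index in a promoter of `up` upstream bases
.rel_to_index <- function(offset, up) {
  if (offset == 0L) .stopf("TSS-relative coordinates have no position 0")
  if (offset > 0L) up + offset else up + offset + 1L
}

# draw a concrete instance of an IUPAC consensus
.instantiate_consensus <- function(consensus) {
  codes <- .check_iupac(consensus)
  paste(vapply(codes, function(cd) {
    set <- .IUPAC_SETS[[cd]]
    set[[sample.int(length(set), 1L)]]
  }, character(1L)), collapse = "")
}

#' Simulate promoters with planted cis-elements
#'
#' Uniform-random background sequences with concrete element instances
#' (sampled from each consensus) written in at requested TSS-relative
#' offsets and strands; minus-strand plants are inserted as the reverse
#' complement so a both-strand scan recovers them on the minus strand.
#' Planted instances may not overlap one another.
#'
#' @param n_genes Number of promoters; ids `prom1..`, overridable via
#'   `gene_ids`.
#' @param plant_spec Data frame with columns `gene` (id or 1-based index),
#'   `element`, `offset` (TSS-relative, no 0), `strand` (`"+"`/`"-"`).
#' @param seed Integer seed.
#' @param upstream,downstream Promoter window (default 1500/500).
#' @param library Element library (default packaged library).
#' @param gene_ids Optional explicit promoter/gene ids.
#' @return List with `records` (promoter [seq_record]s carrying TSS
#'   metadata) and `truth` (the plant table with the concrete inserted
#'   sequences).
#' @export
synth_promoters <- function(n_genes, plant_spec = NULL, seed = 1L,
                            upstream = 1500L, downstream = 500L,
                            library = load_element_library(),
                            gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("prom%d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  L <- upstream + downstream
  .with_seed(seed, {
    seqs <- setNames(lapply(gene_ids, function(g) {
      paste(sample(.BASES, L, replace = TRUE), collapse = "")
    }), gene_ids)
    truth <- data.frame(gene = character(0), element = character(0),
                        offset = integer(0), strand = character(0),
                        inserted = character(0), stringsAsFactors = FALSE)
    if (!is.null(plant_spec) && nrow(plant_spec) > 0L) {
      occupied <- setNames(vector("list", n_genes), gene_ids)
      for (i in seq_len(nrow(plant_spec))) {
        gene <- plant_spec$gene[[i]]
        if (is.numeric(gene)) gene <- gene_ids[[gene]]
        if (!gene %in% gene_ids) .stopf("unknown promoter gene '%s'", gene)
        el <- plant_spec$element[[i]]
        cons <- library$consensus[match(el, library$name)]
        if (is.na(cons)) .stopf("element '%s' not in library", el)
        strand <- plant_spec$strand[[i]]
        w <- nchar(cons)
        idx <- .rel_to_index(as.integer(plant_spec$offset[[i]]), upstream)
        if (idx < 1L || idx + w - 1L > L) {
          .stopf("plant position %d outside promoter window", plant_spec$offset[[i]])
        }
        iv <- c(idx, idx + w - 1L)
        for (old in occupied[[gene]]) {
          if (iv[[1L]] <= old[[2L]] && iv[[2L]] >= old[[1L]]) {
            .stopf("planted elements overlap in promoter '%s'", gene)
          }
        }
        occupied[[gene]] <- c(occupied[[gene]], list(iv))
        inst <- .instantiate_consensus(cons)
        put <- if (strand == "+") inst else .revcomp(inst)
        s <- seqs[[gene]]
        substr(s, idx, idx + w - 1L) <- put
        seqs[[gene]] <- s
        truth <- rbind(truth, data.frame(
          gene = gene, element = el, offset = as.integer(plant_spec$offset[[i]]),
          strand = strand, inserted = inst, stringsAsFactors = FALSE))
      }
    }
    records <- lapply(gene_ids, function(g) {
      rec <- seq_record(paste0(g, "_promoter"), seqs[[g]], "dna")
      attr(rec, "gene_id") <- g
      attr(rec, "upstream") <- as.integer(upstream)
      attr(rec, "downstream") <- as.integer(downstream)
      attr(rec, "tss_index") <- as.integer(upstream) + 1L
      attr(rec, "truncated") <- FALSE
      rec
    })
    names(records) <- gene_ids
    list(records = records, truth = truth)
  })
}

#' Simulate a synthetic polytopic membrane protein
#'
#' Alternates hydrophilic loops (residues sampled from R/K/D/E/Q/N) with
#' hydrophobic membrane-spanning segments (I/L/V/F), recording the planted
#' segment coordinates. Defaults give segments long enough that the
#' windowed hydropathy scan ([hydropathy_profile] + [predict_tmh] at their
#' defaults) recovers every planted segment.
#'
#' @param n_tmh Number of transmembrane segments.
#' @param tmh_len Segment length in residues (default 25; a 19-residue
#'   scan window erodes about 4 residues from each end of a detected run,
#'   so segments shorter than ~23 fall below the default 15-residue
#'   minimum run).
#' @param loop_len Loop length in residues (default 30).
#' @param seed Integer seed.
#' @param id Record id.
#' @param c_tail_len Extra hydrophilic C-terminal tail (default 0).
#' @return List with `protein` ([seq_record]) and `truth` (data frame of
#'   planted `start`/`end` residue coordinates plus parameters).
#' @export
synth_membrane_protein <- function(n_tmh = 10L, tmh_len = 25L, loop_len = 30L,
                                   seed = 1L, id = "synthetic_membrane_protein",
                                   c_tail_len = 0L) {
  hydrophobic <- c("I", "L", "V", "F")
  hydrophilic <- c("R", "K", "D", "E", "Q", "N")
  n_tmh <- as.integer(n_tmh)
  .with_seed(seed, {
    pieces <- character(0)
    starts <- integer(0); ends <- integer(0)
    pos <- 0L
    add <- function(res) {
      pieces <<- c(pieces, paste(res, collapse = ""))
      pos <<- pos + length(res)
    }
    add(sample(hydrophilic, loop_len, replace = TRUE))
    if (n_tmh > 0L) {
      for (i in seq_len(n_tmh)) {
        starts <- c(starts, pos + 1L)
        add(sample(hydrophobic, tmh_len, replace = TRUE))
        ends <- c(ends, pos)
        add(sample(hydrophilic, loop_len, replace = TRUE))
      }
    }
    if (c_tail_len > 0L) add(sample(hydrophilic, c_tail_len, replace = TRUE))
    rec <- seq_record(id, paste(pieces, collapse = ""), "protein")
    list(protein = rec,
         truth = list(segments = data.frame(start = starts, end = ends),
                      n_tmh = n_tmh, tmh_len = tmh_len, loop_len = loop_len,
                      seed = seed))
  })
}

# genomic position of a 1-based spliced-CDS offset
.cds_offset_to_genomic <- function(model, off) {
  run <- 0L
  for (i in seq_len(nrow(model$cds))) {
    s <- model$cds[i, 1L]; e <- model$cds[i, 2L]
    w <- e - s + 1L
    if (off <= run + w) {
      within <- off - run
      return(if (model$strand == "+") s + within - 1L else e - within + 1L)
    }
    run <- run + w
  }
  NA_integer_
}

# random HWE genotypes for n samples at a random allele frequency
.random_genotypes <- function(n_samples) {
  if (n_samples == 0L) return(character(0))
  af <- stats::runif(1L, 0.05, 0.5)
  alleles <- matrix(stats::runif(2L * n_samples) < af, nrow = 2L)
  counts <- colSums(alleles)
  c("0/0", "0/1", "1/1")[counts + 1L]
}

#' Simulate variants of requested consequence categories for a gene
#'
#' For each requested category the generator samples genomic sites where
#' that consequence is achievable (rejection sampling), verifies every
#' candidate's label with [classify_variant] before emitting it, and
#' records the intended category as ground truth. Positions are distinct
#' across the emitted set. Requests that cannot be realised on the given
#' model (e.g. splice-site variants on an intronless gene) are errors.
#'
#' @param g A [gene_model].
#' @param genome [seq_record] of the gene's contig.
#' @param category_counts Named integer vector, names from the consequence
#'   categories (`synonymous`, `non_synonymous`, `stop_gained`,
#'   `start_lost`, `start_gained`, `codon_deletion`, `frame_shift`,
#'   `splice_site_donor`, `splice_site_acceptor`, `non_genic`).
#' @param seed Integer seed.
#' @param n_samples Diploid individuals to genotype (HWE at a random
#'   allele frequency per site); 0 for site-only records.
#' @return List with `variants` (list of [variant_record]s) and `truth`
#'   (data frame `pos`, `ref`, `alt`, `category`).
#' @export
synth_variants <- function(g, genome, category_counts, seed = 1L,
                           n_samples = 0L) {
  stopifnot(inherits(g, "gene_model"), inherits(genome, "seq_record"))
  bad <- setdiff(names(category_counts), .CONSEQUENCE_LEVELS)
  if (length(bad) > 0L) .stopf("unknown category '%s'", bad[[1L]])
  introns <- .introns(g)
  cds_len <- sum(g$cds[, 2L] - g$cds[, 1L] + 1L)
  span <- .gene_span(g)
  .with_seed(seed, {
    used <- integer(0)
    out <- list()
    truth <- list()
    base_at <- function(p) substr(genome$residues, p, p)

    try_snv <- function(p, alt, category) {
      if (p %in% used) return(FALSE)
      ref <- base_at(p)
      if (ref == alt) return(FALSE)
      v <- variant_record(g$contig_id, p, ref, alt, character(0))
      cc <- tryCatch(classify_variant(v, g, genome), error = function(e) NULL)
      if (is.null(cc) || cc$category != category) return(FALSE)
      used <<- c(used, p)
      out[[length(out) + 1L]] <<- v
      truth[[length(truth) + 1L]] <<- data.frame(
        pos = p, ref = ref, alt = alt, category = category,
        stringsAsFactors = FALSE)
      TRUE
    }
    try_del <- function(p, del_len, category) {
      ps <- p:(p + del_len)
      if (any(ps %in% used)) return(FALSE)
      ref <- substr(genome$residues, p, p + del_len)
      alt <- base_at(p)
      v <- tryCatch(variant_record(g$contig_id, p, ref, alt, character(0)),
                    error = function(e) NULL)
      if (is.null(v)) return(FALSE)
      cc <- tryCatch(classify_variant(v, g, genome), error = function(e) NULL)
      if (is.null(cc) || cc$category != category) return(FALSE)
      used <<- c(used, ps)
      out[[length(out) + 1L]] <<- v
      truth[[length(truth) + 1L]] <<- data.frame(
        pos = p, ref = ref, alt = alt, category = category,
        stringsAsFactors = FALSE)
      TRUE
    }
    sample_until <- function(n_needed, category, proposer) {
      got <- 0L
      for (attempt in seq_len(20000L)) {
        if (got >= n_needed) return(invisible(NULL))
        if (isTRUE(proposer())) got <- got + 1L
      }
      if (got < n_needed) {
        .stopf("could not realise %d '%s' variant(s) on gene '%s'",
               n_needed, category, g$gene_id)
      }
    }

    cds_start_g <- if (g$strand == "+") g$cds[1L, 1L] else g$cds[1L, 2L]
    utr_tx <- .genomic_to_tx_offset(g, cds_start_g) - 1L
    utr5_pos <- integer(0)
    if (utr_tx >= 1L) {
      exonic <- unlist(lapply(seq_len(nrow(g$exons)), function(i) {
        g$exons[i, 1L]:g$exons[i, 2L]
      }))
      utr5_pos <- exonic[vapply(exonic, function(p) {
        tx <- .genomic_to_tx_offset(g, p)
        !is.na(tx) && tx <= utr_tx
      }, logical(1L))]
    }

    for (category in names(category_counts)) {
      n_needed <- as.integer(category_counts[[category]])
      if (n_needed <= 0L) next
      proposer <- switch(category,
        synonymous = ,
        non_synonymous = ,
        stop_gained = function() {
          off <- sample(4:cds_len, 1L)
          p <- .cds_offset_to_genomic(g, off)
          try_snv(p, sample(.BASES, 1L), category)
        },
        start_lost = function() {
          off <- sample.int(3L, 1L)
          p <- .cds_offset_to_genomic(g, off)
          try_snv(p, sample(.BASES, 1L), category)
        },
        start_gained = function() {
          if (length(utr5_pos) < 3L) {
            .stopf("gene '%s' lacks a 5'UTR for start_gained", g$gene_id)
          }
          p <- utr5_pos[[sample.int(length(utr5_pos), 1L)]]
          try_snv(p, sample(.BASES, 1L), category)
        },
        codon_deletion = function() {
          wide <- which(g$cds[, 2L] - g$cds[, 1L] + 1L >= 5L)
          if (length(wide) == 0L) {
            .stopf("gene '%s' has no CDS segment wide enough for a codon deletion",
                   g$gene_id)
          }
          i <- wide[[sample.int(length(wide), 1L)]]
          p <- sample(g$cds[i, 1L]:(g$cds[i, 2L] - 3L), 1L)
          try_del(p, 3L, category)
        },
        frame_shift = function() {
          wide <- which(g$cds[, 2L] - g$cds[, 1L] + 1L >= 2L)
          i <- wide[[sample.int(length(wide), 1L)]]
          p <- sample(g$cds[i, 1L]:(g$cds[i, 2L] - 1L), 1L)
          try_del(p, 1L, category)
        },
        splice_site_donor = ,
        splice_site_acceptor = function() {
          if (nrow(introns) == 0L) {
            .stopf("gene '%s' has no introns; cannot place %s", g$gene_id, category)
          }
          i <- sample.int(nrow(introns), 1L)
          s <- introns[i, 1L]; e <- introns[i, 2L]
          donor <- if (g$strand == "+") c(s, min(s + 1L, e)) else c(max(e - 1L, s), e)
          accep <- if (g$strand == "+") c(max(e - 1L, s), e) else c(s, min(s + 1L, e))
          win <- if (category == "splice_site_donor") donor else accep
          try_snv(sample(win[[1L]]:win[[2L]], 1L), sample(.BASES, 1L), category)
        },
        non_genic = function() {
          p <- sample(span[[1L]]:span[[2L]], 1L)
          try_snv(p, sample(.BASES, 1L), category)
        },
        .stopf("unsupported category '%s'", category))
      if ((category %in% c("splice_site_donor", "splice_site_acceptor")) &&
          nrow(introns) == 0L) {
        .stopf("gene '%s' has no introns; cannot place %s", g$gene_id, category)
      }
      sample_until(n_needed, category, proposer)
    }
    variants <- out
    if (n_samples > 0L) {
      variants <- lapply(variants, function(v) {
        variant_record(v$contig_id, v$pos, v$ref, v$alt,
                       .random_genotypes(as.integer(n_samples)))
      })
    }
    ord <- order(vapply(variants, function(v) v$pos, integer(1L)))
    list(variants = variants[ord],
         truth = do.call(rbind, truth)[ord, , drop = FALSE])
  })
}
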