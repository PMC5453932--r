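
# --- full synthetic study bundle ------------------------------------------

# random DNA of length n (uses current RNG stream)
.random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

# 1500-nt upstream promoter region with elements planted at negative
# TSS-relative offsets; returns sequence + truth rows
.plant_upstream <- function(gene_id, up_len, plant_counts, library) {
  s <- .random_dna(up_len)
  occupied <- list()
  truth <- list()
  for (el in names(plant_counts)) {
    n_el <- plant_counts[[el]]
    if (n_el <= 0L) next
    cons <- library$consensus[match(el, library$name)]
    if (is.na(cons)) .stopf("element '%s' not in library", el)
    w <- nchar(cons)
    for (k in seq_len(n_el)) {
      for (attempt in seq_len(500L)) {
        offset <- -sample(30:(up_len - 30L), 1L)
        idx <- up_len + offset + 1L
        iv <- c(idx, idx + w - 1L)
        clash <- any(vapply(occupied, function(o) {
          iv[[1L]] <= o[[2L]] && iv[[2L]] >= o[[1L]]
        }, logical(1L)))
        if (!clash) break
      }
      if (clash) .stopf("could not place element '%s' without overlap", el)
      occupied[[length(occupied) + 1L]] <- iv
      strand <- sample(c("+", "-"), 1L)
      inst <- .instantiate_consensus(cons)
      substr(s, iv[[1L]], iv[[2L]]) <- if (strand == "+") inst else .revcomp(inst)
      truth[[length(truth) + 1L]] <- data.frame(
        gene = gene_id, element = el, offset = offset, strand = strand,
        inserted = inst, stringsAsFactors = FALSE)
    }
  }
  list(sequence = s, truth = if (length(truth) > 0L) do.call(rbind, truth)
       else NULL)
}

# assemble one gene (plus orientation first, optionally mirrored to the
# minus strand) from a CDS and a planted upstream promoter region
.assemble_gene <- function(gene_id, contig_id, cds, n_exons, promoter_up,
                           strand = "+", utr5 = 150L, utr3 = 150L,
                           flank = 100L) {
  cds_len <- nchar(cds)
  base <- cds_len %/% n_exons
  sizes <- rep(base, n_exons)
  extra <- cds_len - base * n_exons
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stopifnot(all(sizes >= 5L))
  chunk_start <- cumsum(c(1L, sizes[-n_exons]))
  chunks <- substring(cds, chunk_start, chunk_start + sizes - 1L)

  pieces <- c(.random_dna(flank), promoter_up)
  pos <- flank + nchar(promoter_up)
  tss <- pos + 1L
  exons <- matrix(integer(0), ncol = 2L)
  cds_iv <- matrix(integer(0), ncol = 2L)
  # first exon: 5'UTR + first CDS chunk
  pieces <- c(pieces, .random_dna(utr5), chunks[[1L]])
  exons <- rbind(exons, c(tss, pos + utr5 + sizes[[1L]]))
  cds_iv <- rbind(cds_iv, c(pos + utr5 + 1L, pos + utr5 + sizes[[1L]]))
  pos <- pos + utr5 + sizes[[1L]]
  if (n_exons > 1L) {
    for (i in 2L:n_exons) {
      ilen <- sample(120:250, 1L)
      intron <- paste0("GT", .random_dna(ilen - 4L), "AG")
      pieces <- c(pieces, intron)
      pos <- pos + ilen
      ex_start <- pos + 1L
      last <- i == n_exons
      exon_seq <- if (last) paste0(chunks[[i]], .random_dna(utr3)) else chunks[[i]]
      pieces <- c(pieces, exon_seq)
      exons <- rbind(exons, c(ex_start, pos + nchar(exon_seq)))
      cds_iv <- rbind(cds_iv, c(ex_start, ex_start + sizes[[i]] - 1L))
      pos <- pos + nchar(exon_seq)
    }
  } else {
    pieces <- c(pieces, .random_dna(utr3))
    exons[1L, 2L] <- exons[1L, 2L] + utr3
    pos <- pos + utr3
  }
  pieces <- c(pieces, .random_dna(flank))
  contig <- paste(pieces, collapse = "")
  L <- nchar(contig)
  if (strand == "-") {
    contig <- .revcomp(contig)
    flip <- function(m) cbind(L - m[, 2L] + 1L, L - m[, 1L] + 1L)
    exons <- flip(exons)
    cds_iv <- flip(cds_iv)
  }
  model <- gene_model(gene_id, contig_id, strand, exons, cds_iv)
  list(contig = seq_record(contig_id, contig, "dna"), model = model)
}

#' Generate a complete synthetic eight-member gene-family study
#'
#' Builds, from one seed, every input the analysis pipeline consumes,
#' emulating a small NHX-type antiporter family: eight gene models on
#' synthetic contigs in three subfamilies (five vacuolar, one endosomal,
#' two plasma-membrane members), coding sequences in which two paralogous
#' pairs (`NHX1`/`NHX2`, `NHX7`/`NHX8`) were evolved to target synonymous
#' divergences of 0.22 and 0.20 under purifying selection; membrane
#' proteins with 10 (12 for the PM class) planted transmembrane segments;
#' promoters with planted cis-elements; a 24-condition expression matrix
#' with planted co-expression modules and shared hub genes; a 20-individual
#' variant panel with known consequence labels; a flat gene-to-term
#' annotation map; and labelled reference proteins for subfamily
#' assignment. All generating parameters and labels are returned as ground
#' truth.
#'
#' @param seed Integer seed; the bundle is fully determined by it.
#' @return A list of class `nhx_bundle`; see [write_bundle] for writing it
#'   to standard file formats.
#' @export
nhx_scenario <- function(seed = 1L) {
  .with_seed(seed, {
    tabs <- .codon_tables()
    lib <- load_element_library()
    sub_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)

    # class scaffolds: membrane proteins with planted TMH architecture
    vac_mem <- synth_membrane_protein(10L, 25L, 22L, seed = sub_seed(),
                                      id = "vac_scaffold", c_tail_len = 52L)
    endo_mem <- synth_membrane_protein(10L, 25L, 22L, seed = sub_seed(),
                                       id = "endo_scaffold", c_tail_len = 45L)
    pm_mem <- synth_membrane_protein(12L, 25L, 22L, seed = sub_seed(),
                                     id = "pm_scaffold", c_tail_len = 559L)
    anc <- list(Vac = .protein_to_random_cds(vac_mem$protein$residues),
                Endo = .protein_to_random_cds(endo_mem$protein$residues),
                PM = .protein_to_random_cds(pm_mem$protein$residues))
    S_anc <- lapply(anc, function(a) sum(tabs$syn_sites[a]))

    evolve <- function(class, omega, ks_lineage) {
      .evolve_lineage(anc[[class]], omega, S_anc[[class]] * ks_lineage)
    }
    members <- list(
      NHX1 = evolve("Vac", 0.227, 0.11),
      NHX2 = evolve("Vac", 0.227, 0.11),
      NHX3 = evolve("Vac", 0.20, 0.45),
      NHX4 = evolve("Vac", 0.20, 0.45),
      NHX5 = evolve("Vac", 0.20, 0.45),
      NHX6 = evolve("Endo", 0.20, 0.05),
      NHX7 = evolve("PM", 0.25, 0.10),
      NHX8 = evolve("PM", 0.25, 0.10))
    refs <- list(REF_Vac = evolve("Vac", 0.20, 0.30),
                 REF_Endo = evolve("Endo", 0.20, 0.30),
                 REF_PM = evolve("PM", 0.20, 0.30))
    classes <- c(NHX1 = "Vac", NHX2 = "Vac", NHX3 = "Vac", NHX4 = "Vac",
                 NHX5 = "Vac", NHX6 = "Endo", NHX7 = "PM", NHX8 = "PM")
    reference_classes <- c(REF_Vac = "Vac", REF_Endo = "Endo", REF_PM = "PM")
    n_exons <- c(NHX1 = 14L, NHX2 = 14L, NHX3 = 14L, NHX4 = 14L, NHX5 = 14L,
                 NHX6 = 22L, NHX7 = 23L, NHX8 = 23L)
    strands <- c(NHX1 = "+", NHX2 = "+", NHX3 = "+", NHX4 = "-", NHX5 = "+",
                 NHX6 = "+", NHX7 = "+", NHX8 = "-")

    # paralog-pair truth (pairwise realized divergence from event counts)
    pair_truth <- data.frame(
      gene_a = c("NHX1", "NHX7"), gene_b = c("NHX2", "NHX8"),
      target_ks = c(0.22, 0.20), omega = c(0.227, 0.25),
      realized_ks = c(
        (members$NHX1$syn_events + members$NHX2$syn_events) / S_anc$Vac,
        (members$NHX7$syn_events + members$NHX8$syn_events) / S_anc$PM),
      realized_ka = c(
        (members$NHX1$nonsyn_events + members$NHX2$nonsyn_events) /
          (3 * length(anc$Vac) - S_anc$Vac),
        (members$NHX7$nonsyn_events + members$NHX8$nonsyn_events) /
          (3 * length(anc$PM) - S_anc$PM)),
      stringsAsFactors = FALSE)

    # promoter element counts per gene (HSE-rich PM/Endo promoters)
    plant_counts <- list(
      NHX1 = c(ABRE = 2, HSE = 3, `TC-rich` = 3, ARE = 1, MBS = 1),
      NHX2 = c(ABRE = 1, HSE = 3, `TC-rich` = 2, ARE = 1),
      NHX3 = c(ABRE = 1, HSE = 3, `TC-rich` = 2, ARE = 1, MBS = 1),
      NHX4 = c(ABRE = 2, HSE = 3, `TC-rich` = 3, ARE = 1),
      NHX5 = c(ABRE = 1, HSE = 3, `TC-rich` = 2, ARE = 1),
      NHX6 = c(ABRE = 1, HSE = 8, `TC-rich` = 2, ARE = 1),
      NHX7 = c(ABRE = 2, HSE = 7, `TC-rich` = 2, ARE = 5, MBS = 2,
               `Box-W1` = 1),
      NHX8 = c(HSE = 7, `TC-rich` = 3, ARE = 3, MBS = 1, `Box-W1` = 1))

    contigs <- list(); genes <- list(); prom_truth <- list()
    cds_recs <- list(); prot_recs <- list()
    for (gid in names(members)) {
      # CDS includes a stop codon, as an annotated CDS would
      cds <- paste0(paste(members[[gid]]$codons, collapse = ""),
                    sample(.STOP_CODONS, 1L))
      cds_recs[[gid]] <- seq_record(gid, cds, "dna")
      prot_recs[[gid]] <- seq_record(gid, .translate_cds(cds, gid), "protein")
      up <- .plant_upstream(gid, 1500L, plant_counts[[gid]], lib)
      if (!is.null(up$truth)) prom_truth[[gid]] <- up$truth
      asm <- .assemble_gene(gid, paste0("ctg_", gid), cds, n_exons[[gid]],
                            up$sequence, strand = strands[[gid]])
      contigs[[asm$contig$id]] <- asm$contig
      genes[[gid]] <- asm$model
    }
    for (rid in names(refs)) {
      cds <- paste0(paste(refs[[rid]]$codons, collapse = ""),
                    sample(.STOP_CODONS, 1L))
      cds_recs[[rid]] <- seq_record(rid, cds, "dna")
      prot_recs[[rid]] <- seq_record(rid, .translate_cds(cds, rid), "protein")
    }
    prom_truth <- do.call(rbind, unname(prom_truth))

    # co-expression compendium: per-member modules, one shared module with
    # hub genes for the endosomal/PM members, one member with no partners
    module_spec <- list(
      mod_nhx1 = c("NHX1", sprintf("cx1_%d", 1:6)),
      mod_nhx3 = c("NHX3", sprintf("cx3_%d", 1:10)),
      mod_nhx4 = c("NHX4", sprintf("cx4_%d", 1:8)),
      mod_nhx5 = c("NHX5", sprintf("cx5_%d", 1:7)),
      mod_shared = c("NHX6", "NHX7", "NHX8", sprintf("hub%d", 1:8)),
      mod_lone = "NHX2")
    n_module_genes <- length(unlist(module_spec))
    expr <- synth_expression(n_genes = n_module_genes + 60L,
                             n_conditions = 24L, module_spec = module_spec,
                             noise_sd = 0.05, seed = sub_seed())

    # flat annotation map: shared-module genes carry the transport term
    all_expr_genes <- rownames(expr$matrix)
    terms_pool <- c("metabolic process", "transcription regulation",
                    "photosynthesis", "cell wall organization")
    ann <- list()
    for (gidx in seq_along(all_expr_genes)) {
      gid <- all_expr_genes[[gidx]]
      tm <- if (gid %in% module_spec$mod_shared) "ion transmembrane transport"
            else terms_pool[[sample.int(length(terms_pool), 1L)]]
      ann[[gidx]] <- data.frame(gene_id = gid, term = tm,
                                stringsAsFactors = FALSE)
    }
    annotation <- do.call(rbind, ann)

    # population variants with known consequence labels
    var_counts <- list(
      NHX1 = c(non_synonymous = 4, synonymous = 2, start_gained = 1),
      NHX2 = c(non_synonymous = 3, synonymous = 1),
      NHX3 = c(non_synonymous = 5, codon_deletion = 1),
      NHX4 = c(non_synonymous = 3, start_lost = 1),
      NHX5 = c(non_synonymous = 4, splice_site_acceptor = 1),
      NHX6 = c(non_synonymous = 2),
      NHX7 = c(non_synonymous = 8, stop_gained = 1, splice_site_donor = 1,
               frame_shift = 1, synonymous = 3),
      NHX8 = c(non_synonymous = 7, splice_site_donor = 1, start_gained = 1,
               synonymous = 2))
    variants <- list(); var_truth <- list()
    for (gid in names(var_counts)) {
      sv <- synth_variants(genes[[gid]], contigs[[genes[[gid]]$contig_id]],
                           var_counts[[gid]], seed = sub_seed(),
                           n_samples = 20L)
      variants[[gid]] <- sv$variants
      tt <- sv$truth
      tt$gene <- gid
      var_truth[[gid]] <- tt
    }
    var_truth <- do.call(rbind, unname(var_truth))

    structure(list(
      seed = seed,
      contigs = contigs, genes = genes,
      cds = cds_recs, proteins = prot_recs,
      classes = classes, reference_classes = reference_classes,
      pairs = pair_truth,
      promoter_truth = prom_truth,
      expression = expr$matrix, expression_truth = expr$truth,
      annotation = annotation,
      variants = variants, variant_truth = var_truth,
      params = list(lambda = 9.1e-9, pearson_threshold = 0.85,
                    promoter_upstream = 1500L, promoter_downstream = 500L,
                    n_individuals = 20L)),
      class = "nhx_bundle")
  })
}

#' @export
print.nhx_bundle <- function(x, ...) {
  cat(sprintf(paste0("<nhx_bundle seed=%d: %d genes, %d contigs, ",
                     "%d expression genes x %d conditions, %d variants>\n"),
              x$seed, length(x$genes), length(x$contigs),
              nrow(x$expression), ncol(x$expression),
              sum(lengths(x$variants))))
  invisible(x)
}

#' Serialize gene models to GFF3 text
#'
#' @param models List of [gene_model]s.
#' @param path Optional output path; text returned when `NULL`.
#' @export
write_gff3 <- function(models, path = NULL) {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- .gene_span(m)
    row <- function(type, s, e, id = NULL, parent = NULL) {
      attrs <- c(if (!is.null(id)) paste0("ID=", id),
                 if (!is.null(parent)) paste0("Parent=", parent))
      paste(m$contig_id, "nhxdiverge", type, s, e, ".", m$strand, ".",
            paste(attrs, collapse = ";"), sep = "\t")
    }
    lines <- c(lines, row("gene", span[[1L]], span[[2L]], id = m$gene_id))
    mrna_id <- paste0(m$gene_id, ".1")
    lines <- c(lines, row("mRNA", span[[1L]], span[[2L]], id = mrna_id,
                          parent = m$gene_id))
    ex <- m$exons[order(m$exons[, 1L]), , drop = FALSE]
    for (i in seq_len(nrow(ex))) {
      lines <- c(lines, row("exon", ex[i, 1L], ex[i, 2L], parent = mrna_id))
    }
    cd <- m$cds[order(m$cds[, 1L]), , drop = FALSE]
    for (i in seq_len(nrow(cd))) {
      lines <- c(lines, row("CDS", cd[i, 1L], cd[i, 2L], parent = mrna_id))
    }
  }
  if (is.null(path)) return(paste0(paste(lines, collapse = "\n"), "\n"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic study bundle to standard file formats
#'
#' Writes the bundle's contigs (`genome.fa`), coding and protein sequences
#' (`cds.fa`, `proteins.fa`), gene models (`genes.gff3`), variant panel
#' (`variants.vcf`), expression matrix (`expression.tsv`), annotation map
#' (`annotation.tsv`), a JSON ground-truth file (`truth.json`) and a
#' ready-to-run pipeline configuration (`config.json`) into `dir`.
#'
#' @param bundle An `nhx_bundle` from [nhx_scenario].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path to `config.json`.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "nhx_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(unname(bundle$contigs), p("genome.fa"))
  write_fasta(unname(bundle$cds), p("cds.fa"))
  write_fasta(unname(bundle$proteins), p("proteins.fa"))
  write_gff3(bundle$genes, p("genes.gff3"))
  all_vars <- unlist(bundle$variants, recursive = FALSE, use.names = FALSE)
  ord <- order(vapply(all_vars, function(v) v$contig_id, character(1L)),
               vapply(all_vars, function(v) v$pos, integer(1L)))
  write_vcf(all_vars[ord], p("variants.vcf"),
            sample_ids = sprintf("ind%02d", seq_len(bundle$params$n_individuals)))
  write_expression_matrix(bundle$expression, p("expression.tsv"))
  utils::write.table(bundle$annotation, p("annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(seed = bundle$seed, classes = as.list(bundle$classes),
                reference_classes = as.list(bundle$reference_classes),
                pairs = bundle$pairs, promoter_truth = bundle$promoter_truth,
                module_membership = as.list(bundle$expression_truth$membership),
                variant_truth = bundle$variant_truth)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  config <- list(
    genome_fasta = "genome.fa", cds_fasta = "cds.fa",
    protein_fasta = "proteins.fa", gff3 = "genes.gff3",
    vcf = "variants.vcf", expression_tsv = "expression.tsv",
    annotation_tsv = "annotation.tsv",
    paralog_pairs = list(c("NHX1", "NHX2"), c("NHX7", "NHX8")),
    reference_classes = as.list(bundle$reference_classes),
    seed_genes = names(bundle$genes),
    params = list(lambda = 9.1e-9, windows = c(60L, 90L),
                  pearson_threshold = 0.85, promoter_upstream = 1500L,
                  promoter_downstream = 500L, tmh_window = 19L,
                  tmh_threshold = 1.6, tmh_min_len = 15L, q_cut = 0.05))
  jsonlite::write_json(config, p("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(p("config.json"))
}
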