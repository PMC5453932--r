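
.default_pipeline_params <- function() {
  list(lambda = 9.1e-9, windows = c(60L, 90L), window_step = 6L,
       pearson_threshold = 0.85, promoter_upstream = 1500L,
       promoter_downstream = 500L, tmh_window = 19L, tmh_threshold = 1.6,
       tmh_min_len = 15L, q_cut = 0.05, align_match = 1,
       align_mismatch = -1, align_gap = -1, min_seed_degree = 2L)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full divergence-analysis pipeline
#'
#' Orchestrates every stage over one input bundle: gene characterization
#' (deduced ORF length, molecular weight, isoelectric point, transmembrane
#' segments, exon/intron structure), pairwise identity and
#' neighbor-joining subfamily assignment, Ka/Ks estimation with sliding
#' windows and duplication dating for configured paralog pairs, promoter
#' cis-element scanning and tallying, Pearson-threshold co-expression
#' network with shared hubs and term enrichment, and variant consequence
#' annotation with per-gene summaries and allele frequencies. All outputs
#' are TSV/newick/JSON files under `out_dir`, plus a machine-readable
#' `manifest.json` (package version, parameters, input checksums, output
#' row counts). The run is deterministic given the inputs.
#'
#' @param config Path to a JSON configuration file, or an equivalent list.
#'   Recognised fields: `genome_fasta`, `cds_fasta`, `protein_fasta`
#'   (optional; translated from CDS when absent), `gff3`, `vcf`,
#'   `expression_tsv`, `annotation_tsv`, `element_library` (optional JSON),
#'   `paralog_pairs` (list of 2-vectors of gene ids), `reference_classes`
#'   (named list: reference id -> class), `seed_genes` (network seeds;
#'   defaults to all gene-model ids) and `params` (see
#'   details; unset entries keep their defaults: lambda 9.1e-9, windows
#'   60/90 bp, Pearson threshold 0.85, promoter -1500/+500, hydropathy
#'   window 19 / threshold 1.6 / min length 15, q-cut 0.05).
#' @param out_dir Output directory (created if needed).
#' @param base_dir Directory against which relative input paths are
#'   resolved; defaults to the config file's directory (or `.` for list
#'   configs).
#' @return Invisibly, a list with the in-memory stage results and the
#'   output file paths.
#' @export
run_pipeline <- function(config, out_dir, base_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) .stopf("config file '%s' not found", config)
    if (is.null(base_dir)) base_dir <- dirname(config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  }
  if (is.null(base_dir)) base_dir <- "."
  params <- utils::modifyList(.default_pipeline_params(),
                              if (is.null(config$params)) list() else config$params)
  resolve <- function(field, required = TRUE) {
    p <- config[[field]]
    if (is.null(p)) {
      if (required) .stopf("config field '%s' is required", field)
      return(NULL)
    }
    full <- if (file.exists(p)) p else file.path(base_dir, p)
    if (!file.exists(full)) .stopf("input path '%s' (field '%s') not found", full, field)
    full
  }
  stage <- function(name, n) message(sprintf("[%s] %s", name, n))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, fname) {
    outputs[[fname]] <<- .write_tsv(df, file.path(out_dir, fname))
  }

  ## --- inputs --------------------------------------------------------------
  in_paths <- c(genome = resolve("genome_fasta"), cds = resolve("cds_fasta"),
                gff3 = resolve("gff3"), vcf = resolve("vcf"),
                expression = resolve("expression_tsv"),
                annotation = resolve("annotation_tsv"))
  prot_path <- resolve("protein_fasta", required = FALSE)
  lib_path <- resolve("element_library", required = FALSE)
  genome <- read_fasta(in_paths[["genome"]])
  genome <- setNames(genome, vapply(genome, function(r) r$id, character(1L)))
  models <- read_gene_models(in_paths[["gff3"]])
  cds <- read_fasta(in_paths[["cds"]], alphabet = "dna")
  cds <- setNames(cds, vapply(cds, function(r) r$id, character(1L)))
  proteins <- if (!is.null(prot_path)) {
    pr <- read_fasta(prot_path, alphabet = "protein")
    setNames(pr, vapply(pr, function(r) r$id, character(1L)))
  } else {
    lapply(cds, function(r) seq_record(r$id, .translate_cds(r$residues, r$id),
                                       "protein"))
  }
  expr <- read_expression_matrix(in_paths[["expression"]])
  annotation <- utils::read.delim(in_paths[["annotation"]],
                                  stringsAsFactors = FALSE)
  variants <- read_vcf(in_paths[["vcf"]])
  library <- load_element_library(lib_path)
  family <- names(models)
  stage("inputs", sprintf("%d gene models, %d sequences, %d variants",
                          length(models), length(cds), length(variants)))

  ## --- gene characterization ----------------------------------------------
  tmh_by_gene <- list()
  char_rows <- lapply(family, function(gid) {
    if (is.null(cds[[gid]])) .stopf("no CDS sequence for gene '%s'", gid)
    prot <- proteins[[gid]]
    prof <- hydropathy_profile(prot, window = params$tmh_window)
    tmh <- predict_tmh(prof, threshold = params$tmh_threshold,
                       min_len = params$tmh_min_len)
    tmh_by_gene[[gid]] <<- tmh
    struct <- gene_structure_summary(models[[gid]])
    data.frame(gene = gid, cds_bp = nchar(cds[[gid]]$residues),
               orf_aa = deduced_protein_length(nchar(cds[[gid]]$residues)),
               mw_kda = round(molecular_weight(prot) / 1000, 1L),
               pi = round(isoelectric_point(prot), 2L),
               tmh_count = nrow(tmh), exon_count = struct$exon_count,
               intron_count = struct$intron_count,
               intron_phases = paste(struct$intron_phases, collapse = ","),
               stringsAsFactors = FALSE)
  })
  emit(do.call(rbind, char_rows), "gene_summary.tsv")
  tmh_tab <- do.call(rbind, lapply(family, function(gid) {
    t <- tmh_by_gene[[gid]]
    if (nrow(t) == 0L) return(NULL)
    cbind(data.frame(gene = gid, stringsAsFactors = FALSE), t)
  }))
  if (is.null(tmh_tab)) {
    tmh_tab <- data.frame(gene = character(0), start = integer(0),
                          end = integer(0), mean_hydropathy = numeric(0))
  }
  emit(tmh_tab, "tmh_segments.tsv")
  stage("characterize", sprintf("%d genes", length(family)))

  ## --- identity, tree, subfamilies ----------------------------------------
  idm <- identity_matrix(unname(proteins), match = params$align_match,
                         mismatch = params$align_mismatch,
                         gap = params$align_gap)
  emit(data.frame(id = rownames(idm), idm, check.names = FALSE), "identity.tsv")
  dmat <- (100 - idm) / 100
  diag(dmat) <- 0
  tree <- nj_tree(dmat)
  ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
  outputs[["tree.nwk"]] <- file.path(out_dir, "tree.nwk")
  subfam <- NULL
  if (!is.null(config$reference_classes)) {
    rc <- unlist(config$reference_classes)
    subfam <- assign_subfamilies(family, rc, dmat)
    emit(subfam, "subfamilies.tsv")
  }
  stage("phylogeny", sprintf("%d taxa", nrow(idm)))

  ## --- Ka/Ks, windows, dating ----------------------------------------------
  kaks_rows <- list(); window_tracks <- list()
  pairs <- config$paralog_pairs
  if (is.matrix(pairs)) pairs <- split(pairs, seq_len(nrow(pairs)))
  if (!is.null(pairs)) {
    for (pr in pairs) {
      a <- pr[[1L]]; b <- pr[[2L]]
      aln <- global_align(proteins[[a]], proteins[[b]],
                          match = params$align_match,
                          mismatch = params$align_mismatch,
                          gap = params$align_gap)
      caln <- back_translate(aln, cds[[a]], cds[[b]])
      est <- ng86_kaks(caln)
      date <- divergence_time(est$Ks, params$lambda)
      kaks_rows[[length(kaks_rows) + 1L]] <- data.frame(
        gene_a = a, gene_b = b, S = est$S_sites, N = est$N_sites,
        Sd = est$Sd, Nd = est$Nd, Ka = est$Ka, Ks = est$Ks,
        ratio = est$ratio, selection = classify_selection(est$ratio),
        date_mya = date, stringsAsFactors = FALSE)
      for (w in params$windows) {
        track <- sliding_window_kaks(caln, window_bp = w,
                                     step_bp = params$window_step)
        fname <- sprintf("window_%s_%s_%dbp.tsv", a, b, w)
        emit(track, fname)
        window_tracks[[fname]] <- track
      }
    }
    emit(do.call(rbind, kaks_rows), "kaks_pairs.tsv")
    stage("kaks", sprintf("%d pair(s)", length(pairs)))
  }

  ## --- promoter elements ---------------------------------------------------
  hit_list <- lapply(family, function(gid) {
    prom <- extract_promoter(models[[gid]], genome[[models[[gid]]$contig_id]],
                             upstream = params$promoter_upstream,
                             downstream = params$promoter_downstream)
    scan_elements(prom, library)
  })
  hits <- do.call(rbind, hit_list)
  emit(hits, "element_hits.tsv")
  tally <- element_tally(hits, family, library$name)
  emit(data.frame(gene = rownames(tally), tally, check.names = FALSE),
       "element_tally.tsv")
  stage("elements", sprintf("%d hits", nrow(hits)))

  ## --- co-expression network ----------------------------------------------
  seeds <- if (!is.null(config$seed_genes)) unlist(config$seed_genes) else family
  seeds <- intersect(seeds, rownames(expr))
  net <- build_network(expr, seeds, threshold = params$pearson_threshold)
  emit(net$edges, "network_edges.tsv")
  hubs <- shared_hubs(net, min_seed_degree = params$min_seed_degree)
  emit(hubs, "network_hubs.tsv")
  enr_rows <- list()
  all_neigh <- unique(unlist(lapply(seeds, seed_neighbors, net = net)))
  sel_sets <- c(list(all_seeds = setdiff(all_neigh, seeds)),
                setNames(lapply(seeds, function(s) {
                  setdiff(seed_neighbors(net, s), seeds)
                }), seeds))
  for (nm in names(sel_sets)) {
    er <- enrich_terms(sel_sets[[nm]], annotation, q_cut = params$q_cut)
    if (nrow(er) > 0L) {
      enr_rows[[nm]] <- cbind(data.frame(selection = nm,
                                         stringsAsFactors = FALSE), er)
    }
  }
  enr <- if (length(enr_rows) > 0L) do.call(rbind, enr_rows) else
    data.frame(selection = character(0), term = character(0))
  rownames(enr) <- NULL
  emit(enr, "enrichment.tsv")
  stage("network", sprintf("%d edges, %d shared hub(s)", nrow(net$edges),
                           nrow(hubs)))

  ## --- variant effects -----------------------------------------------------
  calls <- annotate_variants(variants, models, genome, tmh = tmh_by_gene)
  emit(calls, "variant_calls.tsv")
  summaries <- lapply(family, function(gid) {
    s <- summarize_gene(calls, models[[gid]], tmh = tmh_by_gene[[gid]])
    cbind(data.frame(gene = s$gene_id, gene_length_bp = s$gene_length_bp,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(s$counts)),
          data.frame(total = s$total, tmh_count = s$tmh_count,
                     tmh_pct = s$tmh_pct, density_per_kb = s$density_per_kb))
  })
  emit(do.call(rbind, summaries), "variant_summary.tsv")
  af <- do.call(rbind, lapply(variants, function(v) {
    data.frame(contig = v$contig_id, pos = v$pos, ref = v$ref, alt = v$alt,
               alt_freq = allele_frequency(v), stringsAsFactors = FALSE)
  }))
  emit(af, "allele_frequencies.tsv")
  stage("variants", sprintf("%d calls", nrow(calls)))

  ## --- manifest ------------------------------------------------------------
  manifest <- list(
    package = "nhxdiverge",
    version = as.character(utils::packageVersion("nhxdiverge")),
    parameters = params,
    inputs = as.list(tools::md5sum(in_paths)),
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage("manifest", "written")

  invisible(list(out_dir = out_dir, outputs = outputs,
                 characterization = do.call(rbind, char_rows),
                 identity = idm, tree = tree, subfamilies = subfam,
                 kaks = if (length(kaks_rows) > 0L) do.call(rbind, kaks_rows) else NULL,
                 window_tracks = window_tracks,
                 element_hits = hits, element_tally = tally,
                 network = net, hubs = hubs, enrichment = enr,
                 variant_calls = calls,
                 variant_summary = do.call(rbind, summaries),
                 allele_frequencies = af,
                 manifest = manifest))
}
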