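#' Relative expression from qPCR Ct values (2^-ddCt)
#'
#' Computes fold change of a target gene relative to a calibrator condition
#' using the comparative-Ct method: replicate Ct values are averaged on the
#' Ct scale, `dCt = target - reference` within each condition, and the fold
#' change is `2^-(dCt_sample - dCt_calibrator)`.
#'
#' @param sample,calibrator Lists with numeric elements `target_ct` and
#'   `reference_ct` (replicate vectors allowed).
#' @return Fold change (positive number; 1 means no change).
#' @export
relative_expression <- function(sample, calibrator) {
  dct <- function(x, what) {
    if (is.null(x$target_ct) || is.null(x$reference_ct) ||
        length(x$reference_ct) == 0L || anyNA(x$reference_ct)) {
      .stopf("%s is missing reference Ct values", what)
    }
    if (length(x$target_ct) == 0L || anyNA(x$target_ct)) {
      .stopf("%s is missing target Ct values", what)
    }
    ct <- c(x$target_ct, x$reference_ct)
    if (any(ct <= 0) || any(ct >= 50)) .stopf("Ct values must lie in (0, 50)")
    mean(x$target_ct) - mean(x$reference_ct)
  }
  2^-(dct(sample, "sample") - dct(calibrator, "calibrator"))
}

#' Pearson correlation with validation
#'
#' Sample Pearson correlation of two equal-length numeric vectors of length
#' at least 3; constant vectors are rejected (their correlation is
#' undefined).
#'
#' @param x,y Numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) .stopf("vectors must have equal length")
  if (length(x) < 3L) .stopf("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) .stopf("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    .stopf("correlation undefined for a constant vector")
  }
  stats::cor(x, y)
}

#' Build a Pearson-threshold co-expression network
#'
#' For each seed (family) gene, connects every other gene whose expression
#' profile has Pearson correlation strictly greater than `threshold`
#' (seed-seed edges follow the same rule). Profiles are `log2(x + 1)`
#' transformed by default before correlating; constant-profile genes are
#' skipped with a warning.
#'
#' @param m Expression matrix (genes x conditions, >= 3 conditions) as
#'   returned by [read_expression_matrix].
#' @param seeds Character vector of seed gene ids (must be rows of `m`).
#' @param threshold Correlation threshold; edges require `r > threshold`
#'   strictly (default 0.85).
#' @param log2_transform Apply `log2(x + 1)` before correlating.
#' @return Object of class `coexpression_network`: list with `nodes`,
#'   `edges` (data frame `gene_a`, `gene_b`, `r`; `gene_a < gene_b`),
#'   `seed_genes`, `threshold`, `skipped` (constant genes).
#' @export
build_network <- function(m, seeds, threshold = 0.85, log2_transform = TRUE) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) < 3L) .stopf("need at least 3 conditions")
  missing_seed <- setdiff(seeds, rownames(m))
  if (length(missing_seed) > 0L) {
    .stopf("seed '%s' absent from expression matrix", missing_seed[[1L]])
  }
  x <- if (log2_transform) log2(m + 1) else m
  sds <- apply(x, 1L, stats::sd)
  skipped <- rownames(x)[sds == 0]
  if (length(skipped) > 0L) {
    warning(sprintf("skipping %d constant-profile gene(s): %s",
                    length(skipped),
                    paste(utils::head(skipped, 3L), collapse = ", ")),
            call. = FALSE)
  }
  x <- x[sds > 0, , drop = FALSE]
  seeds_used <- intersect(seeds, rownames(x))
  edges <- data.frame(gene_a = character(0), gene_b = character(0),
                      r = numeric(0), stringsAsFactors = FALSE)
  if (length(seeds_used) > 0L && nrow(x) > 1L) {
    rmat <- stats::cor(t(x[seeds_used, , drop = FALSE]), t(x))
    pairs <- list()
    for (s in seeds_used) {
      r <- rmat[s, ]
      hit <- names(r)[r > threshold & names(r) != s]
      for (g in hit) {
        key <- paste(sort(c(s, g)), collapse = "\r")
        pairs[[key]] <- r[[g]]
      }
    }
    if (length(pairs) > 0L) {
      ab <- do.call(rbind, strsplit(names(pairs), "\r", fixed = TRUE))
      edges <- data.frame(gene_a = ab[, 1L], gene_b = ab[, 2L],
                          r = unname(unlist(pairs)), stringsAsFactors = FALSE)
      edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  structure(list(nodes = sort(unique(c(seeds, edges$gene_a, edges$gene_b))),
                 edges = edges, seed_genes = seeds, threshold = threshold,
                 skipped = skipped),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network: %d node(s), %d edge(s), %d seed(s), r > %g>\n",
              length(x$nodes), nrow(x$edges), length(x$seed_genes), x$threshold))
  invisible(x)
}

#' Genes co-expressed with a given seed
#'
#' @param net A `coexpression_network`.
#' @param seed One seed gene id.
#' @return Character vector of neighbours (any node linked to the seed).
#' @export
seed_neighbors <- function(net, seed) {
  stopifnot(inherits(net, "coexpression_network"))
  e <- net$edges
  sort(unique(c(e$gene_b[e$gene_a == seed], e$gene_a[e$gene_b == seed])))
}

#' Shared hub genes across family seeds
#'
#' Non-seed genes connected to at least `min_seed_degree` seed genes,
#' ordered by decreasing seed-degree then gene id.
#'
#' @param net A `coexpression_network` with >= 2 seeds.
#' @param min_seed_degree Minimum number of connected seeds (default 2).
#' @return Data frame with `gene`, `seed_degree` and `seeds`
#'   (comma-separated seed ids).
#' @export
shared_hubs <- function(net, min_seed_degree = 2L) {
  stopifnot(inherits(net, "coexpression_network"))
  if (length(net$seed_genes) < 2L) .stopf("need a network with at least 2 seeds")
  e <- net$edges
  seed_set <- net$seed_genes
  touch <- rbind(
    data.frame(gene = e$gene_b, seed = e$gene_a,
               stringsAsFactors = FALSE)[e$gene_a %in% seed_set, ],
    data.frame(gene = e$gene_a, seed = e$gene_b,
               stringsAsFactors = FALSE)[e$gene_b %in% seed_set, ])
  touch <- touch[!(touch$gene %in% seed_set), , drop = FALSE]
  if (nrow(touch) == 0L) {
    return(data.frame(gene = character(0), seed_degree = integer(0),
                      seeds = character(0), stringsAsFactors = FALSE))
  }
  touch <- unique(touch)
  spl <- split(touch$seed, touch$gene)
  out <- data.frame(gene = names(spl),
                    seed_degree = vapply(spl, length, integer(1L)),
                    seeds = vapply(spl, function(s) paste(sort(s), collapse = ","),
                                   character(1L)),
                    stringsAsFactors = FALSE)
  out <- out[out$seed_degree >= min_seed_degree, , drop = FALSE]
  out <- out[order(-out$seed_degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(K, N - K, n)`: the probability of
#' observing at least `k` annotated genes in a selection of size `n` drawn
#' from a background of `N` genes of which `K` carry the term.
#'
#' @param k Observed hits in the selection.
#' @param K Term size in the background.
#' @param n Selection size.
#' @param N Background size.
#' @return Probability in `[0, 1]`.
#' @export
hypergeometric_pvalue <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (anyNA(vals) || any(vals < 0) || K > N || n > N || k > min(K, n)) {
    .stopf("inconsistent counts: require 0 <= k <= min(K, n) and K, n <= N")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a p-value vector (wraps
#' `p.adjust(method = "BH")` after validating the input range).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1)) {
    .stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric term enrichment of a gene selection
#'
#' Tests each annotation term for over-representation in a selection (for
#' example a seed's co-expression neighbourhood) against a background of
#' all annotated genes, with BH control of the false discovery rate.
#'
#' @param selection Character vector of selected gene ids.
#' @param annotation Data frame with columns `gene_id` and `term` (flat
#'   gene-to-term map; one row per assignment).
#' @param background Background gene ids; defaults to all genes with at
#'   least one annotation.
#' @param q_cut Reported significance cut on the adjusted value (rows are
#'   returned regardless; `significant` flags `q < q_cut`).
#' @return Data frame with `term`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `significant`, ordered by `p`.
#' @export
enrich_terms <- function(selection, annotation, background = NULL,
                         q_cut = 0.05) {
  stopifnot(is.data.frame(annotation),
            all(c("gene_id", "term") %in% colnames(annotation)))
  if (is.null(background)) background <- unique(annotation$gene_id)
  annotation <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  selection <- intersect(unique(selection), background)
  N <- length(background)
  n <- length(selection)
  terms <- sort(unique(annotation$term))
  if (length(terms) == 0L || n == 0L) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), significant = logical(0)))
  }
  rows <- lapply(terms, function(tm) {
    genes_tm <- unique(annotation$gene_id[annotation$term == tm])
    K <- length(genes_tm)
    k <- length(intersect(genes_tm, selection))
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               p = hypergeometric_pvalue(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < q_cut
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
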