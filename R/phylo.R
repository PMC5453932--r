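#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj]) over a symmetric,
#' zero-diagonal distance matrix. Negative branch lengths, which NJ can
#' produce on non-additive matrices, are clamped to zero with the deficit
#' moved to the sister branch so that path lengths are preserved as far as
#' possible. On additive matrices the generating tree is recovered exactly.
#'
#' @param d Symmetric numeric matrix with labels as dimnames (or a `dist`).
#' @return An [ape::phylo] tree; serialize with [ape::write.tree].
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d))
  labels <- rownames(d)
  if (is.null(labels) || is.null(colnames(d)) || !identical(labels, colnames(d))) {
    .stopf("distance matrix must carry identical row and column labels")
  }
  if (nrow(d) < 2L) .stopf("need at least 2 labels")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-10))) {
    .stopf("distance matrix is not symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) .stopf("distance matrix diagonal must be zero")
  if (any(d < 0)) .stopf("distances must be non-negative")
  if (nrow(d) == 2L) {
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
                 edge.length = rep(d[1L, 2L] / 2, 2L),
                 tip.label = labels, Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(d))
  len <- tree$edge.length
  neg <- which(len < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1L]
    sibs <- setdiff(which(tree$edge[, 1L] == parent), e)
    if (length(sibs) > 0L) len[sibs[[1L]]] <- len[sibs[[1L]]] + len[[e]]
    len[[e]] <- 0
  }
  tree$edge.length <- pmax(len, 0)
  tree
}

#' Assign queries to subfamilies by nearest labelled reference
#'
#' Each query is given the class of its nearest reference under the supplied
#' distance matrix; exact ties are broken toward the lexicographically
#' smaller reference id and flagged.
#'
#' @param query_ids Character vector of query labels.
#' @param reference_classes Named character vector mapping reference id to
#'   class label (e.g. `c(refA = "Vac", refB = "PM")`).
#' @param d Distance matrix covering all queries and references.
#' @return Data frame with columns `query`, `class`, `nearest_reference`,
#'   `distance`, `tie`.
#' @export
assign_subfamilies <- function(query_ids, reference_classes, d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  refs <- names(reference_classes)
  if (is.null(refs) || length(refs) == 0L) {
    .stopf("reference_classes must be a named vector")
  }
  missing_q <- setdiff(query_ids, rownames(d))
  if (length(missing_q) > 0L) {
    .stopf("query '%s' missing from distance matrix", missing_q[[1L]])
  }
  missing_r <- setdiff(refs, rownames(d))
  if (length(missing_r) > 0L) {
    .stopf("reference '%s' missing from distance matrix", missing_r[[1L]])
  }
  refs <- sort(refs)   # lexicographic tie-break: first minimum wins
  rows <- lapply(query_ids, function(q) {
    dd <- d[q, refs]
    best <- which.min(dd)
    tie <- sum(dd == dd[[best]]) > 1L
    data.frame(query = q, class = unname(reference_classes[[refs[[best]]]]),
               nearest_reference = refs[[best]], distance = unname(dd[[best]]),
               tie = tie, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
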