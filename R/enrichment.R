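#' Hypergeometric gene-set enrichment
#'
#' For each set, tests over-representation of the selection in the set by
#' the upper-tail hypergeometric probability
#' `P[X >= k] = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`,
#' where `N` is the universe size, `K` the set size in the universe, `n`
#' the selection size in the universe, and `k` the overlap. Significance
#' is declared at raw `p < alpha` (matching how enrichment p-values are
#' conventionally reported for these maps); Benjamini-Hochberg adjusted
#' values are emitted as an extra, non-default column.
#'
#' @param selection Character vector of selected genes (e.g. UpCor); genes
#'   outside the universe are dropped with a warning.
#' @param collection A `gene_set_collection` (`sets` + `universe`).
#' @param alpha Raw significance level (default 0.05).
#' @return Data frame `set_id`, `k`, `K`, `n`, `N`, `p`, `p_adj`,
#'   `significant`, sorted by ascending p.
#' @export
hypergeometric_enrichment <- function(selection, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(collection$universe)
  if (length(universe) == 0L) stop("empty universe")
  if (length(selection) == 0L) stop("empty selection")
  selection <- unique(selection)
  outside <- setdiff(selection, universe)
  if (length(outside) > 0) {
    warning(length(outside), " selected gene(s) outside the universe dropped")
    selection <- intersect(selection, universe)
    if (length(selection) == 0L) stop("no selected genes in the universe")
  }
  N <- length(universe)
  n <- length(selection)
  rows <- lapply(names(collection$sets), function(id) {
    set <- intersect(unique(collection$sets[[id]]), universe)
    K <- length(set)
    k <- length(intersect(set, selection))
    # P[X >= k], upper tail of Hypergeometric(N, K, n)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p < alpha
  res <- res[order(res$p, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Population map of selected genes across enriched sets
#'
#' Binary gene x set membership matrix over the selection genes that
#' appear in at least one significant set, with genes and sets ordered by
#' hierarchical clustering (Euclidean distance, average linkage) of their
#' membership vectors, so that genes shared across pathways form visible
#' blocks.
#'
#' @param selection Character vector of selected genes.
#' @param enrichment Result of [hypergeometric_enrichment()].
#' @param collection The `gene_set_collection` used for enrichment.
#' @return Binary matrix (genes x significant sets), rows/columns in
#'   cluster order; a 0 x 0 matrix (with a message) if nothing is
#'   significant.
#' @export
population_map <- function(selection, enrichment, collection) {
  stopifnot(inherits(collection, "gene_set_collection"),
            is.data.frame(enrichment))
  sig <- enrichment$set_id[enrichment$significant]
  if (length(sig) == 0L) {
    message("no significant sets: empty population map")
    return(matrix(0L, 0L, 0L))
  }
  member <- vapply(sig, function(id)
    as.integer(selection %in% collection$sets[[id]]),
    integer(length(selection)))
  member <- matrix(member, nrow = length(selection),
                   dimnames = list(selection, sig))
  member <- member[rowSums(member) > 0L, , drop = FALSE]
  if (nrow(member) == 0L) {
    message("no selected gene belongs to a significant set")
    return(member)
  }
  row_ord <- if (nrow(member) > 2L)
    stats::hclust(stats::dist(member), method = "average")$order
  else seq_len(nrow(member))
  col_ord <- if (ncol(member) > 2L)
    stats::hclust(stats::dist(t(member)), method = "average")$order
  else seq_len(ncol(member))
  member[row_ord, col_ord, drop = FALSE]
}
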