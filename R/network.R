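#' Induce the direct-interaction subgraph of a gene selection
#'
#' Restricts an undirected interaction graph to the selected genes: nodes
#' are the intersection of selection and graph vertices, edges are the
#' interactions with both endpoints selected. No intermediate
#' ("interpolated") nodes are added. Inducing twice with the same
#' selection is a no-op.
#'
#' @param graph An [igraph::graph] with vertex names.
#' @param selection Character vector of genes.
#' @return The induced undirected subgraph (possibly empty, with a
#'   message).
#' @export
induce_subgraph <- function(graph, selection) {
  stopifnot(igraph::is_igraph(graph))
  keep <- intersect(unique(selection), igraph::V(graph)$name)
  if (length(keep) == 0L)
    message("selection does not intersect the interaction graph")
  igraph::induced_subgraph(graph, keep)
}

#' Connected components, hubs, and summary of an interaction subnetwork
#'
#' Decomposes the induced subgraph into connected components, reports the
#' components of two or more nodes (the "networks"), the largest-component
#' size, and a hub ranking: per component, nodes sorted by within-component
#' degree ("direct neighbors"), ties broken lexicographically by gene name.
#'
#' @param graph An undirected [igraph::graph] (typically from
#'   [induce_subgraph()]).
#' @return A `subnetwork_result` list: `components` (node lists, size
#'   descending), `largest_size`, `n_components_ge2`, `singletons`,
#'   `hub_ranking` (data frame `node`, `degree`, `component`).
#' @export
subnetwork_components <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0L) {
    return(structure(list(components = list(), largest_size = 0L,
                          n_components_ge2 = 0L, singletons = character(0),
                          hub_ranking = data.frame(node = character(0),
                                                   degree = integer(0),
                                                   component = integer(0))),
                     class = "subnetwork_result"))
  }
  comp <- igraph::components(graph)
  nodes <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  members <- split(nodes, comp$membership)
  sizes <- lengths(members)
  ord <- order(-sizes, vapply(members, min, character(1)))
  members <- members[ord]
  ge2 <- members[lengths(members) >= 2L]
  singles <- unlist(members[lengths(members) == 1L], use.names = FALSE)
  hub <- if (length(ge2) > 0) {
    do.call(rbind, lapply(seq_along(ge2), function(i) {
      m <- ge2[[i]]
      d <- deg[m]
      o <- order(-d, m)
      data.frame(node = m[o], degree = as.integer(d[o]), component = i,
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(node = character(0), degree = integer(0),
                    component = integer(0))
  rownames(hub) <- NULL
  structure(list(components = unname(ge2),
                 largest_size = if (length(members)) max(sizes) else 0L,
                 n_components_ge2 = length(ge2),
                 singletons = sort(singles),
                 hub_ranking = hub),
            class = "subnetwork_result")
}

#' @export
print.subnetwork_result <- function(x, ...) {
  cat("subnetwork_result:", x$n_components_ge2,
      "component(s) of >= 2 nodes; largest =", x$largest_size,
      "nodes;", length(x$singletons), "singleton(s)\n")
  if (nrow(x$hub_ranking) > 0)
    cat("top hub:", x$hub_ranking$node[1], "with",
        x$hub_ranking$degree[1], "direct neighbors\n")
  invisible(x)
}

#' Fraction of a selection captured by its largest interaction network
#'
#' `100 * largest_size / selection_size`, i.e. the percentage of selected
#' transcripts directly interconnected by known interactions. Reported
#' rounded to the nearest integer by default (full precision with
#' `rounded = FALSE`).
#'
#' @param largest_size Node count of the largest component.
#' @param selection_size Size of the gene selection.
#' @param rounded Round to the nearest integer percent.
#' @return Percentage (numeric).
#' @examples
#' network_fraction(57, 219)  # 26
#' @export
network_fraction <- function(largest_size, selection_size, rounded = TRUE) {
  if (selection_size <= 0) stop("'selection_size' must be positive")
  if (largest_size < 0) stop("'largest_size' must be non-negative")
  pct <- 100 * largest_size / selection_size
  if (rounded) round(pct) else pct
}

#' Permutation p-value for the largest-component size
#'
#' Null model: selections of the observed size drawn uniformly at random
#' from the graph's nodes (degree-unadjusted). For each of `n_perm` draws
#' the largest induced-component size is recorded; the p-value uses the
#' add-one correction `p = (1 + #[null >= observed]) / (n_perm + 1)`, so
#' `1/(n_perm+1) <= p <= 1` always. A degree-preserving variant
#' (`degree_bins`) stratifies the draw by node-degree quantile bins.
#'
#' @param graph The full interaction [igraph::graph].
#' @param selection_size Number of nodes drawn per permutation.
#' @param observed Observed largest-component size.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param degree_bins If > 1, draw within this many degree-quantile strata
#'   matching the observed selection's degree profile (requires
#'   `selection`).
#' @param selection Observed selection (only for `degree_bins > 1`).
#' @return A `permutation_null` list: `p`, `null_sizes`, `n_perm`,
#'   `observed`, `seed`.
#' @export
component_size_pvalue <- function(graph, selection_size, observed,
                                  n_perm = 999L, seed = 1L,
                                  degree_bins = 1L, selection = NULL) {
  stopifnot(igraph::is_igraph(graph))
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("'n_perm' must be >= 1")
  nodes <- igraph::V(graph)$name
  if (selection_size > length(nodes))
    stop("'selection_size' exceeds the number of graph nodes")
  use_strata <- degree_bins > 1L
  if (use_strata) {
    if (is.null(selection)) stop("degree-preserving draw needs 'selection'")
    deg <- igraph::degree(graph)
    breaks <- unique(stats::quantile(deg, probs = seq(0, 1,
                                                      length.out = degree_bins + 1)))
    bin <- cut(deg, breaks = breaks, include.lowest = TRUE)
    sel_bin <- bin[match(intersect(selection, nodes), nodes)]
    quota <- table(sel_bin)
    by_bin <- split(nodes, bin)
  }
  withr::with_seed(seed, {
    null_sizes <- vapply(seq_len(n_perm), function(i) {
      draw <- if (use_strata) {
        unlist(lapply(names(quota), function(b)
          sample(by_bin[[b]], min(quota[[b]], length(by_bin[[b]])))),
          use.names = FALSE)
      } else sample(nodes, selection_size)
      sub <- igraph::induced_subgraph(graph, draw)
      if (igraph::vcount(sub) == 0L) 0
      else max(igraph::components(sub)$csize)
    }, numeric(1))
  })
  p <- (1 + sum(null_sizes >= observed)) / (n_perm + 1)
  structure(list(p = p, null_sizes = null_sizes, n_perm = n_perm,
                 observed = observed, seed = as.integer(seed)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation_null: observed %d vs %d draws; p = %.4g\n",
              x$observed, x$n_perm, x$p))
  invisible(x)
}
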