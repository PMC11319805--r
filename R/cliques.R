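#' Detect grooming cliques
#'
#' Community detection on the weighted grooming network. The default
#' `fast_greedy` method is a deterministic modularity-maximising
#' agglomeration; `louvain` and `spinglass` are also available (spinglass
#' requires a connected graph). An edgeless network degrades to one clique
#' per individual with a warning.
#'
#' @param grooming symmetric non-negative weight matrix.
#' @param method `"fast_greedy"`, `"louvain"` or `"spinglass"`.
#' @param seed integer seed (stochastic methods only).
#' @return named integer vector of clique labels.
#' @export
detect_cliques <- function(grooming,
                           method = c("fast_greedy", "louvain", "spinglass"),
                           seed = 1L) {
  method <- match.arg(method)
  G <- as.matrix(grooming)
  stopifnot(nrow(G) == ncol(G))
  if (any(G < 0)) stop("detect_cliques: negative weights")
  if (!isTRUE(all.equal(G, t(G)))) stop("detect_cliques: matrix not symmetric")
  ids <- rownames(G)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(G)))
  if (all(G == 0)) {
    warning("detect_cliques: empty graph; each node is its own clique")
    return(stats::setNames(seq_len(nrow(G)), ids))
  }
  g <- igraph::graph_from_adjacency_matrix(G, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(derive_seed(seed, 7L))
  comm <- switch(method,
    fast_greedy = igraph::cluster_fast_greedy(g),
    louvain = igraph::cluster_louvain(g),
    spinglass = igraph::cluster_spinglass(g))
  labels <- igraph::membership(comm)
  # never return a partition worse than all-singletons
  singles <- seq_len(nrow(G))
  if (igraph::modularity(g, labels, weights = igraph::E(g)$weight) <
      igraph::modularity(g, singles, weights = igraph::E(g)$weight))
    labels <- singles
  stats::setNames(as.integer(labels), ids)
}

#' Modularity of a hard partition of a weighted network
#'
#' @param grooming symmetric weight matrix.
#' @param labels membership vector.
#' @return scalar modularity.
#' @export
partition_modularity <- function(grooming, labels) {
  g <- igraph::graph_from_adjacency_matrix(as.matrix(grooming),
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::modularity(g, as.integer(factor(labels)),
                     weights = igraph::E(g)$weight)
}
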