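#' Build a score-filtered protein interaction graph
#'
#' Keeps edges with `score > min_score` (strict inequality, the convention
#' for 0-1000 style interaction scores) whose endpoints both lie in
#' `node_subset` when one is given; nodes of the subset without a surviving
#' edge are retained as isolated, degree-0 nodes.
#'
#' @param edge_table Tibble from [read_ppi()] / [ppi_edge_table()].
#' @param node_subset Optional protein identifiers to restrict to (e.g. the
#'   drug-regulated features).
#' @param min_score Strict score threshold. Default 950.
#' @return A list of class `ppi_graph` with `graph` (an
#'   [igraph::make_graph()] object), `nodes`, `edges` (filtered tibble) and
#'   `degree_of` (named integer vector).
#' @export
build_graph <- function(edge_table, node_subset = NULL, min_score = 950) {
  edges <- dplyr::filter(edge_table, .data$score > .env$min_score)
  if (!is.null(node_subset)) {
    node_subset <- unique(as.character(node_subset))
    edges <- dplyr::filter(
      edges,
      .data$protein_a %in% node_subset, .data$protein_b %in% node_subset
    )
    nodes <- node_subset
  } else {
    nodes <- unique(c(edges$protein_a, edges$protein_b))
  }
  nodes <- sort(nodes, method = "radix")
  g <- igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b")],
    directed = FALSE,
    vertices = nodes
  )
  structure(
    list(
      graph = g,
      nodes = nodes,
      edges = tibble::as_tibble(edges),
      degree_of = igraph::degree(g)
    ),
    class = "ppi_graph"
  )
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf(
    "<ppi_graph> %d nodes, %d edges\n",
    length(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' @export
tidy.ppi_graph <- function(x, ...) {
  hub_ranking(x)
}

#' @export
glance.ppi_graph <- function(x, ...) {
  comp <- igraph::components(x$graph)
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    n_components = comp$no,
    max_degree = if (length(x$degree_of)) max(x$degree_of) else 0L
  )
}

#' Degree-based hub ranking
#'
#' Higher-degree nodes are treated as more functionally central; ties are
#' broken by node identifier so the ranking is reproducible.
#'
#' @param graph A `ppi_graph`.
#' @param top_n Number of nodes to return (default all).
#' @return Tibble with columns `node`, `degree`, sorted by descending
#'   degree, ties by node.
#' @export
hub_ranking <- function(graph, top_n = Inf) {
  deg <- graph$degree_of
  out <- tibble::tibble(node = names(deg), degree = as.integer(deg))
  out <- out[order(-out$degree, out$node, method = "radix"), , drop = FALSE]
  utils::head(out, n = top_n)
}

#' Connected clusters of a PPI graph
#'
#' Interaction-network clusters read as connected components of size at
#' least `min_cluster_size`.
#'
#' @param graph A `ppi_graph`.
#' @param min_cluster_size Minimum nodes per reported cluster. Default 3.
#' @return List of sorted node vectors, largest cluster first (ties by first
#'   member).
#' @export
connected_clusters <- function(graph, min_cluster_size = 3) {
  comp <- igraph::components(graph$graph)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, function(x) sort(x, method = "radix"))
  members <- members[lengths(members) >= min_cluster_size]
  ord <- order(
    -lengths(members),
    vapply(members, `[`, character(1), 1L),
    method = "radix"
  )
  unname(members[ord])
}
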