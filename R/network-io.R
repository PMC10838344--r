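#' Construct a pathway overlap network
#'
#' Nodes are pathways (with their enrichment statistics as attributes);
#' undirected edges connect pathways whose flip-gene memberships overlap
#' significantly. Built by [build_network()]; constructed directly only
#' in tests.
#'
#' @param nodes data frame with at least a `pathway` column; the usual
#'   attribute columns are `overlap`, `ef`, `p`, `fdr`, `cluster`,
#'   `flip_class`.
#' @param edges data frame with columns `from`, `to`, `shared_genes`,
#'   `jaccard`, `p`. May have zero rows.
#' @return Object of class `pathway_network`.
#' @export
pathway_network <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), "pathway" %in% names(nodes))
  if (anyDuplicated(nodes$pathway)) stop("duplicate pathway node")
  if (nrow(edges)) {
    stopifnot(all(c("from", "to") %in% names(edges)))
    if (any(edges$from == edges$to)) stop("self-loop edge")
    bad <- setdiff(c(edges$from, edges$to), nodes$pathway)
    if (length(bad)) stop("edge endpoint not a node: ", bad[1L])
  }
  structure(list(nodes = nodes, edges = edges), class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat("pathway_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

net_to_igraph <- function(net) {
  nodes <- net$nodes
  names(nodes)[names(nodes) == "pathway"] <- "name"
  if (nrow(net$edges)) {
    igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                  vertices = nodes)
  } else {
    g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
    for (col in names(nodes))
      g <- igraph::set_vertex_attr(g, col, value = nodes[[col]])
    g
  }
}

#' Write a pathway network as GraphML plus a JSON edge-list twin
#'
#' Emits a Cytoscape-loadable GraphML file carrying all node attributes
#' (enrichment factor, p, FDR, cluster, flip class) and edge attributes
#' (shared gene count, Jaccard, overlap p), together with a JSON twin
#' (`<path>.json`) holding the node and edge tables verbatim.
#'
#' @param net a [pathway_network()].
#' @param path GraphML output file; the JSON twin is written next to it.
#' @return Invisibly, `net`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "pathway_network"))
  igraph::write_graph(net_to_igraph(net), path, format = "graphml")
  jsonlite::write_json(list(nodes = net$nodes, edges = net$edges),
                       paste0(path, ".json"), digits = NA, na = "null")
  invisible(net)
}

#' Re-read a GraphML pathway network
#'
#' Parse-back counterpart of [write_network()], mainly for round-trip
#' validation.
#'
#' @param path GraphML file written by [write_network()].
#' @return A [pathway_network()].
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- as.data.frame(igraph::vertex_attr(g), stringsAsFactors = FALSE)
  nodes$id <- NULL
  names(nodes)[names(nodes) == "name"] <- "pathway"
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(from = el[, 1L], to = el[, 2L],
                      stringsAsFactors = FALSE)
  for (a in igraph::edge_attr_names(g))
    edges[[a]] <- igraph::edge_attr(g, a)
  pathway_network(nodes, edges)
}
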