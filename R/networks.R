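#' Adverse-event network container
#'
#' Undirected network of AE terms with scored edges, produced by either
#' co-occurrence method. Nodes are the AEs incident to at least one edge and
#' carry the fraction of patients they affect plus an optional anatomical
#' class from an annotation table.
#'
#' @param edges Tibble of undirected edges with columns `ae_i`, `ae_j`
#'   (reordered so `ae_i < ae_j`) plus method-specific metric columns.
#' @param prevalence Optional [ae_prevalence()] tibble used to attach node
#'   prevalence.
#' @param method Label for the method that produced the network.
#' @param annotations Optional tibble (`term`, `anatomical_class`).
#' @return An object of class `ae_network`: list with `nodes`, `edges`,
#'   `method`.
#' @export
ae_network <- function(edges, prevalence = NULL, method = "generic",
                       annotations = NULL) {
  edges <- as_tibble(edges)
  if (nrow(edges) > 0L) {
    swap <- edges$ae_i > edges$ae_j
    if (any(swap)) {
      tmp <- edges$ae_i[swap]
      edges$ae_i[swap] <- edges$ae_j[swap]
      edges$ae_j[swap] <- tmp
    }
    if (any(edges$ae_i == edges$ae_j)) stop("self-loop edge", call. = FALSE)
    key <- paste(edges$ae_i, edges$ae_j, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate undirected edge", call. = FALSE)
    edges <- edges[order(edges$ae_i, edges$ae_j), ]
  }
  terms <- sort(unique(c(edges$ae_i, edges$ae_j)))
  nodes <- tibble(term = terms, prevalence = NA_real_,
                  anatomical_class = NA_character_)
  if (!is.null(prevalence)) {
    idx <- match(nodes$term, prevalence$term)
    nodes$prevalence <- prevalence$prevalence[idx]
  }
  if (!is.null(annotations)) {
    idx <- match(nodes$term, annotations$term)
    nodes$anatomical_class <- as.character(annotations$anatomical_class[idx])
  }
  structure(list(nodes = nodes, edges = edges, method = method),
            class = "ae_network")
}

#' @export
print.ae_network <- function(x, ...) {
  cat(sprintf("AE network (%s): %d AEs, %d edges\n",
              x$method, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

edge_keys <- function(net) {
  if (nrow(net$edges) == 0L) return(character(0))
  paste(pmin(net$edges$ae_i, net$edges$ae_j),
        pmax(net$edges$ae_i, net$edges$ae_j), sep = "\r")
}

#' Compare two AE networks
#'
#' Measures the agreement of two networks over the same term universe:
#' shared node and edge counts, the fraction those represent of each network
#' (rounded to two decimals for reporting), and each network's
#' edges-per-node ratio (also two decimals).
#'
#' @param a,b [ae_network()] objects.
#' @return A list of class `network_comparison`.
#' @export
compare_networks <- function(a, b) {
  nodes_a <- a$nodes$term
  nodes_b <- b$nodes$term
  keys_a <- edge_keys(a)
  keys_b <- edge_keys(b)
  shared_nodes <- length(intersect(nodes_a, nodes_b))
  shared_edges <- length(intersect(keys_a, keys_b))
  ratio <- function(num, den) if (den > 0) round(num / den, 2) else NA_real_
  structure(list(
    n_nodes_a = length(nodes_a), n_edges_a = length(keys_a),
    n_nodes_b = length(nodes_b), n_edges_b = length(keys_b),
    shared_nodes = shared_nodes, shared_edges = shared_edges,
    shared_node_frac_a = ratio(shared_nodes, length(nodes_a)),
    shared_node_frac_b = ratio(shared_nodes, length(nodes_b)),
    shared_edge_frac_a = ratio(shared_edges, length(keys_a)),
    shared_edge_frac_b = ratio(shared_edges, length(keys_b)),
    edges_per_node_a = ratio(length(keys_a), length(nodes_a)),
    edges_per_node_b = ratio(length(keys_b), length(nodes_b))
  ), class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("Network comparison\n",
           "  A: %d AEs, %d edges (%.2f edges/AE)\n",
           "  B: %d AEs, %d edges (%.2f edges/AE)\n",
           "  shared: %d AEs (%.0f%% of A), %d edges (%.0f%% of A)\n"),
    x$n_nodes_a, x$n_edges_a, x$edges_per_node_a,
    x$n_nodes_b, x$n_edges_b, x$edges_per_node_b,
    x$shared_nodes, 100 * x$shared_node_frac_a,
    x$shared_edges, 100 * x$shared_edge_frac_a))
  invisible(x)
}

#' Convert an AE network to igraph
#'
#' @param net An [ae_network()].
#' @return An undirected [igraph::igraph] graph with node and edge attributes.
#' @export
as_igraph <- function(net) {
  nodes <- as.data.frame(net$nodes)
  names(nodes)[1] <- "name"
  edges <- as.data.frame(net$edges)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}
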