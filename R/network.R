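#' Extract the disease-specific subnetwork
#'
#' Induces the subgraph of the interactome on the selected genes, keeping
#' only edges whose weight reaches `weight_floor` (0.5 = medium
#' confidence).  With `prune_isolated = TRUE` (default), selected genes
#' left without any admissible edge are dropped from the node set, which
#' is why the final node count can fall below the number of selected genes.
#'
#' @param network A [weighted_network()].
#' @param selected_genes Genes spanning the subnetwork; genes absent from
#'   the network are reported via a warning.
#' @param weight_floor Minimum edge weight retained (default 0.5).
#' @param prune_isolated Drop nodes with no retained edge?
#' @return Object of class `subnetwork`: `nodes` (character vector),
#'   `edges` (data frame `gene1`, `gene2`, `weight`), `weight_floor`.
#' @export
extract_subnetwork <- function(network, selected_genes, weight_floor = 0.5,
                               prune_isolated = TRUE) {
  selected_genes <- unique(as.character(selected_genes))
  missing <- setdiff(selected_genes, network$genes)
  if (length(missing) > 0)
    warning(sprintf("%d selected genes are not in the network and were ignored",
                    length(missing)))
  sel <- sort(intersect(selected_genes, network$genes), method = "radix")
  sub <- weighted_network(sel, network$W[sel, sel, drop = FALSE])
  edges <- network_edges(sub)
  edges <- edges[edges$weight >= weight_floor, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- if (prune_isolated)
    sort(unique(c(edges$gene1, edges$gene2)), method = "radix")
  else sel
  structure(list(nodes = nodes, edges = edges, weight_floor = weight_floor),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("subnetwork: %d nodes, %d edges (weight floor %.3g)\n",
              length(x$nodes), nrow(x$edges), x$weight_floor))
  invisible(x)
}

adjacency_list <- function(nodes, edges) {
  i <- match(edges$gene1, nodes)
  j <- match(edges$gene2, nodes)
  adj <- vector("list", length(nodes))
  for (v in seq_along(nodes)) adj[[v]] <- integer(0)
  if (length(i) > 0) {
    by_i <- split(j, i)
    by_j <- split(i, j)
    for (nm in names(by_i)) adj[[as.integer(nm)]] <- c(adj[[as.integer(nm)]], by_i[[nm]])
    for (nm in names(by_j)) adj[[as.integer(nm)]] <- c(adj[[as.integer(nm)]], by_j[[nm]])
  }
  adj
}

#' k-core decomposition by recursive minimum-degree peeling
#'
#' Computes every node's core number: the largest `k` such that the node
#' belongs to the k-core, the maximal subgraph in which all nodes have at
#' least `k` neighbors within the subgraph.  Obtained by recursively
#' deleting nodes whose current degree is below the running threshold.
#' Edge weights are ignored (degrees are unweighted edge counts on the
#' already-thresholded subnetwork).
#'
#' @param sub A `subnetwork` (or any list with `nodes` and `edges`).
#' @return Object of class `core_decomposition`: `core_number` (named
#'   integer vector), `layers` (list indexed `"0"`, `"1"`, ... of gene
#'   sets; see [core_layers()]), `kmax`.
#' @export
k_core_decompose <- function(sub) {
  nodes <- sub$nodes
  adj <- adjacency_list(nodes, sub$edges)
  deg <- vapply(adj, length, integer(1))
  alive <- rep(TRUE, length(nodes))
  core <- integer(length(nodes))
  k <- 0L
  remaining <- length(nodes)
  while (remaining > 0L) {
    repeat {
      low <- which(alive & deg <= k)
      if (length(low) == 0L) break
      core[low] <- k
      alive[low] <- FALSE
      remaining <- remaining - length(low)
      for (v in low) {
        nb <- adj[[v]]
        nb <- nb[alive[nb]]
        deg[nb] <- deg[nb] - 1L
      }
    }
    k <- k + 1L
  }
  core <- stats::setNames(core, nodes)
  dec <- structure(list(core_number = core, kmax = if (length(core)) max(core) else 0L),
                   class = "core_decomposition")
  dec$layers <- core_layers(dec)
  dec
}

#' Core layers of a decomposition
#'
#' The k-core layer `l_k` is the set of nodes belonging to the k-core but
#' not the (k+1)-core, i.e. the nodes with core number exactly `k`; the
#' layers partition the node set and the k-core is the union of layers
#' `l_j`, `j >= k`.
#'
#' @param dec A `core_decomposition`.
#' @return Named list mapping `"k"` to the character vector of layer
#'   members, for every `k` from 0 to `kmax`.
#' @export
core_layers <- function(dec) {
  ks <- 0:dec$kmax
  layers <- lapply(ks, function(k)
    sort(names(dec$core_number)[dec$core_number == k], method = "radix"))
  names(layers) <- as.character(ks)
  layers
}

#' Three-way core-periphery partition
#'
#' Splits nodes by core number: outer layer (`core <= k_outer_max`), medium
#' layer (`k_outer_max < core <= k_medium_max`) and inner core
#' (`core > k_medium_max`).
#'
#' @param dec A `core_decomposition`.
#' @param k_outer_max,k_medium_max Ordered cutpoints
#'   (`0 < k_outer_max < k_medium_max`).
#' @return Object of class `core_periphery_partition`: `inner`, `medium`,
#'   `outer` gene sets and `cutpoints`.
#' @export
partition_core_periphery <- function(dec, k_outer_max = 10L, k_medium_max = 35L) {
  if (!(k_outer_max > 0 && k_medium_max > k_outer_max))
    stop("cutpoints must satisfy 0 < k_outer_max < k_medium_max")
  core <- dec$core_number
  nodes <- names(core)
  structure(list(
    inner = sort(nodes[core > k_medium_max], method = "radix"),
    medium = sort(nodes[core > k_outer_max & core <= k_medium_max],
                  method = "radix"),
    outer = sort(nodes[core <= k_outer_max], method = "radix"),
    cutpoints = c(k_outer_max = as.integer(k_outer_max),
                  k_medium_max = as.integer(k_medium_max))),
    class = "core_periphery_partition")
}

#' Per-layer composition counts for tagged gene sets
#'
#' Counts, for each core layer and each named gene set (seeds, drug
#' targets, ...), how many of the layer's nodes carry the tag.
#'
#' @param dec A `core_decomposition`.
#' @param tagged_sets Named list of character gene-id vectors.
#' @return Data frame with columns `layer`, `n_nodes`, then one count
#'   column per tag.
#' @export
layer_composition <- function(dec, tagged_sets = list()) {
  layers <- core_layers(dec)
  out <- data.frame(layer = as.integer(names(layers)),
                    n_nodes = vapply(layers, length, integer(1)),
                    row.names = NULL)
  for (tag in names(tagged_sets))
    out[[tag]] <- vapply(layers, function(l)
      length(intersect(l, tagged_sets[[tag]])), integer(1))
  out
}

#' Flag subnetwork nodes belonging to a reference gene set
#'
#' @param sub A `subnetwork`.
#' @param reference Character vector of reference gene identifiers.
#' @param label Annotation label used in the report message.
#' @return Named logical vector over `sub$nodes`; the count of `TRUE`
#'   entries is reported via a message.
#' @export
annotate_membership <- function(sub, reference, label = "reference") {
  flag <- stats::setNames(sub$nodes %in% reference, sub$nodes)
  message(sprintf("%d of %d subnetwork nodes are in the %s set",
                  sum(flag), length(flag), label))
  flag
}

#' Export a subnetwork as GraphML
#'
#' Writes a GraphML file (via igraph) with edge weights and optional
#' per-node attributes for external viewers.
#'
#' @param sub A `subnetwork`.
#' @param path Output file path.
#' @param node_attrs Optional data frame of node attributes with a `gene`
#'   column matching `sub$nodes`.
#' @return The path, invisibly.
#' @export
write_subnetwork_graphml <- function(sub, path, node_attrs = NULL) {
  vdf <- data.frame(name = sub$nodes, stringsAsFactors = FALSE)
  if (!is.null(node_attrs)) {
    stopifnot("gene" %in% names(node_attrs))
    vdf <- cbind(vdf, node_attrs[match(sub$nodes, node_attrs$gene),
                                 setdiff(names(node_attrs), "gene"),
                                 drop = FALSE])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = sub$edges$gene1, to = sub$edges$gene2,
               weight = sub$edges$weight, stringsAsFactors = FALSE),
    directed = FALSE, vertices = vdf)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
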