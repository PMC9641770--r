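#' Undirected networks as symmetric adjacency matrices
#'
#' Throughout the package an undirected network is represented as a symmetric
#' binary adjacency matrix with node names as dimnames. The node order of the
#' matrix is the node order of the network. These helpers construct such
#' matrices from edge lists and back.
#'
#' @param nodes character vector giving the node order.
#' @param edges two-column matrix or data.frame of node name pairs (may be
#'   empty for an edgeless network).
#' @return `make_network()` returns a symmetric 0/1 matrix; `network_edges()`
#'   a data.frame with columns `a`, `b` (one row per unordered edge, a < b in
#'   node order).
#' @examples
#' g <- make_network(c("s", "g1", "t1"), rbind(c("s", "g1"), c("g1", "t1")))
#' network_edges(g)
#' @export
make_network <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicated node names")
  adj <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2) stop("edges must have two columns")
    a <- as.character(edges[, 1]); b <- as.character(edges[, 2])
    bad <- !(a %in% nodes) | !(b %in% nodes)
    if (any(bad)) stop("edges reference unknown nodes: ",
                       paste(unique(c(a[bad], b[bad])), collapse = ", "))
    if (any(a == b)) stop("self loops are not allowed")
    adj[cbind(a, b)] <- 1
    adj[cbind(b, a)] <- 1
  }
  adj
}

#' @rdname make_network
#' @param adj symmetric adjacency matrix.
#' @export
network_edges <- function(adj) {
  adj <- check_network(adj)
  idx <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  data.frame(a = rownames(adj)[idx[, 1]], b = colnames(adj)[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' @rdname make_network
#' @export
n_edges <- function(adj) {
  sum(adj[upper.tri(adj)] != 0)
}

check_network <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stop("adjacency must be a square matrix")
  if (is.null(rownames(adj))) stop("adjacency must carry node names")
  if (any(adj != t(adj))) stop("adjacency must be symmetric")
  if (any(diag(adj) != 0)) stop("self loops are not allowed")
  adj
}

as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
}

# Deterministic key for an unordered node pair.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Read and write edge-list TSV files
#'
#' Networks are serialized as tab-separated edge lists with a header
#' (`node_a`, `node_b`, plus any per-edge statistic columns). Isolated nodes
#' are preserved through an optional `nodes` attribute line handled by the
#' `nodes` argument on read.
#'
#' @param adj adjacency matrix (see [make_network()]).
#' @param path file path.
#' @export
write_edge_list <- function(adj, path) {
  ed <- network_edges(adj)
  data.table::fwrite(
    data.frame(node_a = ed$a, node_b = ed$b),
    path, sep = "\t")
  invisible(path)
}

#' @rdname write_edge_list
#' @param nodes optional full node order; defaults to nodes seen in the file.
#' @export
read_edge_list <- function(path, nodes = NULL) {
  ed <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (is.null(nodes))
    nodes <- sort(unique(c(ed$node_a, ed$node_b)))
  make_network(nodes, as.matrix(ed[, c("node_a", "node_b")]))
}
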