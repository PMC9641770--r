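#' Network propagation scores by random walk with restart
#'
#' Computes steady-state visiting probabilities of a random walk that, at
#' each step, restarts with probability `restart` to a uniform distribution
#' over the seed nodes and otherwise moves to a uniformly chosen neighbour.
#' Mass at degree-zero nodes is returned to the seeds (dangling-node rule).
#' The fixed point of
#' \deqn{s = (1 - r) P^T s + r e}
#' is found by power iteration.
#'
#' @param graph undirected igraph.
#' @param seeds character vector of seed node names (must exist in `graph`).
#' @param restart restart probability in (0, 1], default 0.5.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter iteration cap.
#' @return named nonnegative vector over all graph nodes, summing to 1.
#' @export
propagate_node_scores <- function(graph, seeds, restart = 0.5,
                                  tol = 1e-10, max_iter = 100000) {
  nodes <- igraph::V(graph)$name
  missing <- setdiff(seeds, nodes)
  if (length(missing))
    stop("seed node(s) absent from graph: ", paste(missing, collapse = ", "))
  if (!length(seeds)) stop("at least one seed is required")
  stopifnot(restart > 0, restart <= 1)

  n <- length(nodes)
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  deg <- Matrix::rowSums(A)
  e <- setNames(numeric(n), nodes)
  e[unique(seeds)] <- 1 / length(unique(seeds))

  s <- e
  for (it in seq_len(max_iter)) {
    walk <- numeric(n)
    live <- deg > 0
    if (any(live))
      walk <- as.numeric(Matrix::crossprod(A[live, , drop = FALSE],
                                           s[live] / deg[live]))
    dangling <- sum(s[!live])
    s_new <- (1 - restart) * (walk + dangling * e) + restart * e
    if (sum(abs(s_new - s)) < tol) {
      s <- s_new
      break
    }
    s <- s_new
  }
  s <- s / sum(s)
  setNames(as.numeric(s), nodes)
}

#' Genes on minimum node-cost shortest paths
#'
#' Converts propagation scores to nonnegative node costs
#' `W(v) = max(PS) - PS(v)` (order-equivalent to weighting nodes by -PS) and
#' extracts, for every (trans entity, cis gene) pair, the single
#' minimum-interior-cost path -- endpoint costs are excluded, so directly
#' adjacent pairs cost 0. Cost ties are broken by the lexicographically
#' smallest node-name sequence. Disconnected pairs contribute nothing.
#'
#' @param graph undirected igraph (PPI augmented with CpG nodes).
#' @param scores named propagation score vector ([propagate_node_scores()]).
#' @param from,to character vectors of endpoint node names (pairs outside
#'   the graph are skipped).
#' @return sorted character vector: the union of interior nodes over all
#'   chosen paths.
#' @export
shortest_path_genes <- function(graph, scores, from, to) {
  nodes <- igraph::V(graph)$name
  if (length(bad <- setdiff(names(scores), nodes)) ||
      length(setdiff(nodes, names(scores))))
    stop("scores must be defined exactly on the graph nodes")
  cost <- max(scores) - scores[nodes]
  from <- intersect(from, nodes)
  to <- intersect(to, nodes)

  interior <- character()
  for (s in from) {
    paths <- dijkstra_paths(graph, cost, s)
    for (t in setdiff(to, s)) {
      p <- paths[[t]]
      if (is.null(p)) next # disconnected
      if (length(p) > 2) interior <- c(interior, p[-c(1, length(p))])
    }
  }
  sort(unique(interior))
}

# Dijkstra with node costs charged on entry (source excluded); for a fixed
# source the argmin path to t under interior cost equals the argmin under
# entry cost since cost(t) is a constant shift. Ties broken by
# lexicographically smallest node-name path.
dijkstra_paths <- function(graph, cost, source) {
  nodes <- igraph::V(graph)$name
  n <- length(nodes)
  adj <- igraph::adjacent_vertices(graph, nodes)
  eps <- 1e-12

  dist <- setNames(rep(Inf, n), nodes)
  path <- setNames(vector("list", n), nodes)
  done <- setNames(logical(n), nodes)
  dist[source] <- 0
  path[[source]] <- source

  lex_less <- function(a, b) {
    k <- min(length(a), length(b))
    for (i in seq_len(k)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
    length(a) < length(b)
  }

  for (step in seq_len(n)) {
    open <- which(!done & is.finite(dist))
    if (!length(open)) break
    dmin <- min(dist[open])
    cand <- open[dist[open] <= dmin + eps]
    u <- names(cand)[1]
    if (length(cand) > 1) {
      for (v in names(cand)[-1]) if (lex_less(path[[v]], path[[u]])) u <- v
    }
    done[u] <- TRUE
    for (v in names(adj[[u]])) {
      if (done[v]) next
      nd <- dist[u] + cost[v]
      np <- c(path[[u]], v)
      if (nd < dist[v] - eps ||
          (nd <= dist[v] + eps && lex_less(np, path[[v]]))) {
        dist[v] <- nd
        path[[v]] <- np
      }
    }
  }
  path[!done] <- list(NULL)
  path
}
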