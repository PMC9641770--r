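# Shared fixture objects, built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    .fixture_cache$spec <- fixture_spec(seed = 11)
    .fixture_cache$fx <- make_locus_fixture(.fixture_cache$spec)
  }
  list(spec = .fixture_cache$spec, fx = .fixture_cache$fx)
}

default_prior <- function() {
  if (is.null(.fixture_cache$prior)) {
    d <- default_fixture()
    .fixture_cache$prior <- make_prior_reference(d$fx, d$spec)
  }
  .fixture_cache$prior
}

pair_key_test <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# Random Erdos-Renyi-style adjacency with named nodes.
random_network <- function(n_nodes, p_edge = 0.2) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  adj <- matrix(0, n_nodes, n_nodes, dimnames = list(nodes, nodes))
  ut <- which(upper.tri(adj))
  on <- ut[runif(length(ut)) < p_edge]
  adj[on] <- 1
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}

# Prior matrix whose support is exactly the edge set of a graph.
prior_from_graph <- function(adj, strength = 0.9) {
  P <- matrix(pseudo_prior(), nrow(adj), ncol(adj), dimnames = dimnames(adj))
  P[adj != 0] <- strength
  diag(P) <- 0
  P
}

# Brute-force confusion counts by explicit pair enumeration.
brute_confusion <- function(pred, truth) {
  nodes <- sort(union(rownames(pred), rownames(truth)))
  has_edge <- function(adj, a, b) {
    a %in% rownames(adj) && b %in% rownames(adj) && adj[a, b] != 0
  }
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (j <= i) next
      p <- has_edge(pred, nodes[i], nodes[j])
      t <- has_edge(truth, nodes[i], nodes[j])
      if (p && t) tp <- tp + 1L
      else if (!p && !t) tn <- tn + 1L
      else if (p && !t) fp <- fp + 1L
      else fn <- fn + 1L
    }
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

brute_mcc <- function(c) {
  num <- c$tp * c$tn - c$fp * c$fn
  den <- sqrt(c$tp + c$fp) * sqrt(c$tp + c$fn) *
    sqrt(c$tn + c$fp) * sqrt(c$tn + c$fn)
  if (den == 0) 0 else num / den
}
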