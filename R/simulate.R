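#' Sample a ground-truth graph from a prior matrix
#'
#' Includes edge (i, j) iff its prior exceeds the pseudo-prior and a
#' uniform draw u_ij <= p_ij. Deterministic given the RNG state.
#'
#' @param P prior matrix ([assemble_prior_matrix()]).
#' @return adjacency matrix in the prior's node order.
#' @export
sample_graph_from_priors <- function(P) {
  nodes <- rownames(P)
  adj <- matrix(0, nrow(P), ncol(P), dimnames = dimnames(P))
  ut <- which(upper.tri(P))
  u <- runif(length(ut))
  on <- P[ut] > pseudo_prior() & u <= P[ut]
  adj[ut[on]] <- 1
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}

#' Degree-preserving rewiring that injects prior error
#'
#' Replaces a requested fraction of the graph's original edges by repeated
#' double-edge swaps (two edges (a,b), (c,d) on four distinct nodes are
#' replaced by (a,d), (c,b) or (a,c), (b,d)). Every introduced edge must be
#' absent from the prior support (prior <= 1e-7), no self loops or parallel
#' edges arise, and the degree sequence and edge count are exactly
#' preserved. Swapping continues until `ceiling(fraction * |E|)` of the
#' original edges have been removed; since one swap can remove two original
#' edges, swaps overshooting the target are avoided whenever an exact
#' alternative exists (the realized count can exceed the target by at most
#' one). After `max_tries` failed proposals an error is raised
#' (near-complete prior support can make the constraint infeasible).
#'
#' @param G adjacency matrix.
#' @param fraction fraction of original edges to replace, in [0, 1].
#' @param P prior matrix on the same nodes.
#' @param max_tries total proposal budget (default 1e5).
#' @param restarts number of fresh swap sequences attempted before
#'   declaring the constraint infeasible: the constrained swap walk cannot
#'   revisit prior-supported slots, so an unlucky sequence can dead-end on
#'   a feasible instance (default 20).
#' @export
rewire_with_error <- function(G, fraction, P, max_tries = 1e5,
                              restarts = 20) {
  stopifnot(fraction >= 0, fraction <= 1)
  check_network(G)
  if (fraction == 0) return(G)
  if (n_edges(G) < 2) stop("rewiring needs at least two edges")
  budget <- ceiling(max_tries / restarts)
  for (attempt in seq_len(restarts)) {
    out <- rewire_once(G, fraction, P, budget)
    if (!is.null(out)) return(out)
  }
  stop("rewiring infeasible: exceeded ", max_tries, " proposals over ",
       restarts, " restarts without replacing ",
       ceiling(fraction * n_edges(G)), " original edges")
}

# One constrained swap sequence; NULL when the proposal budget runs out.
rewire_once <- function(G, fraction, P, max_tries) {
  ed <- network_edges(G)
  m <- nrow(ed)
  target <- ceiling(fraction * m)
  adj <- G
  orig_keys <- pair_key(ed$a, ed$b)
  replaced <- character() # original edges currently absent
  edges <- as.matrix(ed)

  allowed <- function(a, b) {
    a != b && adj[a, b] == 0 && P[a, b] <= pseudo_prior()
  }

  tries <- 0
  while (length(replaced) < target) {
    tries <- tries + 1
    if (tries > max_tries) return(NULL)
    k <- sample.int(nrow(edges), 2)
    e1 <- edges[k[1], ]; e2 <- edges[k[2], ]
    if (length(unique(c(e1, e2))) < 4) next
    # prefer swaps that hit the target exactly; overshoot by one only as a
    # last resort (a swap can remove two original edges at once)
    would_remove <- length(setdiff(
      intersect(pair_key(c(e1[1], e2[1]), c(e1[2], e2[2])), orig_keys),
      replaced))
    if (length(replaced) + would_remove > target && tries <= max_tries / 2)
      next
    # two possible reconnections; try them in random order
    opts <- list(rbind(c(e1[1], e2[2]), c(e2[1], e1[2])),
                 rbind(c(e1[1], e2[1]), c(e1[2], e2[2])))
    for (opt in sample(opts)) {
      if (allowed(opt[1, 1], opt[1, 2]) && allowed(opt[2, 1], opt[2, 2])) {
        adj[e1[1], e1[2]] <- adj[e1[2], e1[1]] <- 0
        adj[e2[1], e2[2]] <- adj[e2[2], e2[1]] <- 0
        adj[opt[1, 1], opt[1, 2]] <- adj[opt[1, 2], opt[1, 1]] <- 1
        adj[opt[2, 1], opt[2, 2]] <- adj[opt[2, 2], opt[2, 1]] <- 1
        edges <- edges[-k, , drop = FALSE]
        edges <- rbind(edges, opt)
        old_keys <- pair_key(c(e1[1], e2[1]), c(e1[2], e2[2]))
        new_keys <- pair_key(opt[, 1], opt[, 2])
        replaced <- union(replaced, intersect(old_keys, orig_keys))
        replaced <- setdiff(replaced, new_keys)
        break
      }
    }
  }
  adj
}

#' Simulate Gaussian data with a graph-structured covariance
#'
#' Builds a precision matrix supported exactly on the graph: off-diagonal
#' entries drawn uniformly from +/-[0.4, 0.8] on edges and 0 elsewhere, the
#' diagonal set to |lambda_min| + 0.1 of the off-diagonal part to force
#' positive definiteness. The covariance (its inverse) is standardized to
#' unit variances and rows are drawn i.i.d. multivariate normal with mean 0.
#'
#' @param G adjacency matrix.
#' @param n sample count (>= 2).
#' @param edge_range magnitude range of precision entries on edges.
#' @return list: `data` (n x p matrix, columns named by nodes, all
#'   continuous), `precision` (generating precision after standardization),
#'   `sigma` (target covariance/correlation).
#' @export
simulate_gaussian <- function(G, n, edge_range = c(0.4, 0.8)) {
  check_network(G)
  stopifnot(n >= 2)
  p <- nrow(G)
  nodes <- rownames(G)

  omega <- matrix(0, p, p, dimnames = dimnames(G))
  ut <- which(upper.tri(G) & G != 0)
  if (length(ut)) {
    mag <- runif(length(ut), edge_range[1], edge_range[2])
    sgn <- sample(c(-1, 1), length(ut), replace = TRUE)
    omega[ut] <- mag * sgn
    omega[lower.tri(omega)] <- t(omega)[lower.tri(omega)]
  }
  lam_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  diag(omega) <- abs(lam_min) + 0.1

  sigma <- solve(omega)
  d <- sqrt(diag(sigma))
  sigma <- sigma / tcrossprod(d)
  precision <- solve(sigma)
  precision[abs(precision) < 1e-12] <- 0 # scaling keeps the zero pattern

  ch <- chol(sigma)
  z <- matrix(rnorm(n * p), n, p)
  x <- z %*% ch
  colnames(x) <- nodes
  list(data = x, precision = precision, sigma = sigma)
}

#' Discretize a continuous column into genotype dosages
#'
#' Cuts the column at its empirical order-statistic quantiles (type 1) at
#' cumulative levels f0 and f0+f1; values <= q1 become dosage 0, values
#' <= q2 dosage 1, the rest dosage 2. Dosage counts match floor(n * f)
#' within +/-1; classes with zero frequency are simply absent.
#'
#' @param column numeric vector.
#' @param dosage_freqs numeric length-3 vector (f0, f1, f2) summing to 1.
#' @export
discretize_snp <- function(column, dosage_freqs) {
  stopifnot(length(dosage_freqs) == 3,
            abs(sum(dosage_freqs) - 1) < 1e-9, all(dosage_freqs >= 0))
  cum <- cumsum(dosage_freqs)
  q1 <- if (dosage_freqs[1] > 0)
    quantile(column, cum[1], type = 1, names = FALSE) else -Inf
  q2 <- if (dosage_freqs[2] > 0)
    quantile(column, cum[2], type = 1, names = FALSE) else q1
  if (dosage_freqs[3] == 0)
    q2 <- max(column)
  as.integer(ifelse(column <= q1, 0L, ifelse(column <= q2, 1L, 2L)))
}

#' Thin a prior matrix to a kept fraction of its informative entries
#'
#' Uniformly selects `round((1 - keep_fraction) * m)` of the m non-pseudo
#' entries and resets them to the pseudo-prior, emulating incomplete prior
#' knowledge. Pseudo entries are never touched; symmetry is preserved.
#'
#' @param P prior matrix.
#' @param keep_fraction fraction of informative entries to keep, in (0, 1].
#' @export
degrade_priors <- function(P, keep_fraction) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  if (keep_fraction == 1) return(P)
  cls <- attr(P, "prior_class")
  ut <- which(upper.tri(P) & P > pseudo_prior())
  n_drop <- round((1 - keep_fraction) * length(ut))
  if (n_drop == 0) return(P)
  drop <- sample(ut, n_drop)
  idx <- arrayInd(drop, dim(P))
  mirror <- cbind(idx[, 2], idx[, 1])
  out <- P
  out[idx] <- pseudo_prior()
  out[mirror] <- pseudo_prior()
  if (!is.null(cls)) {
    cls[idx] <- "pseudo"
    cls[mirror] <- "pseudo"
    attr(out, "prior_class") <- cls
  }
  out
}
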