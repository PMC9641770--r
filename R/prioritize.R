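#' Graph score for hotspot network prioritization
#'
#' Scores an inferred network by biologically desirable structure. Only the
#' connected component (cluster) containing the sentinel SNP is considered.
#' With cis genes \eqn{G_C} and trans entities \eqn{T} of the locus set:
#' \itemize{
#'   \item \eqn{G_S}: cis genes in the cluster adjacent to the SNP or to
#'     another cis gene (1-hop);
#'   \item \eqn{\bar G_S}: cis genes in the cluster in neither case;
#'   \item \eqn{G_T}: trans entities reachable from some cis gene by a path
#'     traversing neither the SNP nor another trans entity;
#'   \item \eqn{\bar G_T}: trans entities adjacent to the SNP;
#'   \item \eqn{D_G}: edge density of the cluster.
#' }
#' \deqn{S_G = -\log_{10}(D_G)\left[\frac{|G_S| - |\bar G_S|}{|G_C|}
#'   + \frac{|G_T| - |\bar G_T|}{|T|}\right]}
#' The score is 0 when the SNP is absent from the network or no cis gene
#' lies in its cluster; sparser graphs score higher through the density
#' term.
#'
#' @param G adjacency matrix (nodes must be locus-set nodes).
#' @param ls locus set.
#' @return list of class `graph_score`: `score`, `density`, and the role
#'   breakdown (`g_s`, `g_s_bar`, `g_t`, `g_t_bar` as node vectors).
#' @export
graph_score <- function(G, ls) {
  check_network(G)
  if (!length(ls$cis_genes) || !length(ls$trans_entities))
    stop("malformed locus set: needs at least one cis gene and one trans entity")
  unknown <- setdiff(rownames(G), ls$nodes)
  if (length(unknown))
    stop("network nodes outside the locus set: ",
         paste(unknown, collapse = ", "))

  zero <- structure(list(score = 0, density = NA_real_,
                         g_s = character(), g_s_bar = character(),
                         g_t = character(), g_t_bar = character()),
                    class = "graph_score")
  snp <- ls$snp
  if (!snp %in% rownames(G)) return(zero)

  ig <- as_igraph(G)
  comp <- igraph::components(ig)
  cluster <- names(which(comp$membership == comp$membership[snp]))
  cis_in <- intersect(ls$cis_genes, cluster)
  if (!length(cis_in)) return(zero)

  sub <- G[cluster, cluster, drop = FALSE]
  n <- length(cluster)
  dens <- n_edges(sub) / (n * (n - 1) / 2)

  adj_of <- function(v) names(which(sub[v, ] != 0))
  g_s <- cis_in[vapply(cis_in, function(g) {
    nb <- adj_of(g)
    snp %in% nb || length(intersect(nb, setdiff(cis_in, g))) > 0
  }, FALSE)]
  g_s_bar <- setdiff(cis_in, g_s)

  trans_in <- intersect(ls$trans_entities, cluster)
  g_t_bar <- trans_in[vapply(trans_in, function(t) snp %in% adj_of(t), FALSE)]

  # reachability from cis genes on the cluster with the SNP and the *other*
  # trans entities removed (BFS per trans entity)
  g_t <- trans_in[vapply(trans_in, function(t) {
    keep <- setdiff(cluster, c(snp, setdiff(trans_in, t)))
    if (!t %in% keep) return(FALSE)
    sg <- sub[keep, keep, drop = FALSE]
    cg <- igraph::components(as_igraph(sg))
    any(cg$membership[intersect(cis_in, keep)] == cg$membership[t])
  }, FALSE)]

  score <- -log10(dens) *
    ((length(g_s) - length(g_s_bar)) / length(ls$cis_genes) +
       (length(g_t) - length(g_t_bar)) / length(ls$trans_entities))
  structure(list(score = score, density = dens, g_s = g_s,
                 g_s_bar = g_s_bar, g_t = g_t, g_t_bar = g_t_bar),
            class = "graph_score")
}

#' @export
print.graph_score <- function(x, ...) {
  cat(sprintf(
    "graph score %.4f (density %s; |G_S| %d, |G_S bar| %d, |G_T| %d, |G_T bar| %d)\n",
    x$score, ifelse(is.na(x$density), "-", signif(x$density, 3)),
    length(x$g_s), length(x$g_s_bar), length(x$g_t), length(x$g_t_bar)))
  invisible(x)
}

#' GWAS-catalog membership filter for a hotspot
#'
#' TRUE iff any LD proxy or alias rsID of the hotspot SNP appears in the
#' catalog. Proxy retrieval (R-squared > 0.8 SNPs plus aliases) happens
#' upstream; this consumes the prepared lookup table.
#'
#' @param snp_id sentinel SNP id.
#' @param proxies data.frame with columns `snp` and `proxy` (one row per
#'   proxy/alias rsID; include the SNP itself as its own proxy row if
#'   direct matches should count).
#' @param catalog character vector of catalog rsIDs.
#' @export
gwas_filter <- function(snp_id, proxies, catalog) {
  mine <- proxies$proxy[proxies$snp == snp_id]
  if (!length(mine)) {
    warning("SNP ", snp_id, " missing from the proxy table")
    return(FALSE)
  }
  any(mine %in% catalog)
}

#' Consensus network across cohorts
#'
#' Keeps only edges present in both networks; nodes without any surviving
#' adjacent edge are dropped. Commutative, associative and idempotent.
#'
#' @param net_a,net_b adjacency matrices.
#' @export
merge_networks <- function(net_a, net_b) {
  check_network(net_a); check_network(net_b)
  shared <- intersect(rownames(net_a), rownames(net_b))
  common <- (net_a[shared, shared, drop = FALSE] != 0) &
    (net_b[shared, shared, drop = FALSE] != 0)
  keep <- shared[rowSums(common) > 0]
  (common[keep, keep, drop = FALSE]) * 1
}

#' Rank hotspot networks for downstream analysis
#'
#' Orders entries by graph score (descending), then edge count and node
#' count (ascending, preferring smaller networks), then hotspot id.
#'
#' @param entries data.frame with columns `hotspot`, `score`, `edges`,
#'   `nodes`.
#' @return the data.frame reordered, with a `rank` column prepended.
#' @export
rank_networks <- function(entries) {
  stopifnot(all(c("hotspot", "score", "edges", "nodes") %in% names(entries)))
  ord <- order(-entries$score, entries$edges, entries$nodes,
               entries$hotspot)
  out <- entries[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
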