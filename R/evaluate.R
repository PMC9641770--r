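#' Edge confusion counts between two networks
#'
#' Classifies every unordered node pair over the union of the two node sets
#' (a node absent from one network contributes no edges there) as TP, FP,
#' FN or TN.
#'
#' @param pred,truth adjacency matrices (node sets may differ).
#' @return list of class `confusion_counts` with fields `tp`, `tn`, `fp`,
#'   `fn`; they always sum to `n * (n - 1) / 2` over the union node set.
#' @export
confusion <- function(pred, truth) {
  check_network(pred); check_network(truth)
  nodes <- sort(union(rownames(pred), rownames(truth)))
  expand <- function(adj) {
    out <- matrix(0, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    out[rownames(adj), colnames(adj)] <- (adj != 0) * 1
    out
  }
  a <- expand(pred); b <- expand(truth)
  ut <- upper.tri(a)
  structure(list(tp = sum(a[ut] == 1 & b[ut] == 1),
                 tn = sum(a[ut] == 0 & b[ut] == 0),
                 fp = sum(a[ut] == 1 & b[ut] == 0),
                 fn = sum(a[ut] == 0 & b[ut] == 1)),
            class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' with the convention that a zero denominator factor yields 0.
#'
#' @param c `confusion_counts` object (or list with tp/tn/fp/fn).
#' @return value in [-1, 1].
#' @export
mcc <- function(c) {
  tp <- as.numeric(c$tp); tn <- as.numeric(c$tn)
  fp <- as.numeric(c$fp); fn <- as.numeric(c$fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Sensitivity and specificity of edge recovery
#'
#' `TP / (TP + FN)` and `TN / (TN + FP)`, with 0/0 defined as 0.
#' @param c `confusion_counts` object.
#' @return named numeric vector `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(c) {
  sens <- if (c$tp + c$fn == 0) 0 else c$tp / (c$tp + c$fn)
  spec <- if (c$tn + c$fp == 0) 0 else c$tn / (c$tn + c$fp)
  c(sensitivity = sens, specificity = spec)
}

#' Cross-cohort replication MCC
#'
#' MCC between two inferred networks (symmetric whenever the node sets
#' coincide), the replication measure between cohorts.
#' @param net_a,net_b adjacency matrices.
#' @export
cross_cohort_mcc <- function(net_a, net_b) {
  mcc(confusion(net_a, net_b))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d  (MCC %.4f)\n",
              x$tp, x$tn, x$fp, x$fn, mcc(x)))
  invisible(x)
}

#' Summarize prior and replication support of inferred edges
#'
#' For every edge of an inferred network, reports whether it carried prior
#' evidence (prior above the pseudo floor), whether it is present in a
#' replication network, and the absolute marginal correlation of its
#' endpoints in gaussianized replication data. Edges with an endpoint
#' missing from the replication data are flagged and get no correlation.
#'
#' @param inferred adjacency matrix.
#' @param P prior matrix covering the inferred nodes.
#' @param replication_data samples x nodes matrix from the replication
#'   cohort.
#' @param replication_net adjacency matrix inferred on the replication
#'   cohort.
#' @return data.frame: `a`, `b`, `has_prior`, `replicated`, `abs_cor`,
#'   `complete` (FALSE when an endpoint is missing).
#' @export
edge_support_summary <- function(inferred, P, replication_data,
                                 replication_net) {
  ed <- network_edges(inferred)
  if (!nrow(ed))
    return(data.frame(a = character(), b = character(),
                      has_prior = logical(), replicated = logical(),
                      abs_cor = numeric(), complete = logical()))
  rep_edges <- if (is.null(replication_net)) character() else {
    re <- network_edges(replication_net)
    pair_key(re$a, re$b)
  }
  g <- gaussianize(replication_data)
  out <- lapply(seq_len(nrow(ed)), function(k) {
    a <- ed$a[k]; b <- ed$b[k]
    complete <- a %in% colnames(g) && b %in% colnames(g)
    data.frame(
      a = a, b = b,
      has_prior = P[a, b] > pseudo_prior(),
      replicated = pair_key(a, b) %in% rep_edges,
      abs_cor = if (complete) abs(cor(g[, a], g[, b])) else NA_real_,
      complete = complete, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
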