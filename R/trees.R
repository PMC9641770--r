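#' Tree-ensemble regulatory link ranking
#'
#' For each column as target, fits a random-forest regression on all other
#' columns and takes the impurity importance of each predictor as the
#' directed link weight, normalized to sum to one per target. Directed
#' weights are symmetrized by the maximum of the two directions and the
#' unordered links returned in nonincreasing weight order. Deterministic
#' given `seed` (forests run single-threaded with per-target seeds).
#'
#' @param data samples x nodes matrix.
#' @param num_trees trees per forest (default 1000).
#' @param seed integer seed.
#' @return data.frame of class `ranked_links`: `a`, `b`, `weight`
#'   (nonincreasing), plus a `nodes` attribute with the column order.
#' @export
tree_ensemble_links <- function(data, num_trees = 1000, seed = 1) {
  data <- as.matrix(data)
  p <- ncol(data)
  if (p < 3) stop("need at least 3 columns")
  nodes <- colnames(data)

  W <- matrix(0, p, p, dimnames = list(nodes, nodes)) # W[i, j]: i -> j
  for (j in seq_len(p)) {
    df <- data.frame(data[, -j, drop = FALSE])
    names(df) <- nodes[-j]
    df$.target <- data[, j]
    fit <- ranger::ranger(
      dependent.variable.name = ".target", data = df,
      num.trees = num_trees, importance = "impurity",
      num.threads = 1, seed = seed + j)
    imp <- fit$variable.importance[nodes[-j]]
    imp[!is.finite(imp) | imp < 0] <- 0
    if (sum(imp) > 0) imp <- imp / sum(imp)
    W[nodes[-j], j] <- imp
  }

  sym <- pmax(W, t(W))
  ut <- which(upper.tri(sym), arr.ind = TRUE)
  links <- data.frame(a = nodes[ut[, 1]], b = nodes[ut[, 2]],
                      weight = sym[ut], stringsAsFactors = FALSE)
  links <- links[order(-links$weight, links$a, links$b), ]
  rownames(links) <- NULL
  attr(links, "nodes") <- nodes
  class(links) <- c("ranked_links", class(links))
  links
}
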