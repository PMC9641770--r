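#' Scale-free-topology cutoff selection for ranked links
#'
#' Screens up to 200 weight quantiles as candidate cutoffs (all unique
#' weights if fewer). For each cutoff, the network of links with weight at
#' or above the cutoff is formed and its goodness of fit to a scale-free
#' degree distribution computed: log10 degree frequency is regressed on
#' log10 degree over logarithmically spaced degree bins (10 bins,
#' zero-frequency bins dropped) and the regression R-squared taken.
#' Candidates occupying fewer than 3 bins (degenerate degree
#' distributions, e.g. stars) are assigned no fit. Among candidates with
#' R-squared > 0.8 the one with the most edges is returned; otherwise the
#' candidate with the highest R-squared; if no candidate has enough bins,
#' the largest candidate network, with a warning.
#'
#' @param links `ranked_links` data.frame ([tree_ensemble_links()]), or any
#'   data.frame with columns `a`, `b`, `weight`.
#' @param n_quantiles number of candidate cutoffs (default 200).
#' @param r2_threshold scale-free fit threshold (default 0.8).
#' @param n_bins number of logarithmic degree bins (default 10).
#' @return list: `network` (adjacency), `cutoff`, `r2`, `profile`
#'   (data.frame cutoff/edges/r2).
#' @export
scale_free_cutoff <- function(links, n_quantiles = 200,
                              r2_threshold = 0.8, n_bins = 10) {
  nodes <- attr(links, "nodes")
  if (is.null(nodes)) nodes <- sort(unique(c(links$a, links$b)))
  w <- links$weight
  uw <- sort(unique(w))
  cutoffs <- if (length(uw) <= n_quantiles) uw else
    sort(unique(quantile(w, probs = seq(0, 1, length.out = n_quantiles),
                         type = 1, names = FALSE)))

  profile <- data.frame(cutoff = cutoffs, edges = NA_real_, r2 = NA_real_)
  nets <- vector("list", length(cutoffs))
  for (k in seq_along(cutoffs)) {
    sel <- links[links$weight >= cutoffs[k], , drop = FALSE]
    adj <- make_network(nodes, sel[, c("a", "b")])
    nets[[k]] <- adj
    profile$edges[k] <- nrow(sel)
    profile$r2[k] <- scale_free_r2(adj, n_bins = n_bins)
  }

  ok <- !is.na(profile$r2)
  good <- ok & profile$r2 > r2_threshold & profile$edges > 0
  if (any(good)) {
    pick <- which(good)[which.max(profile$edges[good])]
  } else if (any(ok)) {
    pick <- which(ok)[which.max(profile$r2[ok])]
  } else {
    warning("no candidate network has enough distinct degrees for a ",
            "scale-free fit; returning the largest candidate")
    pick <- which.max(profile$edges)
  }
  list(network = nets[[pick]], cutoff = cutoffs[pick],
       r2 = profile$r2[pick], profile = profile)
}

# R-squared of log10(frequency) ~ log10(degree) over log-spaced degree bins;
# NA when fewer than 3 occupied bins.
scale_free_r2 <- function(adj, n_bins = 10) {
  deg <- rowSums(adj != 0)
  deg <- deg[deg > 0]
  if (!length(deg)) return(NA_real_)
  breaks <- unique(10^seq(0, log10(max(deg) + 1), length.out = n_bins + 1))
  if (length(breaks) < 2) return(NA_real_)
  bin <- cut(deg, breaks = breaks, include.lowest = TRUE, right = FALSE)
  freq <- tapply(deg, bin, length)
  mid <- tapply(deg, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(as.numeric(freq[keep])) ~
                     log10(as.numeric(mid[keep])))
  summary(fit)$r.squared
}
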