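#' Prior constants
#'
#' `pseudo_prior()` is the floor probability assigned to edges without any
#' supporting evidence; `tf_prior()` the fixed prior for TF-target edges
#' with binding-site evidence; `prior_cap()` the upper clip keeping priors
#' strictly below 1 so Bernoulli sampling and prior odds stay well defined.
#' @export
pseudo_prior <- function() 1e-7

#' @rdname pseudo_prior
#' @export
tf_prior <- function() 0.99

#' @rdname pseudo_prior
#' @export
prior_cap <- function() 0.999999

new_prior_map <- function(a = character(), b = character(),
                          prior = numeric(), class = character()) {
  data.frame(node_a = pmin(a, b), node_b = pmax(a, b), prior = prior,
             class = class, stringsAsFactors = FALSE)
}

#' SNP-to-gene edge priors from a reference eQTL table
#'
#' Computes the local false discovery rate over all p-values of the
#' reference eQTL table and assigns each SNP-gene pair the prior
#' `1 - lfdr`. Pairs absent from the table fall back to the pseudo-prior at
#' matrix assembly.
#'
#' @param eqtl data.frame with columns `snp`, `gene`, `p`.
#' @param snp sentinel SNP id.
#' @param genes cis genes of the locus set.
#' @param lfdr_min_n minimum table size for the lfdr fit.
#' @return prior map (`node_a`, `node_b`, `prior`, `class`).
#' @export
snp_gene_priors <- function(eqtl, snp, genes, lfdr_min_n = 200) {
  stopifnot(all(c("snp", "gene", "p") %in% names(eqtl)))
  fit <- estimate_lfdr(eqtl$p, min_n = lfdr_min_n)
  sel <- eqtl$snp == snp & eqtl$gene %in% genes
  if (!any(sel)) return(new_prior_map())
  new_prior_map(eqtl$snp[sel], eqtl$gene[sel], 1 - fit$lfdr[sel],
                rep("snp_gene", sum(sel)))
}

#' Preprocess a reference expression matrix for co-expression priors
#'
#' log2(x+1), per-sample quantile normalization, per-gene rank-based
#' inverse-normal transform, then removal of the projection onto the first
#' `n_pcs` principal components.
#'
#' @param raw samples x genes numeric matrix (no missing values).
#' @param n_pcs number of principal components to remove (default 10).
#' @export
preprocess_reference_expression <- function(raw, n_pcs = 10) {
  if (anyNA(raw)) stop("reference expression must not contain NAs")
  if (n_pcs >= min(dim(raw)))
    stop("n_pcs must be smaller than min(samples, genes)")
  x <- log2(raw + 1)
  x <- t(limma::normalizeQuantiles(t(x))) # limma normalizes columns=samples
  x <- apply(x, 2, function(col)
    qnorm((rank(col, ties.method = "average") - 0.5) / length(col)))
  rownames(x) <- rownames(raw)
  if (n_pcs > 0) {
    x <- scale(x, center = TRUE, scale = FALSE)
    pc <- prcomp(x, center = FALSE, rank. = n_pcs)
    x <- x - pc$x %*% t(pc$rotation)
  }
  x
}

#' Gene-to-gene co-expression priors for PPI-connected pairs
#'
#' For each eligible gene pair connected in the PPI network, computes the
#' Pearson correlation p-value on the reference expression, fits the lfdr
#' over all pair p-values, and sets the prior to `1 - lfdr`. Pairs with a
#' gene missing from the reference expression are dropped (pseudo-prior at
#' assembly) with a message.
#'
#' @param reference_expression preprocessed samples x genes matrix.
#' @param ppi undirected igraph of PPIs.
#' @param pairs two-column matrix/data.frame of candidate gene pairs
#'   (typically all role-eligible pairs of the locus set); only
#'   PPI-connected, non-self pairs are scored.
#' @param lfdr_min_n minimum number of scored pairs for the lfdr fit.
#' @export
gene_gene_priors <- function(reference_expression, ppi, pairs,
                             lfdr_min_n = 200) {
  if (!NROW(pairs)) return(new_prior_map())
  pairs <- as.matrix(pairs)
  a <- as.character(pairs[, 1]); b <- as.character(pairs[, 2])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  dup <- duplicated(pair_key(a, b))
  a <- a[!dup]; b <- b[!dup]

  vn <- igraph::V(ppi)$name
  in_ppi <- a %in% vn & b %in% vn
  connected <- logical(length(a))
  if (any(in_ppi))
    connected[in_ppi] <- igraph::get_edge_ids(
      ppi, as.vector(rbind(a[in_ppi], b[in_ppi]))) != 0
  a <- a[connected]; b <- b[connected]
  if (!length(a)) return(new_prior_map())

  have <- a %in% colnames(reference_expression) &
    b %in% colnames(reference_expression)
  if (any(!have))
    message(sum(!have), " PPI pair(s) missing from reference expression; ",
            "left at pseudo-prior")
  a <- a[have]; b <- b[have]
  if (!length(a)) return(new_prior_map())

  n <- nrow(reference_expression)
  pv <- vapply(seq_along(a), function(k) {
    r <- cor(reference_expression[, a[k]], reference_expression[, b[k]])
    r <- max(min(r, 1 - 1e-15), -1 + 1e-15)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }, 0)
  pv <- pmax(pv, .Machine$double.xmin)
  fit <- estimate_lfdr(pv, min_n = lfdr_min_n)
  new_prior_map(a, b, 1 - fit$lfdr, rep("gene_gene", length(a)))
}

#' CpG-to-gene priors from chromatin-state segmentations
#'
#' The prior for a CpG is the (optionally cell-type-weighted) proportion of
#' reference cell lines in which the 200 bp chromHMM window containing the
#' CpG carries a TSS-related state ([tss_states()]). The prior is assigned
#' only to CpG-gene pairs whose genomic distance (CpG position to gene
#' interval) is at most `max_distance` bp.
#'
#' @param cpgs data.frame with `target_id`, `target_chrom`, `target_pos`.
#' @param cpg_gene_pairs two-column matrix of (CpG id, gene id) candidates,
#'   e.g. trans CpGs against their neighbouring genes.
#' @param annotation gene annotation table.
#' @param chromhmm stacked segmentation table ([read_chromhmm()]).
#' @param weights optional named numeric vector of cell-type weights (e.g.
#'   population-mean blood cell proportions), named by cell line; cell
#'   lines without a weight receive the mean weight.
#' @param max_distance distance cutoff in bp (default 200).
#' @export
cpg_gene_priors <- function(cpgs, cpg_gene_pairs, annotation, chromhmm,
                            weights = NULL, max_distance = 200) {
  if (!NROW(cpg_gene_pairs)) return(new_prior_map())
  bad <- setdiff(unique(chromhmm$state), chromhmm_states())
  if (length(bad)) stop("unknown chromHMM state mnemonic(s): ",
                        paste(bad, collapse = ", "))
  cells <- unique(chromhmm$cell)
  w <- rep(1, length(cells))
  names(w) <- cells
  if (!is.null(weights)) {
    known <- intersect(cells, names(weights))
    w[known] <- weights[known]
    if (length(known) && length(known) < length(cells))
      w[setdiff(cells, known)] <- mean(weights[known])
  }

  p_tx <- vapply(unique(cpgs$target_id), function(id) {
    row <- cpgs[cpgs$target_id == id, ][1, ]
    seg <- chromhmm[chromhmm$chrom == row$target_chrom, ]
    # half-open windows: the window [start, end) containing the position
    hit <- seg[seg$start < row$target_pos & row$target_pos <= seg$end, ]
    states <- setNames(hit$state, hit$cell)
    present <- intersect(cells, names(states))
    if (!length(present)) return(0)
    sum(w[present] * (states[present] %in% tss_states())) / sum(w[present])
  }, 0)

  a <- as.character(cpg_gene_pairs[, 1])
  b <- as.character(cpg_gene_pairs[, 2])
  keep <- vapply(seq_along(a), function(k) {
    row <- cpgs[cpgs$target_id == a[k], ]
    ann <- annotation[annotation$gene_id == b[k], ]
    if (!nrow(row) || !nrow(ann)) return(FALSE)
    if (row$target_chrom[1] != ann$chrom[1]) return(FALSE)
    d <- IRanges::distance(
      IRanges::IRanges(row$target_pos[1], row$target_pos[1]),
      iranges0(ann$start[1], ann$end[1]))
    isTRUE(d <= max_distance)
  }, FALSE)
  if (!any(keep)) return(new_prior_map())
  new_prior_map(a[keep], b[keep], unname(p_tx[a[keep]]),
                rep("cpg_gene", sum(keep)))
}

#' TF-to-target priors from binding-site evidence
#'
#' Assigns the fixed prior 0.99 to every (TF, trans target) pair whose
#' binding evidence meets the locus-set windows: a TFBS within 50 bp of a
#' trans CpG, or inside a trans gene's promoter (2000 bp upstream / 1000 bp
#' downstream of the TSS). Self pairs are skipped.
#'
#' @param tfs character vector of locus-set TFs.
#' @param targets trans-entity data.frame (as in [select_tfs()]).
#' @param tfbs cell-type-filtered TFBS table.
#' @param annotation gene annotation table.
#' @export
tf_target_priors <- function(tfs, targets, tfbs, annotation) {
  hits <- tfbs_hits(targets, tfbs, annotation)
  hits <- hits[hits$tf_id %in% tfs & hits$tf_id != hits$target_id, ,
               drop = FALSE]
  if (!nrow(hits)) return(new_prior_map())
  new_prior_map(hits$tf_id, hits$target_id,
                rep(tf_prior(), nrow(hits)),
                rep("tf_target", nrow(hits)))
}

#' Assemble the symmetric per-edge prior matrix of a locus set
#'
#' Combines the class-specific prior maps into one symmetric matrix in
#' locus-set node order. Every unordered pair may be claimed by at most one
#' prior class; unset or zero entries receive the pseudo-prior 1e-7 and all
#' values are clipped to [1e-7, 0.999999].
#'
#' @param locus_set locus set (or any object with a `nodes` field).
#' @param maps list of prior maps from the `*_priors()` builders.
#' @return symmetric numeric matrix with a `prior_class` attribute
#'   (character matrix of per-edge class tags, `"pseudo"` for floor
#'   entries).
#' @export
assemble_prior_matrix <- function(locus_set, maps) {
  nodes <- locus_set$nodes
  stopifnot(length(nodes) >= 2)
  all_maps <- do.call(rbind, c(list(new_prior_map()), maps))
  all_maps <- all_maps[all_maps$node_a %in% nodes &
                         all_maps$node_b %in% nodes, , drop = FALSE]
  key <- pair_key(all_maps$node_a, all_maps$node_b)
  dup_key <- unique(key[duplicated(key)])
  if (length(dup_key)) {
    msgs <- vapply(head(dup_key, 5), function(k) {
      rows <- all_maps[key == k, ]
      sprintf("%s-%s [%s]", rows$node_a[1], rows$node_b[1],
              paste(sort(unique(rows$class)), collapse = "+"))
    }, "")
    stop("pair(s) claimed by more than one prior class: ",
         paste(msgs, collapse = ", "))
  }

  P <- matrix(pseudo_prior(), length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  cls <- matrix("pseudo", length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (nrow(all_maps)) {
    val <- pmin(pmax(all_maps$prior, pseudo_prior()), prior_cap())
    P[cbind(all_maps$node_a, all_maps$node_b)] <- val
    P[cbind(all_maps$node_b, all_maps$node_a)] <- val
    cls[cbind(all_maps$node_a, all_maps$node_b)] <- all_maps$class
    cls[cbind(all_maps$node_b, all_maps$node_a)] <- all_maps$class
  }
  diag(P) <- 0
  diag(cls) <- ""
  attr(P, "prior_class") <- cls
  P
}

#' Scalar density prior from sampled graphs
#'
#' The binomial density prior
#' \deqn{p_{rbinom} = \max\left(\frac{1}{N_S}\,
#'   \frac{\sum_G |E_G|}{|E_T|},\ 10^{-7}\right)}
#' with \eqn{|E_T| = n(n-1)/2} possible edges, summarizing a set of sampled
#' ground-truth graphs by a single edge probability.
#'
#' @param sampled_graphs list of adjacency matrices on `n_nodes` nodes.
#' @param n_nodes node count.
#' @export
density_prior <- function(sampled_graphs, n_nodes) {
  if (!length(sampled_graphs)) stop("at least one sampled graph is required")
  stopifnot(all(vapply(sampled_graphs, nrow, 0L) == n_nodes))
  total <- sum(vapply(sampled_graphs, n_edges, 0))
  e_t <- n_nodes * (n_nodes - 1) / 2
  max(total / length(sampled_graphs) / e_t, pseudo_prior())
}

#' Serialize / read a prior matrix as long-format TSV
#'
#' Columns `node_a`, `node_b`, `prior`, `class`; pseudo entries are not
#' written and are restored on read from the node order given in the
#' header comment line.
#' @param P prior matrix.
#' @param path file path.
#' @export
write_prior_matrix <- function(P, path) {
  nodes <- rownames(P)
  cls <- attr(P, "prior_class")
  idx <- which(upper.tri(P) & P > pseudo_prior(), arr.ind = TRUE)
  dt <- data.frame(node_a = nodes[idx[, 1]], node_b = nodes[idx[, 2]],
                   prior = P[idx],
                   class = if (is.null(cls)) "" else cls[idx])
  con <- file(path, "w")
  writeLines(paste0("# nodes: ", paste(nodes, collapse = ",")), con)
  close(con)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_prior_matrix
#' @export
read_prior_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "# nodes: "))
    stop("missing node-order header line")
  nodes <- strsplit(sub("^# nodes: ", "", header), ",", fixed = TRUE)[[1]]
  dt <- data.table::fread(path, sep = "\t", skip = 1L, header = TRUE)
  P <- matrix(pseudo_prior(), length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  cls <- matrix("pseudo", length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (nrow(dt)) {
    P[cbind(dt$node_a, dt$node_b)] <- dt$prior
    P[cbind(dt$node_b, dt$node_a)] <- dt$prior
    cls[cbind(dt$node_a, dt$node_b)] <- dt$class
    cls[cbind(dt$node_b, dt$node_a)] <- dt$class
  }
  diag(P) <- 0
  diag(cls) <- ""
  attr(P, "prior_class") <- cls
  P
}
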