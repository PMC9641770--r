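#' Specification for the synthetic fixture universe
#'
#' Parameters of the generated miniature genome and cohort data. Defaults
#' describe a single meQTL hotspot with three cis genes, five trans CpGs
#' (each with one overlapping gene), two TFs reached through a PPI path
#' with one known interior gene each, a background PPI of `n_background`
#' genes, reference data of `n_reference` samples and cohorts of
#' `n_samples` samples at a SNP minor allele frequency of `maf`.
#'
#' @param n_cis,n_trans,n_tfs number of planted cis genes, trans CpGs, TFs.
#' @param n_background background PPI genes (prior-reference universe).
#' @param n_reference reference-panel samples for prior construction.
#' @param n_samples per-cohort sample count.
#' @param maf SNP minor allele frequency.
#' @param prior_fraction fraction of true edges receiving prior evidence in
#'   [make_prior_reference()].
#' @param seed RNG seed; identical specs yield byte-identical fixtures.
#' @export
fixture_spec <- function(n_cis = 3, n_trans = 5, n_tfs = 2,
                         n_background = 150, n_reference = 300,
                         n_samples = 200, maf = 0.3,
                         prior_fraction = 1, seed = 1) {
  stopifnot(n_cis >= 1, n_trans >= 1, n_tfs >= 1, n_tfs <= n_trans,
            maf > 0, maf <= 0.5, prior_fraction >= 0, prior_fraction <= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a complete hotspot fixture on disk
#'
#' Writes annotation, TFBS, PPI and QTL tables in their external formats
#' (TSV/BED), reads them back through the package readers, extracts the
#' hotspot and builds its locus set, and returns the planted ground-truth
#' network over the locus-set nodes. The construction guarantees the
#' planted roles are recovered: cis genes lie inside the 1 Mbp window (one
#' decoy gene outside), each CpG carries a TFBS of its assigned TF within
#' 50 bp, and each TF connects to a cis gene through exactly one
#' interior PPI gene.
#'
#' @param spec [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return list: `paths` (named file paths), `hotspot`, `locus_set`,
#'   `truth` (adjacency over locus-set nodes), `annotation`, `tfbs`,
#'   `ppi`, `expressed`.
#' @export
make_locus_fixture <- function(spec, dir = tempfile("fixture")) {
  set.seed(spec$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  snp <- "rs1"
  snp_pos <- 10000000L
  cis <- sprintf("cis%02d", seq_len(spec$n_cis))
  cpgs <- sprintf("cg%02d", seq_len(spec$n_trans))
  cpg_pos <- 1000000L + 10000L * seq_len(spec$n_trans)
  tgt <- sprintf("tgt%02d", seq_len(spec$n_trans))
  tfs <- sprintf("tf%d", seq_len(spec$n_tfs))
  sp <- sprintf("sp%d", seq_len(spec$n_tfs))
  bg <- sprintf("bg%03d", seq_len(spec$n_background))
  tf_of <- setNames(tfs[(seq_len(spec$n_trans) - 1) %% spec$n_tfs + 1],
                    cpgs)

  # --- annotation (1-based TSV) -------------------------------------------
  ann <- rbind(
    data.frame(gene_id = cis, chrom = "chr1",
               start = snp_pos + 50000L * seq_len(spec$n_cis),
               end = snp_pos + 50000L * seq_len(spec$n_cis) + 20000L,
               strand = rep(c("+", "-"), length.out = spec$n_cis)),
    data.frame(gene_id = "decoy1", chrom = "chr1",
               start = snp_pos + 600001L, end = snp_pos + 620000L,
               strand = "+"),
    data.frame(gene_id = tgt, chrom = "chr2",
               start = cpg_pos - 100L, end = cpg_pos + 500L, strand = "+"),
    data.frame(gene_id = tfs, chrom = "chr3",
               start = 1000000L + 100000L * seq_len(spec$n_tfs),
               end = 1000000L + 100000L * seq_len(spec$n_tfs) + 30000L,
               strand = "+"),
    data.frame(gene_id = c(sp, bg), chrom = "chr4",
               start = 1000000L + 50000L * seq_along(c(sp, bg)),
               end = 1000000L + 50000L * seq_along(c(sp, bg)) + 20000L,
               strand = "+"))
  ann_path <- file.path(dir, "annotation.tsv")
  data.table::fwrite(ann, ann_path, sep = "\t")

  # --- TFBS (BED, 0-based): one site per CpG within 50 bp -----------------
  tfbs <- data.frame(chrom = "chr2", start = cpg_pos + 10L,
                     end = cpg_pos + 25L, tf_id = unname(tf_of),
                     score = 1, cell_label = "GM12878")
  tfbs_path <- file.path(dir, "tfbs.bed")
  data.table::fwrite(tfbs, tfbs_path, sep = "\t", col.names = FALSE)

  # --- PPI: tf_k - sp_k - cis_k chains plus a random background ----------
  chain <- do.call(rbind, lapply(seq_len(spec$n_tfs), function(k) {
    rbind(c(tfs[k], sp[k]), c(sp[k], cis[min(k, spec$n_cis)]))
  }))
  bg_edges <- cbind(sample(bg, 3 * spec$n_background, replace = TRUE),
                    sample(bg, 3 * spec$n_background, replace = TRUE))
  bg_edges <- bg_edges[bg_edges[, 1] != bg_edges[, 2], , drop = FALSE]
  anchor <- rbind(c(bg[1], sp[1]), c(bg[2], tfs[1]))
  ppi_path <- file.path(dir, "ppi.tsv")
  data.table::fwrite(
    data.frame(gene_a = c(chain[, 1], anchor[, 1], bg_edges[, 1]),
               gene_b = c(chain[, 2], anchor[, 2], bg_edges[, 2])),
    ppi_path, sep = "\t")

  # --- QTL table ----------------------------------------------------------
  qtl <- data.frame(snp_id = snp, snp_chrom = "chr1", snp_pos = snp_pos,
                    maf = spec$maf, target_id = cpgs, target_type = "cpg",
                    target_chrom = "chr2", target_pos = cpg_pos)
  qtl_path <- file.path(dir, "qtl.tsv")
  data.table::fwrite(qtl, qtl_path, sep = "\t")

  # --- read back through the package readers ------------------------------
  annotation <- read_gene_annotation(ann_path)
  tfbs_tab <- filter_tfbs_cells(read_tfbs_bed(tfbs_path))
  ppi <- read_ppi(ppi_path)
  records <- read_qtl_table(qtl_path)
  expressed <- setdiff(annotation$gene_id, "decoy1")

  hotspots <- extract_hotspots(records, min_trans = min(5, spec$n_trans))
  ls <- build_locus_set(hotspots[1, ], annotation, tfbs_tab, ppi,
                        expressed = expressed)

  # --- planted truth over locus nodes -------------------------------------
  edges <- rbind(
    cbind(snp, cis),
    do.call(rbind, lapply(seq_len(spec$n_tfs), function(k) {
      rbind(c(tfs[k], sp[k]), c(sp[k], cis[min(k, spec$n_cis)]))
    })),
    cbind(unname(tf_of), cpgs),
    cbind(cpgs, tgt))
  edges <- edges[edges[, 1] %in% ls$nodes & edges[, 2] %in% ls$nodes, ,
                 drop = FALSE]
  truth <- make_network(ls$nodes, edges)

  list(paths = list(annotation = ann_path, tfbs = tfbs_path,
                    ppi = ppi_path, qtl = qtl_path),
       hotspot = hotspots[1, ], locus_set = ls, truth = truth,
       annotation = annotation, tfbs = tfbs_tab, ppi = ppi,
       expressed = expressed)
}

#' Generate reference data whose assembled priors hit a chosen edge set
#'
#' Builds the prior-construction inputs (reference eQTL p-values, reference
#' expression, chromHMM segmentations, TFBS) such that a configurable
#' fraction of the true edges receives strong prior evidence of its class
#' and everything else stays at (or is floored to) the pseudo-prior. A
#' fraction of 1 makes the prior support a superset of the true edges; a
#' fraction of 0 yields an all-pseudo matrix.
#'
#' @param fixture result of [make_locus_fixture()].
#' @param spec [fixture_spec()]; `spec$prior_fraction` selects the covered
#'   true edges (uniformly, deterministically given `spec$seed`).
#' @return list: `prior` (assembled prior matrix), `maps`, `eqtl`,
#'   `reference_expression`, `chromhmm`, `covered_edges`.
#' @export
make_prior_reference <- function(fixture, spec) {
  set.seed(spec$seed + 1L)
  ls <- fixture$locus_set
  truth <- fixture$truth
  ed <- network_edges(truth)
  n_cover <- round(spec$prior_fraction * nrow(ed))
  covered <- if (n_cover > 0) sort(sample.int(nrow(ed), n_cover)) else
    integer()
  cov_keys <- pair_key(ed$a, ed$b)[covered]
  is_covered <- function(a, b) pair_key(a, b) %in% cov_keys

  snp <- ls$snp
  # --- reference eQTL table: background + covered SNP-cis rows ------------
  n_bg <- 2000
  eqtl <- data.frame(
    snp = sprintf("rsbg%04d", seq_len(n_bg)),
    gene = sprintf("bggene%04d", seq_len(n_bg)),
    p = pmax(runif(n_bg), 1e-12))
  for (g in ls$cis_genes) {
    if (is_covered(snp, g))
      eqtl <- rbind(eqtl, data.frame(snp = snp, gene = g, p = 1e-12))
  }

  # --- reference expression: correlated columns for covered PPI edges -----
  genes <- unique(c(ls$cis_genes, ls$tfs, ls$sp_genes,
                    sprintf("bg%03d", seq_len(spec$n_background))))
  n <- spec$n_reference
  expr <- matrix(rnorm(n * length(genes)), nrow = n, ncol = length(genes),
                 dimnames = list(sprintf("s%03d", seq_len(n)), genes))
  gene_ed <- ed[ed$a %in% genes & ed$b %in% genes, , drop = FALSE]
  for (k in seq_len(nrow(gene_ed))) {
    if (!is_covered(gene_ed$a[k], gene_ed$b[k])) next
    f <- rnorm(n)
    expr[, gene_ed$a[k]] <- sqrt(0.6) * f +
      sqrt(0.4) * expr[, gene_ed$a[k]]
    expr[, gene_ed$b[k]] <- sqrt(0.6) * f +
      sqrt(0.4) * expr[, gene_ed$b[k]]
  }
  expr_raw <- 2^expr # preprocessing will log it back
  # score background pairs plus covered locus pairs only, so uncovered true
  # edges stay at the pseudo-prior
  ppi_pairs <- igraph::as_edgelist(fixture$ppi)
  in_locus <- matrix(ppi_pairs %in% ls$nodes, ncol = 2)
  drop_pair <- in_locus[, 1] & in_locus[, 2] &
    !vapply(seq_len(nrow(ppi_pairs)), function(k)
      is_covered(ppi_pairs[k, 1], ppi_pairs[k, 2]), FALSE)
  ppi_pairs <- ppi_pairs[!drop_pair, , drop = FALSE]

  # --- chromHMM: TssA at covered CpG-gene CpGs, Quies elsewhere -----------
  cells <- sprintf("E%03d", 1:10)
  cpgs <- fixture$hotspot$targets[[1]]
  cpg_state <- function(id) {
    genes_near <- intersect(ls$cpg_genes, ls$nodes)
    hit <- any(vapply(genes_near, function(g)
      is_covered(id, g), FALSE))
    if (hit) "TssA" else "Quies"
  }
  chromhmm <- do.call(rbind, lapply(cells, function(cell)
    data.frame(cell = cell, chrom = "chr2",
               start = ((cpgs$target_pos - 1L) %/% 200L) * 200L,
               end = ((cpgs$target_pos - 1L) %/% 200L) * 200L + 200L,
               state = vapply(cpgs$target_id, cpg_state, ""))))

  # --- TFBS: keep only sites backing covered TF-CpG edges -----------------
  keep <- vapply(seq_len(nrow(fixture$tfbs)), function(k) {
    cpg <- cpgs$target_id[match(fixture$tfbs$start[k] - 10L,
                                cpgs$target_pos)]
    !is.na(cpg) && is_covered(fixture$tfbs$tf_id[k], cpg)
  }, FALSE)
  tfbs_prior <- fixture$tfbs[keep, , drop = FALSE]

  # --- assemble -----------------------------------------------------------
  maps <- list(
    snp_gene = snp_gene_priors(eqtl, snp, ls$cis_genes),
    gene_gene = gene_gene_priors(
      preprocess_reference_expression(expr_raw, n_pcs = 0),
      fixture$ppi, ppi_pairs),
    cpg_gene = cpg_gene_priors(
      cpgs, as.matrix(expand.grid(cpgs$target_id, ls$cpg_genes,
                                  stringsAsFactors = FALSE)),
      fixture$annotation, chromhmm),
    tf_target = tf_target_priors(ls$tfs, cpgs, tfbs_prior,
                                 fixture$annotation))
  prior <- assemble_prior_matrix(ls, maps)
  list(prior = prior, maps = maps, eqtl = eqtl,
       reference_expression = expr_raw, chromhmm = chromhmm,
       covered_edges = ed[covered, , drop = FALSE])
}

#' Simulate a pair of cohorts sharing one ground-truth network
#'
#' Two independent draws from the Gaussian distribution structured by the
#' true network, each with its own SNP dosage discretization at the spec's
#' allele frequency: shared structure, independent noise, emulating
#' replication cohorts.
#'
#' @param ls locus set (its first node is the SNP column).
#' @param truth adjacency over the locus-set nodes.
#' @param spec [fixture_spec()].
#' @return list of two samples x nodes matrices `A` and `B`.
#' @export
make_cohort_pair <- function(ls, truth, spec) {
  freqs <- hwe_dosage_freqs(spec$maf)
  draw <- function() {
    x <- simulate_gaussian(truth, spec$n_samples)$data
    x[, ls$snp] <- discretize_snp(x[, ls$snp], freqs)
    x
  }
  list(A = draw(), B = draw())
}

#' Random prior matrix for benchmark hotspots
#'
#' Places a strong prior (drawn from `prior_range`) on a random fraction of
#' the node pairs and the pseudo-prior elsewhere: the prior universe from
#' which benchmark ground-truth graphs are sampled.
#'
#' @param n_nodes node count; nodes are named `snp`, `v02`, ..., with the
#'   first node acting as the benchmark SNP column.
#' @param prior_fraction fraction of pairs carrying a prior (default 0.1).
#' @param prior_range range of the informative prior values.
#' @export
random_prior_matrix <- function(n_nodes, prior_fraction = 0.1,
                                prior_range = c(0.7, 0.95)) {
  nodes <- c("snp", sprintf("v%02d", seq_len(n_nodes - 1) + 1))
  P <- matrix(pseudo_prior(), n_nodes, n_nodes,
              dimnames = list(nodes, nodes))
  ut <- which(upper.tri(P))
  on <- sample(ut, max(1, round(prior_fraction * length(ut))))
  P[on] <- runif(length(on), prior_range[1], prior_range[2])
  idx <- arrayInd(on, dim(P))
  P[cbind(idx[, 2], idx[, 1])] <- P[on]
  diag(P) <- 0
  P
}
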