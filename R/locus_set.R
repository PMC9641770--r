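#' Blood-related cell-type terms for TFBS filtering
#'
#' Case-insensitive substring terms used to restrict ChIP-seq TFBS
#' collections (ReMap/ENCODE style) to blood-related cell types.
#' @export
blood_cell_terms <- function() {
  c("amlpz12_leukemic", "aplpz74_leukemia", "bcell", "bjab", "bl41",
    "blood", "lcl", "erythroid", "gm", "hbp", "k562", "kasumi",
    "lymphoblastoid", "mm1s", "p493", "plasma", "sem", "thp1", "u937")
}

#' Filter TFBS intervals by cell-type terms
#'
#' Keeps intervals whose `cell_label` contains at least one of the terms as
#' a case-insensitive substring. An empty term list keeps nothing.
#'
#' @param tfbs TFBS table ([read_tfbs_bed()]).
#' @param terms character vector of substrings (default [blood_cell_terms()]).
#' @export
filter_tfbs_cells <- function(tfbs, terms = blood_cell_terms()) {
  if (!length(terms)) return(tfbs[0, ])
  lab <- tolower(tfbs$cell_label)
  keep <- Reduce(`|`, lapply(tolower(terms), function(tm)
    grepl(tm, lab, fixed = TRUE)))
  tfbs[keep, ]
}

# Windows are 1-based closed genomic intervals; a TFBS hits a CpG if its
# interval is within `cpg_window` bp of the CpG position, and a gene if it
# intersects the promoter (promoter_up upstream to promoter_down downstream
# of the TSS, strand-aware).
tfbs_hits <- function(targets, tfbs, annotation, cpg_window = 50,
                      promoter_up = 2000, promoter_down = 1000) {
  hits <- list()
  for (chrom in unique(targets$target_chrom)) {
    tg <- targets[targets$target_chrom == chrom, , drop = FALSE]
    bs <- tfbs[tfbs$chrom == chrom, , drop = FALSE]
    if (!nrow(bs) || !nrow(tg)) next
    bs_ir <- iranges0(bs$start, bs$end)
    for (k in seq_len(nrow(tg))) {
      if (tg$target_type[k] == "cpg") {
        win <- IRanges::IRanges(tg$target_pos[k], tg$target_pos[k])
        d <- IRanges::distance(win, bs_ir)
        sel <- !is.na(d) & d <= cpg_window
      } else {
        ann <- annotation[annotation$gene_id == tg$target_id[k], ]
        if (!nrow(ann)) next
        win <- promoter_window(ann$tss[1], ann$strand[1],
                               promoter_up, promoter_down)
        sel <- IRanges::overlapsAny(bs_ir, win)
      }
      if (any(sel))
        hits[[length(hits) + 1L]] <- data.frame(
          target_id = tg$target_id[k], tf_id = unique(bs$tf_id[sel]),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(target_id = character(), tf_id = character()))
  unique(do.call(rbind, hits))
}

promoter_window <- function(tss, strand, up = 2000, down = 1000) {
  if (identical(strand, "-")) IRanges::IRanges(max(1, tss - down), tss + up)
  else IRanges::IRanges(max(1, tss - up), tss + down)
}

#' Select transcription factors binding near trans entities
#'
#' A TF enters the locus set if one of its binding intervals lies within
#' 50 bp of a trans CpG position or intersects the promoter window (2000 bp
#' upstream to 1000 bp downstream of the TSS, strand-aware) of a trans gene.
#'
#' @param targets data.frame of trans entities (`target_id`, `target_type`,
#'   `target_chrom`, `target_pos`), e.g. a hotspot's `targets` entry.
#' @param tfbs TFBS table, already restricted to relevant cell types
#'   (see [filter_tfbs_cells()]).
#' @param annotation gene annotation ([read_gene_annotation()]), used for
#'   trans-gene promoter windows.
#' @return character vector of TF ids (sorted).
#' @export
select_tfs <- function(targets, tfbs, annotation) {
  sort(unique(tfbs_hits(targets, tfbs, annotation)$tf_id))
}

#' Post-filter predicted TFBS by score and width
#'
#' Keeps predicted binding intervals with score >= 0.999, merges overlapping
#' intervals per TF and chromosome, and drops merged intervals whose width
#' is not strictly below the 95th percentile (type-7 quantile) of all merged
#' widths.
#'
#' @param scored TFBS table with a numeric `score` column in [0, 1].
#' @param score_cutoff minimum prediction score (default 0.999).
#' @param width_quantile width percentile above which merged intervals are
#'   discarded (default 0.95).
#' @return TFBS-format table of merged high-confidence intervals
#'   (score column set to NA after merging).
#' @export
filter_predicted_tfbs <- function(scored, score_cutoff = 0.999,
                                  width_quantile = 0.95) {
  keep <- scored[!is.na(scored$score) & scored$score >= score_cutoff, ,
                 drop = FALSE]
  if (!nrow(keep))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), tf_id = character(),
                      score = numeric(), cell_label = character()))
  parts <- split(keep, paste(keep$tf_id, keep$chrom, sep = "\r"))
  merged <- do.call(rbind, lapply(parts, function(p) {
    red <- IRanges::reduce(iranges0(p$start, p$end))
    data.frame(chrom = p$chrom[1], start = IRanges::start(red) - 1L,
               end = IRanges::end(red), tf_id = p$tf_id[1],
               score = NA_real_, cell_label = "", stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  w <- merged$end - merged$start
  w95 <- stats::quantile(w, width_quantile, type = 7, names = FALSE)
  merged[w < w95, , drop = FALSE]
}

#' Build the role-tagged locus set for one hotspot
#'
#' Assembles the node universe used for network inference at a hotspot:
#' the sentinel SNP, cis genes (intervals intersecting the 1 Mbp window
#' centered on the SNP, restricted to expressed genes), the trans entities,
#' genes neighbouring each trans CpG (previous, next and overlapping gene;
#' meQTL only), TFs binding near the trans entities, and genes on
#' propagation-weighted shortest PPI paths between trans entities and cis
#' genes.
#'
#' @param hotspot single-row hotspot data.frame ([extract_hotspots()]) or an
#'   equivalent list.
#' @param annotation gene annotation table.
#' @param tfbs cell-type-filtered TFBS table.
#' @param ppi undirected igraph of protein-protein interactions (already
#'   restricted to expressed genes, or restricted here via `expressed`).
#' @param expressed optional character vector of genes with expression data;
#'   cis genes and PPI nodes outside it are dropped.
#' @param cis_window half-width in bp of the cis window (default 500000).
#' @param restart restart probability of the propagation random walk.
#' @return object of class `locus_set`: a list with the role sets (`snp`,
#'   `cis_genes`, `trans_entities`, `cpg_genes`, `tfs`, `sp_genes`), the
#'   deterministic `nodes` order (role order, lexicographic within role,
#'   first role wins for shared identifiers), `qtl_type` and a `valid` flag
#'   (FALSE when no expressed cis gene exists; such hotspots are discarded
#'   from downstream analysis).
#' @export
build_locus_set <- function(hotspot, annotation, tfbs, ppi,
                            expressed = NULL, cis_window = 500000,
                            restart = 0.5) {
  if (is.data.frame(hotspot)) {
    stopifnot(nrow(hotspot) == 1)
    hotspot <- c(as.list(hotspot[, setdiff(names(hotspot), "targets")]),
                 list(targets = hotspot$targets[[1]]))
  }
  targets <- as.data.frame(hotspot$targets)

  ann <- annotation[annotation$chrom == hotspot$snp_chrom, ]
  win <- IRanges::IRanges(max(1, hotspot$snp_pos - cis_window),
                          hotspot$snp_pos + cis_window)
  cis <- ann$gene_id[IRanges::overlapsAny(iranges0(ann$start, ann$end), win)]
  if (!is.null(expressed)) cis <- intersect(cis, expressed)
  cis <- sort(unique(setdiff(cis, hotspot$sentinel_snp)))
  valid <- length(cis) > 0

  trans_entities <- sort(unique(targets$target_id))

  cpg_genes <- character()
  if (identical(hotspot$qtl_type, "meqtl")) {
    cpgs <- targets[targets$target_type == "cpg", , drop = FALSE]
    cpg_genes <- sort(unique(unlist(lapply(seq_len(nrow(cpgs)), function(k)
      neighbour_genes(cpgs$target_chrom[k], cpgs$target_pos[k],
                      annotation)))))
  }

  tfs <- select_tfs(targets, tfbs, annotation)

  sp_genes <- character()
  if (valid && length(trans_entities)) {
    if (!is.null(expressed)) {
      drop <- setdiff(igraph::V(ppi)$name, c(expressed, tfs))
      ppi <- igraph::delete_vertices(ppi, intersect(drop,
                                                    igraph::V(ppi)$name))
    }
    aug <- augment_ppi_with_cpgs(ppi, targets, tfbs, annotation)
    nodes <- igraph::V(aug)$name
    seeds <- intersect(c(trans_entities, cis), nodes)
    src <- intersect(trans_entities, nodes)
    dst <- intersect(cis, nodes)
    if (length(seeds) && length(src) && length(dst)) {
      ps <- propagate_node_scores(aug, seeds, restart = restart)
      sp <- shortest_path_genes(aug, ps, src, dst)
      sp_genes <- sort(setdiff(sp, trans_entities))
    }
  }

  roles <- list(snp = hotspot$sentinel_snp, cis_genes = cis,
                trans_entities = trans_entities, cpg_genes = cpg_genes,
                tfs = tfs, sp_genes = sp_genes)
  nodes <- character()
  for (r in roles) nodes <- c(nodes, setdiff(sort(r), nodes))

  structure(c(roles, list(
    qtl_type = hotspot$qtl_type, snp_chrom = hotspot$snp_chrom,
    snp_pos = hotspot$snp_pos, maf = hotspot$maf,
    nodes = nodes, valid = valid)), class = "locus_set")
}

# previous, next and overlapping genes relative to a 1-based point.
neighbour_genes <- function(chrom, pos, annotation) {
  ann <- annotation[annotation$chrom == chrom, ]
  if (!nrow(ann)) return(character())
  overlapping <- ann$gene_id[ann$start < pos & pos <= ann$end]
  prev <- ann[ann$end < pos, ]
  prv <- if (nrow(prev)) prev$gene_id[which.max(prev$end)] else character()
  nxt_c <- ann[ann$start + 1L > pos, ]
  nxt <- if (nrow(nxt_c)) nxt_c$gene_id[which.min(nxt_c$start)] else character()
  unique(c(prv, nxt, overlapping))
}

# Attach CpG nodes to the PPI graph, linked to the TFs binding within the
# CpG window, so that propagation and shortest paths can traverse them.
augment_ppi_with_cpgs <- function(ppi, targets, tfbs, annotation) {
  cpgs <- targets[targets$target_type == "cpg", , drop = FALSE]
  g <- ppi
  if (nrow(cpgs)) {
    hits <- tfbs_hits(cpgs, tfbs, annotation)
    hits <- hits[hits$tf_id %in% igraph::V(g)$name, , drop = FALSE]
    newv <- setdiff(cpgs$target_id, igraph::V(g)$name)
    g <- igraph::add_vertices(g, length(newv), name = newv)
    if (nrow(hits))
      g <- igraph::add_edges(g, rbind(hits$target_id, hits$tf_id))
  }
  # gene-type trans entities are regular PPI nodes already (if expressed)
  igraph::simplify(g)
}

#' @export
print.locus_set <- function(x, ...) {
  cat("Locus set for", x$snp, sprintf("(%s)", x$qtl_type),
      if (!x$valid) "[invalid: no expressed cis gene]" else "", "\n")
  cat("  cis genes:     ", length(x$cis_genes), "\n")
  cat("  trans entities:", length(x$trans_entities), "\n")
  cat("  CpG genes:     ", length(x$cpg_genes), "\n")
  cat("  TFs:           ", length(x$tfs), "\n")
  cat("  SP genes:      ", length(x$sp_genes), "\n")
  cat("  nodes total:   ", length(x$nodes), "\n")
  invisible(x)
}

#' Serialize a locus set as a node/role TSV
#'
#' @param ls locus set.
#' @param path file path.
#' @export
write_locus_set <- function(ls, path) {
  role_of <- function(n) {
    for (r in c("snp", "cis_genes", "trans_entities", "cpg_genes", "tfs",
                "sp_genes"))
      if (n %in% ls[[r]]) return(r)
    NA_character_
  }
  data.table::fwrite(data.frame(
    node = ls$nodes, role = vapply(ls$nodes, role_of, ""),
    stringsAsFactors = FALSE), path, sep = "\t")
  invisible(path)
}
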