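#' Extract trans-QTL hotspots from an association table
#'
#' Groups trans associations by SNP and keeps loci with at least `min_trans`
#' distinct trans targets. When an LD clustering of the SNPs is supplied,
#' redundant loci are collapsed: with `mode = "prune"` one representative SNP
#' is kept per cluster, chosen by highest minor allele frequency, then
#' largest trans-target count, then SNP id; with `mode = "merge"` the trans
#' targets of all clustered SNPs are pooled and the SNP with the highest MAF
#' becomes the sentinel.
#'
#' @param records QTL table as returned by [read_qtl_table()] (one row per
#'   SNP-target association).
#' @param min_trans minimum number of distinct trans targets (default 5).
#' @param ld_clusters optional named vector mapping SNP ids to cluster
#'   labels; SNPs missing from it form singleton clusters. LD computation is
#'   upstream of this package.
#' @param mode `"prune"` or `"merge"` (see above).
#' @return data.frame with one row per hotspot: `sentinel_snp`, `qtl_type`
#'   (`"meqtl"` if any target is a CpG, else `"eqtl"`), `snp_chrom`,
#'   `snp_pos`, `maf`, `n_trans`, and a list column `targets` holding each
#'   hotspot's trans targets (id, type, chromosome, position).
#' @export
extract_hotspots <- function(records, min_trans = 5, ld_clusters = NULL,
                             mode = c("prune", "merge")) {
  mode <- match.arg(mode)
  empty <- data.frame(sentinel_snp = character(), qtl_type = character(),
                      snp_chrom = character(), snp_pos = integer(),
                      maf = numeric(), n_trans = integer())
  empty$targets <- list()
  if (NROW(records) == 0) return(empty)
  validate_qtl_records(records)

  records <- data.table::as.data.table(records)
  per_snp <- lapply(split(records, by = "snp_id"), function(r) {
    tg <- unique(r[, c("target_id", "target_type", "target_chrom",
                       "target_pos")])
    list(snp_id = r$snp_id[1], snp_chrom = as.character(r$snp_chrom[1]),
         snp_pos = r$snp_pos[1], maf = r$maf[1], targets = tg)
  })

  cluster_of <- function(snp) {
    if (!is.null(ld_clusters) && snp %in% names(ld_clusters))
      as.character(ld_clusters[[snp]])
    else paste0(".singleton.", snp)
  }
  clusters <- split(per_snp, vapply(names(per_snp), cluster_of, ""))

  rows <- lapply(clusters, function(cl) {
    maf <- vapply(cl, `[[`, 0, "maf")
    ntr <- vapply(cl, function(x) nrow(x$targets), 0L)
    ids <- vapply(cl, `[[`, "", "snp_id")
    best <- order(-maf, -ntr, ids)[1]
    rep <- cl[[best]]
    targets <- if (mode == "merge") {
      unique(data.table::rbindlist(lapply(cl, `[[`, "targets")))
    } else rep$targets
    data.table::setorderv(targets, "target_id")
    list(sentinel_snp = rep$snp_id,
         qtl_type = if (any(targets$target_type == "cpg")) "meqtl" else "eqtl",
         snp_chrom = rep$snp_chrom, snp_pos = rep$snp_pos, maf = rep$maf,
         n_trans = nrow(targets), targets = targets)
  })

  rows <- rows[vapply(rows, `[[`, 0L, "n_trans") >= min_trans]
  if (!length(rows)) return(empty)
  out <- data.frame(
    sentinel_snp = vapply(rows, `[[`, "", "sentinel_snp"),
    qtl_type = vapply(rows, `[[`, "", "qtl_type"),
    snp_chrom = vapply(rows, `[[`, "", "snp_chrom"),
    snp_pos = vapply(rows, function(x) as.integer(x$snp_pos), 0L),
    maf = vapply(rows, `[[`, 0, "maf"),
    n_trans = vapply(rows, `[[`, 0L, "n_trans"),
    stringsAsFactors = FALSE)
  out$targets <- lapply(rows, `[[`, "targets")
  out <- out[order(out$sentinel_snp), ]
  rownames(out) <- NULL
  out
}
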