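#' Readers for the tabular input formats
#'
#' All genomic intervals are held internally in the 0-based half-open
#' convention (BED native). 1-based inclusive coordinates in TSV inputs
#' (QTL tables, gene annotation) are converted on read, so a TSV interval
#' `[start, end]` becomes `[start-1, end)` internally; point coordinates
#' (SNP and CpG positions) stay 1-based and are treated as points.
#'
#' @param path file path.
#' @return a `data.table` with the documented columns.
#' @name readers
NULL

#' @describeIn readers Trans-QTL association table. Expected header:
#'   `snp_id`, `snp_chrom`, `snp_pos`, `maf`, `target_id`, `target_type`
#'   (`gene` or `cpg`), `target_chrom`, `target_pos`.
#' @export
read_qtl_table <- function(path) {
  qtl <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("snp_id", "snp_chrom", "snp_pos", "maf", "target_id",
            "target_type", "target_chrom", "target_pos")
  miss <- setdiff(need, names(qtl))
  if (length(miss)) stop("QTL table lacks columns: ",
                         paste(miss, collapse = ", "))
  validate_qtl_records(qtl)
  qtl
}

validate_qtl_records <- function(qtl) {
  bad <- which(!is.finite(qtl$maf) | qtl$maf < 0 | qtl$maf > 0.5)
  if (length(bad))
    stop("malformed MAF (outside [0, 0.5]) at record(s): ",
         paste(head(bad, 10), collapse = ", "))
  bad_t <- which(!qtl$target_type %in% c("gene", "cpg"))
  if (length(bad_t))
    stop("unknown target_type at record(s): ",
         paste(head(bad_t, 10), collapse = ", "))
  invisible(qtl)
}

#' @describeIn readers Gene annotation, either a 5+-column TSV with header
#'   (`gene_id`, `chrom`, `start`, `end`, `strand`; 1-based inclusive) or a
#'   GTF file (gene features are used). Adds the strand-aware `tss`
#'   (1-based position: interval start on `+`, interval end on `-`).
#' @export
read_gene_annotation <- function(path) {
  first <- readLines(path, n = 20L)
  first <- first[!startsWith(first, "#")]
  is_gtf <- length(first) && grepl("gene_id", first[1], fixed = TRUE) &&
    length(strsplit(first[1], "\t", fixed = TRUE)[[1]]) == 9
  if (is_gtf) {
    gtf <- data.table::fread(path, sep = "\t", header = FALSE, skip = "#",
      col.names = c("chrom", "source", "feature", "start", "end", "score",
                    "strand", "frame", "attributes"))
    gtf <- gtf[gtf$feature == "gene", ]
    gene_id <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", gtf$attributes)
    ann <- data.table::data.table(
      gene_id = gene_id, chrom = gtf$chrom,
      start = gtf$start - 1L, end = gtf$end, strand = gtf$strand)
  } else {
    ann <- data.table::fread(path, sep = "\t", header = TRUE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    miss <- setdiff(need, names(ann))
    if (length(miss)) stop("annotation lacks columns: ",
                           paste(miss, collapse = ", "))
    ann <- ann[, need, with = FALSE]
    ann$start <- ann$start - 1L # to 0-based half-open
  }
  if (any(ann$start >= ann$end)) stop("annotation contains empty intervals")
  # tss as 1-based position
  ann$tss <- ifelse(ann$strand == "-", ann$end, ann$start + 1L)
  ann
}

#' @describeIn readers TFBS intervals in BED format (0-based half-open):
#'   columns chrom, start, end, tf_id, and optionally score (real) and
#'   cell_label.
#' @export
read_tfbs_bed <- function(path) {
  bed <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(bed) < 4) stop("TFBS BED needs at least 4 columns")
  names(bed)[1:4] <- c("chrom", "start", "end", "tf_id")
  bed$score <- if (ncol(bed) >= 5) as.numeric(bed[[5]]) else NA_real_
  bed$cell_label <- if (ncol(bed) >= 6) as.character(bed[[6]]) else ""
  bed[, c("chrom", "start", "end", "tf_id", "score", "cell_label")]
}

#' @describeIn readers One chromHMM segmentation per cell line: BED4 with
#'   the 15-state mnemonic in column 4. `paths` is a named vector
#'   (cell line -> file); returns rows stacked with a `cell` column.
#' @param paths named character vector of file paths.
#' @export
read_chromhmm <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    stop("chromHMM paths must be named by cell line")
  segs <- lapply(names(paths), function(cell) {
    bed <- data.table::fread(paths[[cell]], sep = "\t", header = FALSE)
    if (ncol(bed) < 4) stop("chromHMM BED needs 4 columns: ", paths[[cell]])
    names(bed)[1:4] <- c("chrom", "start", "end", "state")
    bed$cell <- cell
    bed[, c("cell", "chrom", "start", "end", "state")]
  })
  out <- data.table::rbindlist(segs)
  bad <- setdiff(unique(out$state), chromhmm_states())
  if (length(bad)) stop("unknown chromHMM state mnemonic(s): ",
                        paste(bad, collapse = ", "))
  out
}

#' @describeIn readers Protein-protein interactions as a 2-column TSV
#'   (header `gene_a`, `gene_b` or none). Self loops are dropped; edges are
#'   returned as an undirected igraph object.
#' @export
read_ppi <- function(path) {
  ed <- data.table::fread(path, sep = "\t", header = "auto",
                          colClasses = "character")
  if (ncol(ed) < 2) stop("PPI table needs 2 columns")
  ed <- ed[, 1:2]
  names(ed) <- c("gene_a", "gene_b")
  ed <- ed[ed$gene_a != ed$gene_b, ]
  g <- igraph::graph_from_edgelist(as.matrix(ed), directed = FALSE)
  igraph::simplify(g)
}

#' @describeIn readers Numeric matrix with row names in the first column
#'   (e.g. samples x genes reference expression, cohort omics matrices).
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1])
  rownames(m) <- as.character(dt[[1]])
  storage.mode(m) <- "double"
  m
}

#' @describeIn readers Write a numeric matrix with row names (inverse of
#'   `read_matrix_tsv`).
#' @param m numeric matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  dt <- data.table::data.table(id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

# 15-state chromHMM mnemonics.
chromhmm_states <- function() {
  c("TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG", "Enh", "ZNF/Rpts",
    "Het", "TssBiv", "BivFlnk", "EnhBiv", "ReprPC", "ReprPCWk", "Quies")
}

#' TSS-related chromHMM states used for CpG-gene priors
#'
#' The four 15-state-model mnemonics marking active or bivalent promoter
#' chromatin; the CpG-gene prior is the (weighted) proportion of reference
#' cell lines whose state at the CpG falls in this set.
#' @export
tss_states <- function() {
  c("TssA", "TssAFlnk", "TssBiv", "BivFlnk")
}

# Convert internal 0-based half-open intervals to IRanges (1-based closed).
iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}
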