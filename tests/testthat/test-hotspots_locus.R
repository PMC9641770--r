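test_that("hotspot extraction applies the trans-target threshold", {
  qtl <- data.frame(
    snp_id = rep(c("rsA", "rsB"), c(5, 4)),
    snp_chrom = "chr1", snp_pos = c(rep(1e6, 5), rep(2e6, 4)),
    maf = c(rep(0.2, 5), rep(0.4, 4)),
    target_id = sprintf("cg%02d", 1:9), target_type = "cpg",
    target_chrom = "chr2", target_pos = 1000 * (1:9))
  hs <- extract_hotspots(qtl, min_trans = 5)
  expect_equal(hs$sentinel_snp, "rsA")
  expect_equal(hs$n_trans, 5L)
  expect_equal(hs$qtl_type, "meqtl")

  # below threshold: no hotspot
  expect_equal(nrow(extract_hotspots(qtl[6:9, ], min_trans = 5)), 0L)
  # empty input: empty result
  expect_equal(nrow(extract_hotspots(qtl[0, ], min_trans = 5)), 0L)
})

test_that("malformed MAF is rejected with the record index", {
  qtl <- data.frame(snp_id = "rsA", snp_chrom = "chr1", snp_pos = 1e6,
                    maf = 0.7, target_id = "cg01", target_type = "cpg",
                    target_chrom = "chr2", target_pos = 1000)
  expect_error(extract_hotspots(qtl), "MAF.*1")
})

test_that("LD-cluster pruning keeps the (maf, trans count) lexicographic best", {
  mk <- function(snp, maf, n) data.frame(
    snp_id = snp, snp_chrom = "chr1", snp_pos = 1e6, maf = maf,
    target_id = sprintf("%s_t%02d", snp, seq_len(n)), target_type = "gene",
    target_chrom = "chr2", target_pos = 1000 * seq_len(n))
  qtl <- rbind(mk("rs1", 0.1, 9), mk("rs2", 0.3, 6), mk("rs3", 0.3, 8))
  cl <- c(rs1 = "c1", rs2 = "c1", rs3 = "c1")

  pruned <- extract_hotspots(qtl, min_trans = 5, ld_clusters = cl,
                             mode = "prune")
  expect_equal(pruned$sentinel_snp, "rs3") # maf first, then trans count
  expect_equal(pruned$n_trans, 8L)

  merged <- extract_hotspots(qtl, min_trans = 5, ld_clusters = cl,
                             mode = "merge")
  expect_equal(merged$sentinel_snp, "rs3")
  expect_equal(merged$n_trans, 23L) # union of all targets

  # prune returns exactly one hotspot per LD cluster
  qtl2 <- rbind(qtl, mk("rs4", 0.2, 7))
  cl2 <- c(cl, rs4 = "c2")
  pruned2 <- extract_hotspots(qtl2, min_trans = 5, ld_clusters = cl2,
                              mode = "prune")
  expect_equal(sort(pruned2$sentinel_snp), c("rs3", "rs4"))
})

test_that("locus-set construction recovers the planted roles", {
  d <- default_fixture()
  ls <- d$fx$locus_set
  expect_true(ls$valid)
  expect_equal(ls$cis_genes, sprintf("cis%02d", 1:3))
  expect_equal(ls$trans_entities, sprintf("cg%02d", 1:5))
  expect_equal(ls$cpg_genes, sprintf("tgt%02d", 1:5))
  expect_equal(ls$tfs, c("tf1", "tf2"))
  expect_true(all(c("sp1", "sp2") %in% ls$sp_genes))
  # decoy outside the 1 Mbp window is excluded
  expect_false("decoy1" %in% ls$nodes)
  # node order: deterministic, no duplicates
  expect_equal(anyDuplicated(ls$nodes), 0L)
  expect_equal(ls$nodes[1], ls$snp)
})

test_that("cis window membership is decided by interval intersection", {
  ann <- data.frame(
    gene_id = c("in1", "in2", "out1"), chrom = "chr1",
    start = c(9600000L, 10499000L, 10600001L),
    end = c(9700000L, 10510000L, 10620000L),
    strand = "+", tss = c(9600001L, 10499001L, 10600002L))
  hot <- list(sentinel_snp = "rs1", qtl_type = "eqtl", snp_chrom = "chr1",
              snp_pos = 10000000L, maf = 0.3,
              targets = data.frame(target_id = "g1", target_type = "gene",
                                   target_chrom = "chr9",
                                   target_pos = 1000L))
  ppi <- igraph::make_empty_graph(directed = FALSE)
  ls <- build_locus_set(hot, ann, data.frame(chrom = character(),
                                             start = integer(),
                                             end = integer(),
                                             tf_id = character(),
                                             score = numeric(),
                                             cell_label = character()),
                        ppi)
  expect_equal(ls$cis_genes, c("in1", "in2")) # out1 starts 1 bp too far
  expect_equal(ls$cpg_genes, character()) # eQTL: no CpG genes
})

test_that("hotspots whose cis genes lack expression are flagged invalid", {
  d <- default_fixture()
  ls_bad <- build_locus_set(d$fx$hotspot, d$fx$annotation, d$fx$tfbs,
                            d$fx$ppi,
                            expressed = setdiff(d$fx$expressed,
                                                sprintf("cis%02d", 1:3)))
  expect_false(ls_bad$valid)
})

test_that("TF selection windows: 50 bp CpG window and strand-aware promoter", {
  cpg <- data.frame(target_id = "cg1", target_type = "cpg",
                    target_chrom = "chr1", target_pos = 1000L)
  ann <- data.frame(gene_id = c("gplus", "gminus"), chrom = "chr1",
                    start = c(5000L, 8000L), end = c(6000L, 9000L),
                    strand = c("+", "-"), tss = c(5001L, 9000L))
  mk_tfbs <- function(start, end, tf = "tfX") data.frame(
    chrom = "chr1", start = start, end = end, tf_id = tf, score = 1,
    cell_label = "gm")

  # CpG at 1000; TFBS [1040,1060) in 0-based = positions 1041..1060 -> gap 40
  expect_equal(select_tfs(cpg, mk_tfbs(1040L, 1060L), ann), "tfX")
  # gap 51 -> excluded
  expect_equal(select_tfs(cpg, mk_tfbs(1051L, 1060L), ann), character())
  expect_equal(select_tfs(cpg, mk_tfbs(900L, 948L), ann), character())
  expect_equal(select_tfs(cpg, mk_tfbs(900L, 949L), ann), "tfX")

  gene_plus <- data.frame(target_id = "gplus", target_type = "gene",
                          target_chrom = "chr1", target_pos = 5001L)
  # promoter of + gene: [tss-2000, tss+1000] = [3001, 6001]
  expect_equal(select_tfs(gene_plus, mk_tfbs(3000L, 3001L), ann), "tfX")
  expect_equal(select_tfs(gene_plus, mk_tfbs(2990L, 3000L), ann),
               character())
  gene_minus <- data.frame(target_id = "gminus", target_type = "gene",
                           target_chrom = "chr1", target_pos = 9000L)
  # promoter of - gene: [tss-1000, tss+2000] = [8000, 11000]
  expect_equal(select_tfs(gene_minus, mk_tfbs(10995L, 11000L), ann), "tfX")
  expect_equal(select_tfs(gene_minus, mk_tfbs(11000L, 11010L), ann),
               character())
})

test_that("cell-type filtering is case-insensitive substring matching", {
  tfbs <- data.frame(chrom = "chr1", start = 1:3, end = 2:4,
                     tf_id = "tfX", score = 1,
                     cell_label = c("GM12878", "HeLa-S3", "whole_blood"))
  kept <- filter_tfbs_cells(tfbs)
  expect_equal(kept$cell_label, c("GM12878", "whole_blood"))
  expect_equal(nrow(filter_tfbs_cells(tfbs, character())), 0L)
  expect_equal(filter_tfbs_cells(tfbs, "hela")$cell_label, "HeLa-S3")
})

test_that("predicted TFBS are score-filtered, merged, and width-capped", {
  sc <- rbind(
    data.frame(chrom = "chr1", start = c(0L, 5L, 100L),
               end = c(10L, 15L, 120L), tf_id = "tfX",
               score = c(0.9995, 0.9995, 0.99), cell_label = ""),
    # wide sites of another TF push the width percentile above 15
    data.frame(chrom = "chr1", start = 1000L * (1:5),
               end = 1000L * (1:5) + 30L, tf_id = "tfY", score = 1,
               cell_label = ""))
  out <- filter_predicted_tfbs(sc)
  # 0.99 dropped, [0,10) and [5,15) merged; the width-30 sites sit at the
  # 95th percentile and are cut by the strict inequality
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end), c(0L, 15L))

  # widths 1..20: the type-7 95th percentile is 19.05, so only 20 is dropped
  sc2 <- data.frame(chrom = "chr1", start = 100L * (1:20),
                    end = 100L * (1:20) + (1:20),
                    tf_id = sprintf("tf%02d", 1:20), score = 1,
                    cell_label = "")
  out2 <- filter_predicted_tfbs(sc2)
  expect_equal(sort(out2$end - out2$start), 1:19)
})

test_that("readers round-trip coordinates losslessly", {
  dir <- withr::local_tempdir()
  ann <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                    start = c(101L, 501L), end = c(200L, 600L),
                    strand = c("+", "-"))
  fa <- file.path(dir, "ann.tsv")
  data.table::fwrite(ann, fa, sep = "\t")
  rd <- read_gene_annotation(fa)
  expect_equal(rd$start, ann$start - 1L) # 0-based half-open internally
  expect_equal(rd$end, ann$end)
  expect_equal(rd$tss, c(101L, 600L)) # strand-aware

  gtf <- file.path(dir, "ann.gtf")
  writeLines(c("#comment",
               paste("chr1", "src", "gene", "101", "200", ".", "+", ".",
                     'gene_id "g1";', sep = "\t"),
               paste("chr1", "src", "gene", "501", "600", ".", "-", ".",
                     'gene_id "g2";', sep = "\t")), gtf)
  rd2 <- read_gene_annotation(gtf)
  expect_equal(rd2$start, rd$start)
  expect_equal(rd2$tss, rd$tss)

  net <- make_network(c("a", "b", "c"), rbind(c("a", "b")))
  fe <- file.path(dir, "edges.tsv")
  write_edge_list(net, fe)
  expect_equal(read_edge_list(fe, nodes = c("a", "b", "c")), net)
})
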