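test_that("lfdr estimator is calibrated on known mixtures", {
  set.seed(101)
  # pure null: lfdr near 1 everywhere
  f0 <- estimate_lfdr(runif(5000))
  expect_gte(f0$eta0, 0.9)
  expect_gte(mean(f0$lfdr), 0.95)

  # 30% Beta(0.1, 1) alternative: tiny p-values get tiny lfdr
  p <- pmin(pmax(c(rbeta(1500, 0.1, 1), runif(3500), 1e-6), 1e-15), 1)
  f1 <- estimate_lfdr(p)
  expect_lt(f1$lfdr[length(p)], 0.05)
  # monotone nondecreasing in p
  ord <- order(f1$pvalues)
  expect_true(all(diff(f1$lfdr[ord]) >= -1e-12))

  # eta0 recovery within +/- 0.1
  for (eta in c(0.5, 0.8, 1.0)) {
    pp <- c(rbeta(round(5000 * (1 - eta)), 0.1, 1),
            runif(round(5000 * eta)))
    pp <- pmin(pmax(pp, 1e-15), 1)
    expect_lt(abs(estimate_lfdr(pp)$eta0 - eta), 0.1)
  }

  # all p = 1: no signal anywhere
  expect_true(all(estimate_lfdr(rep(1, 300))$lfdr == 1))

  expect_error(estimate_lfdr(c(runif(300), 0)), "outside")
  expect_error(estimate_lfdr(c(runif(300), 1.5)), "outside")
  expect_error(estimate_lfdr(runif(50)), "too few")
})

test_that("snp-gene priors are the lfdr complement with pseudo fallback", {
  set.seed(7)
  eqtl <- data.frame(snp = sprintf("rs%04d", 1:1000),
                     gene = sprintf("g%04d", 1:1000),
                     p = pmax(runif(1000), 1e-12))
  eqtl$snp[1] <- "rsX"; eqtl$gene[1] <- "cis1"; eqtl$p[1] <- 1e-12
  m <- snp_gene_priors(eqtl, "rsX", c("cis1", "cis2"))
  expect_equal(nrow(m), 1L) # cis2 missing -> pseudo on assembly
  expect_gt(m$prior, 0.9)
  expect_equal(m$class, "snp_gene")

  # antitone: larger p never yields a larger prior
  f <- estimate_lfdr(eqtl$p)
  ord <- order(eqtl$p)
  expect_true(all(diff((1 - f$lfdr)[ord]) <= 1e-12))
})

test_that("reference expression preprocessing centers and removes factors", {
  set.seed(13)
  raw <- matrix(2^rnorm(100 * 30), 100, 30,
                dimnames = list(sprintf("s%02d", 1:100),
                                sprintf("g%02d", 1:30)))
  # n_pcs = 0: only log/quantile/INT, still per-gene standard normal scores
  x0 <- preprocess_reference_expression(raw, n_pcs = 0)
  expect_equal(dim(x0), dim(raw))
  x <- preprocess_reference_expression(raw, n_pcs = 5)
  expect_lt(max(abs(colMeans(x))), 1e-8)
  expect_error(preprocess_reference_expression(raw, n_pcs = 30), "n_pcs")

  # a strong common factor is removed by one PC
  f <- rnorm(100)
  raw2 <- 2^(outer(f, rep(1, 30)) + matrix(rnorm(3000, sd = 0.3), 100, 30))
  dimnames(raw2) <- dimnames(raw)
  x2 <- preprocess_reference_expression(raw2, n_pcs = 1)
  cm <- cor(x2)
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.1)
})

test_that("gene-gene priors score only PPI-connected expressed pairs", {
  set.seed(19)
  n <- 300
  genes <- sprintf("g%03d", 1:220)
  expr <- matrix(rnorm(n * 220), n, 220,
                 dimnames = list(NULL, genes))
  # plant one strongly correlated PPI pair among null PPI pairs
  f <- rnorm(n)
  expr[, "g001"] <- sqrt(0.8) * f + sqrt(0.2) * expr[, "g001"]
  expr[, "g002"] <- sqrt(0.8) * f + sqrt(0.2) * expr[, "g002"]
  ppi_edges <- cbind(genes[seq(1, 219, 2)], genes[seq(2, 220, 2)])
  extra <- cbind(genes[seq(1, 199, 2)], genes[seq(5, 203, 2)])
  ppi <- igraph::graph_from_edgelist(rbind(ppi_edges, extra),
                                     directed = FALSE)
  pairs <- rbind(ppi_edges, extra,
                 c("g001", "g004"),  # no PPI edge
                 c("g001", "g001")) # self
  m <- gene_gene_priors(expr, ppi, pairs)
  expect_false(any(m$node_a == m$node_b))
  expect_false("g001\rg004" %in% pair_key_test(m$node_a, m$node_b))
  planted <- m$prior[(m$node_a == "g001" & m$node_b == "g002") |
                       (m$node_a == "g002" & m$node_b == "g001")]
  expect_gt(planted, 0.9)
})

test_that("cpg-gene priors count TSS states within the distance rule", {
  cpgs <- data.frame(target_id = c("cg1", "cg2"), target_chrom = "chr2",
                     target_pos = c(1000L, 5000L))
  ann <- data.frame(gene_id = c("gA", "gB"), chrom = "chr2",
                    start = c(1100L, 5300L), end = c(2000L, 6000L),
                    strand = "+", tss = c(1101L, 5301L))
  seg <- do.call(rbind, lapply(1:10, function(k)
    data.frame(cell = sprintf("E%03d", k), chrom = "chr2",
               start = c(800L, 4800L), end = c(1000L, 5000L),
               state = if (k <= 3) "TssA" else "Quies")))
  # cg1 is 100 bp from gA: prior = 3/10 unweighted
  m <- cpg_gene_priors(cpgs, rbind(c("cg1", "gA"), c("cg2", "gB")),
                       ann, seg)
  expect_equal(m$prior[m$node_a == "cg1" | m$node_b == "cg1"], 0.3)
  # cg2 is 300 bp from gB: no prior row
  expect_false(any(m$node_a == "cg2" | m$node_b == "cg2"))

  # weighting: cells 1-3 at weight 0.2, rest at 0.05
  w <- setNames(c(rep(0.2, 3), rep(0.05, 7)), sprintf("E%03d", 1:10))
  mw <- cpg_gene_priors(cpgs, rbind(c("cg1", "gA")), ann, seg, weights = w)
  expect_equal(mw$prior, 0.6 / 0.95)

  seg_bad <- seg; seg_bad$state[1] <- "NotAState"
  expect_error(cpg_gene_priors(cpgs, rbind(c("cg1", "gA")), ann, seg_bad),
               "NotAState")
})

test_that("tf-target priors are fixed at 0.99 for qualifying windows", {
  targets <- data.frame(target_id = c("cg1", "cg2", "tfX"),
                        target_type = c("cpg", "cpg", "gene"),
                        target_chrom = "chr1",
                        target_pos = c(1000L, 9000L, 50L))
  tfbs <- data.frame(chrom = "chr1", start = c(1010L, 20000L),
                     end = c(1030L, 20100L), tf_id = c("tfX", "tfX"),
                     score = 1, cell_label = "gm")
  ann <- data.frame(gene_id = "tfX", chrom = "chr1", start = 40L,
                    end = 500L, strand = "+", tss = 41L)
  m <- tf_target_priors("tfX", targets, tfbs, ann)
  # only cg1 qualifies; the TF-self pair is excluded
  expect_equal(nrow(m), 1L)
  expect_setequal(c(m$node_a, m$node_b), c("cg1", "tfX"))
  expect_equal(m$prior, 0.99)
})

test_that("prior matrix assembly floors, clips, symmetrizes, and rejects conflicts", {
  ls <- list(nodes = c("a", "b", "c", "d"))
  P0 <- assemble_prior_matrix(ls, list())
  expect_true(all(P0[upper.tri(P0)] == 1e-7))

  m1 <- data.frame(node_a = "a", node_b = "b", prior = 0.98,
                   class = "snp_gene")
  P1 <- assemble_prior_matrix(ls, list(m1))
  expect_equal(sum(P1[upper.tri(P1)] != 1e-7), 1L)
  expect_equal(P1["a", "b"], 0.98)
  expect_equal(P1["b", "a"], 0.98)
  expect_equal(attr(P1, "prior_class")["a", "b"], "snp_gene")

  # zero and one are clipped into [1e-7, 0.999999]
  m2 <- data.frame(node_a = c("a", "c"), node_b = c("b", "d"),
                   prior = c(0, 1), class = "cpg_gene")
  P2 <- assemble_prior_matrix(ls, list(m2))
  expect_equal(P2["a", "b"], 1e-7)
  expect_equal(P2["c", "d"], 0.999999)

  clash <- data.frame(node_a = "b", node_b = "a", prior = 0.5,
                      class = "gene_gene")
  expect_error(assemble_prior_matrix(ls, list(m1, clash)),
               "more than one prior class")

  # property: symmetry and floor hold over random constructions
  set.seed(23)
  for (rep in 1:10) {
    nodes <- sprintf("n%02d", 1:8)
    k <- sample(1:10, 1)
    pr <- data.frame(node_a = sample(nodes, k, TRUE),
                     node_b = sample(nodes, k, TRUE),
                     prior = runif(k, -0.1, 1.1), class = "gene_gene")
    pr <- pr[pr$node_a != pr$node_b, , drop = FALSE]
    pr <- pr[!duplicated(pair_key_test(pr$node_a, pr$node_b)), ,
             drop = FALSE]
    P <- assemble_prior_matrix(list(nodes = nodes), list(pr))
    expect_true(all(P == t(P)))
    ut <- P[upper.tri(P)]
    expect_true(all(ut >= 1e-7 & ut <= 0.999999))
  }
})

test_that("density prior follows the binomial edge-count formula", {
  g1 <- random_network(6, 0)
  g1[1, 2] <- g1[2, 1] <- 1
  g1[1, 3] <- g1[3, 1] <- 1
  g1[4, 5] <- g1[5, 4] <- 1
  expect_equal(density_prior(list(g1), 6), 3 / 15)

  empty <- random_network(6, 0)
  expect_equal(density_prior(list(empty, empty), 6), 1e-7)

  set.seed(31)
  g2 <- random_network(5, 0.4)
  g3 <- random_network(5, 0.4)
  expect_equal(density_prior(list(g2, g3), 5),
               max((n_edges(g2) + n_edges(g3)) / 2 / 10, 1e-7))
  expect_error(density_prior(list(), 5), "at least one")
})

test_that("prior matrices round-trip through the long-format TSV", {
  d <- default_prior()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_prior_matrix(d$prior, path)
  back <- read_prior_matrix(path)
  expect_equal(rownames(back), rownames(d$prior))
  expect_equal(unclass(back), unclass(d$prior), ignore_attr = TRUE,
               tolerance = 1e-12)
})
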