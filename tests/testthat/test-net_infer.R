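test_that("gaussianization maps any monotone distortion to normal scores", {
  set.seed(51)
  x <- matrix(rnorm(600 * 3), 600, 3, dimnames = list(NULL, c("a", "b", "c")))
  g <- gaussianize(x)
  ks <- suppressWarnings(ks.test(g[, 1], "pnorm"))
  expect_lt(unname(ks$statistic), 0.05)

  # invariant to monotone pre-distortion
  x2 <- x; x2[, 2] <- exp(3 * x2[, 2])
  expect_equal(gaussianize(x2)[, 2], g[, 2])

  # dosage column: 3 distinct values, order preserved
  d <- sample(0:2, 600, replace = TRUE)
  gd <- gaussianize(cbind(snp = d, x))[, "snp"]
  expect_equal(length(unique(gd)), 3L)
  expect_true(all(diff(gd[order(d)]) >= 0))

  expect_error(gaussianize(cbind(const = rep(1, 600), x)), "const")
})

test_that("penalized MLE matches the 2-variable soft-threshold solution", {
  nodes <- c("a", "b")
  for (s12 in c(-0.7, -0.3, 0, 0.25, 0.6, 0.9)) {
    for (lam in c(0.05, 0.24, 0.26, 0.5, 0.95)) {
      S <- matrix(c(1, s12, s12, 1), 2, dimnames = list(nodes, nodes))
      fit <- penalized_mle(S, penalty_matrix(nodes, lam))
      expect_lt(fit$kkt_residual, 1e-6)
      expect_equal(unname(fit$adjacency[1, 2]),
                   as.numeric(abs(s12) > lam))
      # W12 is the soft-thresholded covariance
      expect_equal(unname(fit$Sigma[1, 2]),
                   sign(s12) * max(abs(s12) - lam, 0), tolerance = 1e-7)
    }
  }
})

test_that("penalized MLE reduces to the inverse covariance at zero penalty", {
  set.seed(53)
  x <- matrix(rnorm(500 * 5), 500, 5,
              dimnames = list(NULL, letters[1:5]))
  S <- cov(x)
  fit <- penalized_mle(S, penalty_matrix(letters[1:5], 0))
  expect_lt(max(abs(fit$Theta - solve(S))), 1e-6)

  # full shrinkage on correlation input: empty adjacency
  R <- cor(x)
  fit2 <- penalized_mle(R, penalty_matrix(letters[1:5], 1))
  expect_equal(n_edges(fit2$adjacency), 0)
})

test_that("KKT stationarity holds on random prior-weighted fits", {
  set.seed(57)
  for (rep in 1:10) {
    G <- random_network(8, 0.3)
    x <- simulate_gaussian(G, 300)$data
    P <- prior_from_graph(G, strength = runif(1, 0.5, 0.99))
    L <- penalty_matrix(colnames(x), runif(1, 0.05, 0.6), P)
    fit <- penalized_mle(cov(scale(x)), L)
    expect_lt(fit$kkt_residual, 1e-6)
  }
})

test_that("penalty construction is antitone in the prior", {
  nodes <- c("a", "b", "c")
  P <- matrix(c(0, 1, 1e-7, 1, 0, 0.5, 1e-7, 0.5, 0), 3,
              dimnames = list(nodes, nodes))
  L <- penalty_matrix(nodes, 0.4, P)
  expect_equal(L["a", "b"], 0) # prior 1 -> no penalty
  expect_equal(L["a", "c"], 0.4 * (1 - 1e-7)) # pseudo -> ~ full omega
  expect_equal(L["b", "c"], 0.2)
  expect_true(all(diag(L) == 0))
})

test_that("cross-validated glasso recovers structure and uses priors", {
  set.seed(61)
  # pure noise: few spurious edges
  spurious <- replicate(3, {
    x <- matrix(rnorm(200 * 20), 200, 20,
                dimnames = list(NULL, sprintf("v%02d", 1:20)))
    suppressWarnings( # empty selected networks are the point here
      n_edges(penalized_cv(x, omega_grid = seq(0.05, 1, 0.05))$network))
  })
  expect_lte(median(spurious), 2)

  # strong 5-edge chain at n = 600: full recovery
  nodes <- sprintf("c%d", 1:6)
  chain <- make_network(nodes, cbind(nodes[-6], nodes[-1]))
  x <- simulate_gaussian(chain, 600)$data
  fit <- penalized_cv(x, omega_grid = seq(0.02, 1, 0.02))
  cc <- confusion(fit$network, chain)
  expect_equal(cc$fn, 0L)
  expect_gte(mcc(cc), 0.8)

  # priors on the true edges can only help (paired, same data and folds)
  set.seed(62)
  G <- random_network(12, 0.2)
  xg <- simulate_gaussian(G, 300)$data
  P <- prior_from_graph(G, 0.99)
  set.seed(99)
  m_p <- mcc(confusion(penalized_cv(xg, P)$network, G))
  set.seed(99)
  m_0 <- mcc(confusion(penalized_cv(xg, NULL)$network, G))
  expect_gte(m_p, m_0)
})

test_that("shrinkage pcor network controls nulls and finds strong edges", {
  set.seed(63)
  x <- matrix(rnorm(500 * 20), 500, 20,
              dimnames = list(NULL, sprintf("v%02d", 1:20)))
  r <- shrinkage_pcor_network(x)
  expect_lte(n_edges(r$network), 1)
  expect_gte(r$shrinkage, 0)
  expect_lte(r$shrinkage, 1)

  G <- random_network(10, 0)
  G[1, 2] <- G[2, 1] <- 1
  xs <- simulate_gaussian(G, 600)$data
  r2 <- shrinkage_pcor_network(xs)
  expect_equal(unname(r2$network[1, 2]), 1)

  expect_error(shrinkage_pcor_network(x[1:2, ]), "3 samples")
  x_na <- x; x_na[1, 3] <- NA
  expect_message(shrinkage_pcor_network(x_na), "missing")
})

test_that("structure-search posteriors respond to data and priors", {
  set.seed(65)
  nodes <- c("a", "b", "c", "d")
  # independent data with pseudo-only priors: no confident edges
  x0 <- matrix(rnorm(400 * 4), 400, 4, dimnames = list(NULL, nodes))
  P0 <- matrix(pseudo_prior(), 4, 4, dimnames = list(nodes, nodes))
  diag(P0) <- 0
  r0 <- mcmc_structure_search(x0, P0, iter = 4000, burnin = 2000, seed = 2)
  expect_true(all(r0$probs < 0.5))

  # bivariate r = 0.9 at n = 600: posterior ~ 1 under a flat prior
  z <- rnorm(600)
  xb <- cbind(a = z, b = 0.9 * z + sqrt(1 - 0.81) * rnorm(600),
              c = rnorm(600))
  rb <- mcmc_structure_search(xb, NULL, iter = 4000, burnin = 2000, seed = 3)
  expect_gte(rb$probs["a", "b"], 0.99)

  # hostile prior on a moderately supported edge lowers its posterior
  # (same data, same seed); r = 0.2 keeps the likelihood from saturating
  xm <- cbind(a = z, b = 0.2 * z + sqrt(1 - 0.04) * rnorm(600),
              c = rnorm(600))
  rm_flat <- mcmc_structure_search(xm, NULL, iter = 4000, burnin = 2000,
                                   seed = 3)
  Ph <- matrix(0.5, 3, 3, dimnames = list(colnames(xm), colnames(xm)))
  Ph["a", "b"] <- Ph["b", "a"] <- pseudo_prior()
  diag(Ph) <- 0
  rh <- mcmc_structure_search(xm, Ph, iter = 4000, burnin = 2000, seed = 3)
  expect_lt(rh$probs["a", "b"], rm_flat$probs["a", "b"])
})

test_that("posterior network selection thresholds correctly", {
  pm <- matrix(c(0, 0.95, 0.85, 0.95, 0, 0.1, 0.85, 0.1, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(n_edges(select_posterior_network(pm, 0.9)), 1)
  expect_equal(n_edges(select_posterior_network(pm, 1)), 0)
  expect_equal(n_edges(select_posterior_network(pm, 0)), 3) # visited edges
})

test_that("tree-ensemble links are ranked, nonnegative and max-symmetrized", {
  set.seed(67)
  G <- random_network(8, 0)
  G[1, 2] <- G[2, 1] <- 1
  x <- simulate_gaussian(G, 400)$data
  links <- tree_ensemble_links(x, num_trees = 300, seed = 5)
  expect_true(all(links$weight >= 0))
  expect_true(all(diff(links$weight) <= 1e-12))
  expect_equal(nrow(links), choose(8, 2))
  # the planted edge dominates across seeds
  tops <- vapply(1:5, function(s) {
    l <- tree_ensemble_links(x, num_trees = 300, seed = s)
    paste(l$a[1], l$b[1])
  }, "")
  expect_true(all(tops == paste(rownames(G)[1], rownames(G)[2])))
  # determinism given the seed
  links2 <- tree_ensemble_links(x, num_trees = 300, seed = 5)
  expect_identical(links, links2)
})

test_that("scale-free cutoff selection follows the R2 rule", {
  # preferential-attachment-style graph with true links ranked first
  set.seed(69)
  ba <- igraph::sample_pa(120, power = 1, m = 1, directed = FALSE)
  adj <- as.matrix(igraph::as_adjacency_matrix(ba))
  dimnames(adj) <- list(sprintf("g%03d", 1:120), sprintf("g%03d", 1:120))
  ed <- network_edges(adj)
  true_links <- data.frame(a = ed$a, b = ed$b,
                           weight = runif(nrow(ed), 0.6, 1))
  # false links below every true weight
  all_pairs <- which(upper.tri(adj) & adj == 0, arr.ind = TRUE)
  pick <- all_pairs[sample.int(nrow(all_pairs), 300), ]
  false_links <- data.frame(a = rownames(adj)[pick[, 1]],
                            b = rownames(adj)[pick[, 2]],
                            weight = runif(300, 0, 0.4))
  links <- rbind(true_links, false_links)
  links <- links[order(-links$weight), ]
  attr(links, "nodes") <- rownames(adj)
  sel <- scale_free_cutoff(links)
  expect_gt(sel$r2, 0.8)
  # the selected network drops the low-weight false tail
  expect_lte(n_edges(sel$network), nrow(links))
  expect_gte(n_edges(sel$network), nrow(true_links) * 0.5)

  # single unique weight: single candidate
  l1 <- data.frame(a = c("a", "b"), b = c("b", "c"), weight = c(1, 1))
  sel1 <- scale_free_cutoff(l1)
  expect_equal(n_edges(sel1$network), 2)

  # star: degenerate two-point degree distribution falls back with warning
  star <- data.frame(a = "hub", b = sprintf("s%02d", 1:15),
                     weight = seq(1, 0.5, length.out = 15))
  expect_warning(sel_s <- scale_free_cutoff(star), "enough distinct")
  expect_gte(n_edges(sel_s$network), 1)
})
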