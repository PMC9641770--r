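#' Configuration for the simulation benchmark
#'
#' Bundles the study conditions of the simulation experiment: number of
#' repeated runs per hotspot, simulated sample size, the prior-error ladder,
#' the sample-size grid, the prior-completeness grid, the SNP minor allele
#' frequency used to discretize the genotype column (Hardy-Weinberg dosage
#' frequencies), the inference methods to run and the RNG seed.
#'
#' @param n_runs repetitions per hotspot (default 100).
#' @param n_samples simulated samples (default 612, a typical cohort size).
#' @param error_fractions prior error ladder (default 0, 0.1, ..., 1).
#' @param subset_sizes sample-size grid for the no-error scenario
#'   (default 50, 100, ..., 600).
#' @param completeness_keep kept prior fractions (default 0.1, ..., 0.9).
#' @param maf minor allele frequency of the simulated SNP (default 0.3).
#' @param methods method names; any of `"glasso_p"`, `"glasso"`,
#'   `"bdgraph_p"`, `"bdgraph"`, `"genenet"`, `"genie3"` (`_p` marks the
#'   prior-aware variants).
#' @param run_error_grid,run_subset_grid,run_completeness_grid,run_density_prior
#'   which scenario blocks to execute.
#' @param mcmc_iter,mcmc_burnin chain length of the Bayesian engine.
#' @param omega_grid penalty grid of the cross-validated graphical lasso.
#' @param seed integer master seed.
#' @export
benchmark_config <- function(n_runs = 100, n_samples = 612,
                             error_fractions = seq(0, 1, by = 0.1),
                             subset_sizes = seq(50, 600, by = 50),
                             completeness_keep = seq(0.1, 0.9, by = 0.1),
                             maf = 0.3,
                             methods = c("glasso_p", "glasso", "bdgraph_p",
                                         "bdgraph", "genenet", "genie3"),
                             run_error_grid = TRUE,
                             run_subset_grid = FALSE,
                             run_completeness_grid = FALSE,
                             run_density_prior = FALSE,
                             mcmc_iter = 10000, mcmc_burnin = 5000,
                             omega_grid = seq(0.01, 1, by = 0.005),
                             seed = 1) {
  stopifnot(all(error_fractions >= 0 & error_fractions <= 1),
            all(subset_sizes <= n_samples),
            all(completeness_keep > 0 & completeness_keep <= 1),
            maf > 0, maf <= 0.5)
  structure(as.list(environment()), class = "benchmark_config")
}

# Hardy-Weinberg dosage frequencies (minor-allele dosage counts 0/1/2).
hwe_dosage_freqs <- function(maf) {
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

run_method <- function(method, data, P, seed, cfg) {
  switch(method,
    glasso_p = penalized_cv(data, P, omega_grid = cfg$omega_grid)$network,
    glasso = penalized_cv(data, NULL, omega_grid = cfg$omega_grid)$network,
    bdgraph_p = select_posterior_network(
      mcmc_structure_search(data, P, iter = cfg$mcmc_iter,
                            burnin = cfg$mcmc_burnin, seed = seed)),
    bdgraph = select_posterior_network(
      mcmc_structure_search(data, NULL, iter = cfg$mcmc_iter,
                            burnin = cfg$mcmc_burnin, seed = seed)),
    genenet = shrinkage_pcor_network(data)$network,
    genie3 = scale_free_cutoff(
      tree_ensemble_links(data, seed = seed))$network,
    stop("unknown method: ", method)
  )
}

uses_prior <- function(method) method %in% c("glasso_p", "bdgraph_p")

#' Run the simulation benchmark
#'
#' For every hotspot prior matrix and run: samples a ground-truth graph
#' from the priors, builds the degree-preserving error ladder, simulates
#' Gaussian data with the graph's covariance structure at the configured
#' sample size, discretizes the first (SNP) column to dosages, runs each
#' configured method and scores the inferred networks against the matching
#' ground truth. Optional blocks repeat the no-error condition on
#' sub-sampled data (sample-size grid), with thinned priors (completeness
#' grid), and with the scalar density prior in place of the edge priors.
#' Method failures are recorded per cell, not fatal. Fully reproducible
#' given `cfg$seed`.
#'
#' @param cfg [benchmark_config()].
#' @param priors named list of prior matrices, one per hotspot; the first
#'   node of each matrix is treated as the SNP column.
#' @return tidy data.frame: `hotspot`, `run`, `method`, `condition`,
#'   `error_fraction`, `subset_size`, `keep_fraction`, `mcc`,
#'   `sensitivity`, `specificity`, `n_edges_pred`, `n_edges_truth`,
#'   `runtime_s`, `error` (message for failed cells).
#' @export
run_benchmark <- function(cfg, priors) {
  stopifnot(inherits(cfg, "benchmark_config"), length(priors) > 0,
            !is.null(names(priors)), length(cfg$methods) > 0)
  rows <- list()
  freqs <- hwe_dosage_freqs(cfg$maf)

  cell <- function(hotspot, run, method, condition, error_fraction,
                   subset_size, keep_fraction, data, P, truth, seed) {
    t0 <- proc.time()[3]
    set.seed(seed) # same fold splits / forests across methods in a cell
    net <- tryCatch(run_method(method, data, P, seed, cfg),
                    error = function(e) conditionMessage(e))
    dt <- proc.time()[3] - t0
    if (is.character(net)) {
      return(data.frame(hotspot = hotspot, run = run, method = method,
                        condition = condition,
                        error_fraction = error_fraction,
                        subset_size = subset_size,
                        keep_fraction = keep_fraction,
                        mcc = NA_real_, sensitivity = NA_real_,
                        specificity = NA_real_, n_edges_pred = NA_real_,
                        n_edges_truth = n_edges(truth), runtime_s = dt,
                        error = net, stringsAsFactors = FALSE))
    }
    cc <- confusion(net, truth)
    ss <- sensitivity_specificity(cc)
    data.frame(hotspot = hotspot, run = run, method = method,
               condition = condition, error_fraction = error_fraction,
               subset_size = subset_size, keep_fraction = keep_fraction,
               mcc = mcc(cc), sensitivity = ss[["sensitivity"]],
               specificity = ss[["specificity"]],
               n_edges_pred = n_edges(net),
               n_edges_truth = n_edges(truth), runtime_s = dt,
               error = NA_character_, stringsAsFactors = FALSE)
  }

  for (hi in seq_along(priors)) {
    hotspot <- names(priors)[hi]
    P <- priors[[hi]]
    for (run in seq_len(cfg$n_runs)) {
      run_seed <- (cfg$seed + 7919L * hi + 104729L * run) %% .Machine$integer.max
      set.seed(run_seed)
      g_truth <- sample_graph_from_priors(P)

      ladder <- list()
      for (f in cfg$error_fractions) {
        g <- if (f == 0 || n_edges(g_truth) == 0) g_truth else
          tryCatch(rewire_with_error(g_truth, f, P),
                   error = function(e) NULL)
        ladder[[sprintf("%.2f", f)]] <- g
      }

      make_data <- function(g) {
        sim <- simulate_gaussian(g, cfg$n_samples)
        x <- sim$data
        x[, 1] <- discretize_snp(x[, 1], freqs)
        x
      }

      if (cfg$run_error_grid) {
        for (f in cfg$error_fractions) {
          g <- ladder[[sprintf("%.2f", f)]]
          if (is.null(g)) next # infeasible rewiring at this fraction
          x <- make_data(g)
          for (m in cfg$methods) {
            rows[[length(rows) + 1L]] <- cell(
              hotspot, run, m, "error_grid", f, cfg$n_samples, 1,
              x, if (uses_prior(m)) P else NULL, g, run_seed)
          }
        }
      }

      if (cfg$run_subset_grid) {
        x0 <- make_data(g_truth)
        for (s in cfg$subset_sizes) {
          xs <- x0[seq_len(s), , drop = FALSE]
          for (m in cfg$methods) {
            rows[[length(rows) + 1L]] <- cell(
              hotspot, run, m, "subset_grid", 0, s, 1,
              xs, if (uses_prior(m)) P else NULL, g_truth, run_seed)
          }
        }
      }

      if (cfg$run_completeness_grid) {
        x0 <- make_data(g_truth)
        for (keep in cfg$completeness_keep) {
          Pk <- degrade_priors(P, keep)
          for (m in cfg$methods[vapply(cfg$methods, uses_prior, TRUE)]) {
            rows[[length(rows) + 1L]] <- cell(
              hotspot, run, m, "completeness_grid", 0, cfg$n_samples,
              keep, x0, Pk, g_truth, run_seed)
          }
        }
      }

      if (cfg$run_density_prior) {
        x0 <- make_data(g_truth)
        p_dens <- density_prior(list(g_truth), nrow(P))
        Pd <- matrix(p_dens, nrow(P), ncol(P), dimnames = dimnames(P))
        diag(Pd) <- 0
        for (m in cfg$methods[vapply(cfg$methods, uses_prior, TRUE)]) {
          rows[[length(rows) + 1L]] <- cell(
            hotspot, run, m, "density_prior", 0, cfg$n_samples, 1,
            x0, Pd, g_truth, run_seed)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
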