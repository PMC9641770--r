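#' Per-edge penalty matrix from a prior matrix
#'
#' Maps priors to graphical-lasso penalties via `Lambda = (1 - P) * omega`
#' (a prior of 1 means no penalty, the pseudo-prior an almost-full penalty
#' `omega`). Without priors the penalty is the constant `omega`. The
#' diagonal is never penalized.
#'
#' @param nodes node names (defines dimension and order).
#' @param omega global penalty weight.
#' @param P optional prior matrix on `nodes`.
#' @export
penalty_matrix <- function(nodes, omega, P = NULL) {
  p <- length(nodes)
  if (is.null(P)) {
    L <- matrix(omega, p, p, dimnames = list(nodes, nodes))
  } else {
    stopifnot(identical(rownames(P), nodes))
    L <- (1 - P) * omega
  }
  diag(L) <- 0
  L
}

#' Penalized Gaussian precision estimation with per-edge penalties
#'
#' Solves
#' \deqn{\max_\Theta\ \log\det\Theta - tr(S\Theta)
#'   - \sum_{i\neq j} \Lambda_{ij} |\Theta_{ij}|}
#' by block coordinate descent (graphical lasso with a penalty matrix; the
#' diagonal is unpenalized). The fit is verified against the KKT
#' stationarity conditions: `|S - Sigma_hat| <= Lambda` entrywise for zero
#' entries of Theta and `S - Sigma_hat + Lambda * sign(Theta) = 0` for
#' nonzero ones.
#'
#' @param S sample covariance (symmetric PSD, with dimnames).
#' @param Lambda penalty matrix ([penalty_matrix()]).
#' @param tol relative convergence tolerance of the outer loop.
#' @param max_iter outer iteration cap.
#' @param zero_tol absolute threshold deciding the adjacency (default 1e-8).
#' @return list: `Theta` (precision estimate), `Sigma` (its inverse as
#'   maintained by the algorithm), `adjacency` (0/1 matrix of the nonzero
#'   off-diagonal pattern), `kkt_residual`, `niter`.
#' @export
penalized_mle <- function(S, Lambda, tol = 1e-9, max_iter = 500,
                          zero_tol = 1e-8) {
  stopifnot(identical(dim(S), dim(Lambda)))
  fit <- glasso_cpp(S, Lambda, tol = tol, max_iter = max_iter)
  if (!fit$converged)
    stop("penalized MLE did not converge after ", max_iter,
         " iterations (max KKT residual ",
         signif(kkt_residual(S, Lambda, fit$Theta, fit$W, zero_tol), 3), ")")
  dimnames(fit$Theta) <- dimnames(S)
  dimnames(fit$W) <- dimnames(S)
  adj <- (abs(fit$Theta) > zero_tol) * 1
  diag(adj) <- 0
  res <- kkt_residual(S, Lambda, fit$Theta, fit$W, zero_tol)
  list(Theta = fit$Theta, Sigma = fit$W, adjacency = adj,
       kkt_residual = res, niter = fit$niter)
}

# Max violation of the stationarity conditions of the penalized problem.
kkt_residual <- function(S, Lambda, Theta, Sigma, zero_tol = 1e-8) {
  D <- S - Sigma
  off <- upper.tri(S) | lower.tri(S)
  zero <- off & abs(Theta) <= zero_tol
  nonzero <- off & abs(Theta) > zero_tol
  r1 <- if (any(zero)) max(pmax(abs(D[zero]) - Lambda[zero], 0)) else 0
  r2 <- if (any(nonzero))
    max(abs(D[nonzero] + Lambda[nonzero] * sign(Theta[nonzero]))) else 0
  max(r1, r2)
}

#' Cross-validated prior-weighted graphical lasso network
#'
#' Screens the global penalty weight omega over a grid: for each omega the
#' model is fitted on each training fold (with `Lambda = (1 - P) * omega`,
#' or the constant omega without priors) and scored on the held-out fold by
#' \deqn{BIC = -2\,\ell(\hat\Theta; S_{test}, n_{test})
#'   + |E(\hat\Theta)|\log(n_{test}),}
#' where \eqn{\hat\Theta} is the training-fold Gaussian MLE restricted to
#' the support selected at that omega (the refit removes the lasso's
#' shrinkage bias, which would otherwise bias selection toward dense
#' low-penalty fits). The omega minimizing the mean test BIC is selected
#' and the model refitted on the full data. Columns are gaussianized and
#' standardized before fitting, so S is a correlation-scale covariance.
#'
#' @param data samples x nodes matrix (mixed dosage/continuous allowed).
#' @param P optional prior matrix in data column order.
#' @param omega_grid penalty weights to screen (default `seq(0.01, 1, 0.005)`).
#' @param k number of folds (default 5).
#' @return list: `network` (adjacency), `omega` (selected weight),
#'   `profile` (data.frame omega/mean test BIC), `fit` (full-data
#'   [penalized_mle()] fit at the selected omega).
#' @export
penalized_cv <- function(data, P = NULL,
                         omega_grid = seq(0.01, 1, by = 0.005), k = 5) {
  x <- scale(gaussianize(data))
  n <- nrow(x)
  p <- ncol(x)
  nodes <- colnames(x)
  if (n < 2 * k) stop("need at least 2 samples per fold")
  if (!is.null(P)) stopifnot(identical(rownames(P), nodes))

  folds <- rep_len(seq_len(k), n)[sample.int(n)]
  omega_grid <- sort(omega_grid, decreasing = TRUE) # warm-start small models
  Lbase <- penalty_matrix(nodes, 1, P) # scaled by omega along the path
  bic <- matrix(NA_real_, length(omega_grid), k)

  for (fold in seq_len(k)) {
    tr <- x[folds != fold, , drop = FALSE]
    te <- x[folds == fold, , drop = FALSE]
    bic[, fold] <- glasso_bic_path_cpp(stats::cov(tr), stats::cov(te),
                                       Lbase, omega_grid, nrow(te),
                                       tol = 1e-7)
  }

  mean_bic <- rowMeans(bic)
  if (all(!is.finite(mean_bic)))
    stop("all cross-validation fits failed")
  best <- which.min(mean_bic)
  omega <- omega_grid[best]

  fit <- penalized_mle(stats::cov(x), penalty_matrix(nodes, omega, P))
  net <- fit$adjacency
  if (n_edges(net) == 0)
    warning("selected network is empty across the omega grid")
  out <- list(network = net, omega = omega,
              profile = data.frame(omega = omega_grid, bic = mean_bic),
              fit = fit)
  out
}

# BIC of a fitted precision against held-out covariance.
gaussian_bic <- function(Theta, S_test, n_test) {
  p <- nrow(Theta)
  ld <- determinant(Theta, logarithm = TRUE)
  if (ld$sign <= 0) return(Inf)
  ll <- 0.5 * n_test *
    (as.numeric(ld$modulus) - sum(S_test * Theta) - p * log(2 * pi))
  nedges <- sum(abs(Theta[upper.tri(Theta)]) > 1e-8)
  -2 * ll + nedges * log(n_test)
}
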