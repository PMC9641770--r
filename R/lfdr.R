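#' Local false discovery rate from a p-value sample
#'
#' Fits the two-component model
#' \deqn{lfdr(p) = \eta_0 f_0(p) / f(p)}
#' with a uniform null \eqn{f_0 = 1}. The mixture density \eqn{f} is
#' estimated on the p-scale by the Grenander (monotone-decreasing) density
#' estimator, i.e. the left derivative of the least concave majorant of the
#' empirical CDF. The null proportion \eqn{\eta_0} is estimated from the
#' density plateau near p = 1 via the majorant tail mass above
#' `plateau_from`. Results are clipped to [0, 1] and are monotone
#' nondecreasing in p (enforced by a final isotonic pass).
#'
#' The lfdr is the posterior probability that a case is null given its
#' p-value; `1 - lfdr` is used as an edge prior throughout the package.
#'
#' @param pvalues numeric vector with values in (0, 1].
#' @param min_n minimum number of p-values required for the density
#'   estimate (default 200).
#' @param plateau_from left end of the plateau window used for the
#'   \eqn{\eta_0} estimate (default 0.8).
#' @return list of class `lfdr_estimate`: `pvalues`, `lfdr` (aligned with
#'   the input), `eta0`, and the fitted density knots (`knots_p`,
#'   `knots_f`).
#' @export
estimate_lfdr <- function(pvalues, min_n = 200, plateau_from = 0.8) {
  bad <- which(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1)
  if (length(bad))
    stop("p-values outside (0, 1] at index: ",
         paste(head(bad, 10), collapse = ", "))
  n <- length(pvalues)
  if (n < min_n)
    stop("too few p-values for density estimation (", n, " < ", min_n, ")")

  g <- grenander_density(pvalues)
  f_at <- function(p) g$f[findInterval(p, g$x, left.open = TRUE) + 1L]

  # plateau eta0: LCM-smoothed tail mass over [plateau_from, 1]
  F_lcm <- stats::approx(c(0, g$x), c(0, g$F), xout = plateau_from,
                         rule = 2)$y
  eta0 <- min(1, (1 - F_lcm) / (1 - plateau_from))

  lfdr <- pmin(1, pmax(0, eta0 / f_at(pvalues)))
  ord <- order(pvalues)
  iso <- stats::isoreg(x = pvalues[ord], y = lfdr[ord])
  lfdr[ord] <- pmin(1, iso$yf)

  structure(list(pvalues = pvalues, lfdr = lfdr, eta0 = eta0,
                 knots_p = g$x, knots_f = g$f),
            class = "lfdr_estimate")
}

# Grenander estimator: slopes of the least concave majorant of the ECDF on
# (0, 1]. Returns right-closed segments: f is constant on (x[i-1], x[i]].
grenander_density <- function(p) {
  sp <- sort(p)
  # pool adjacent violators on slopes of the ECDF polygon, including the
  # terminal segment to (1, 1) so the density integrates to one on (0, 1]
  xs <- unique(c(sp, 1))
  Fe <- vapply(xs, function(x) mean(sp <= x), 0)
  dx <- diff(c(0, xs))
  dF <- diff(c(0, Fe))
  # least concave majorant of the cumulative polygon = isotonic (decreasing)
  # regression of the slopes with segment-length weights
  f <- pava_decreasing(dF / dx, dx)
  list(x = xs, f = f, F = cumsum(f * dx))
}

# Weighted pool-adjacent-violators for a nonincreasing fit.
pava_decreasing <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; idx <- as.list(seq_len(n))
  i <- 1L
  while (i < length(val)) {
    if (val[i] < val[i + 1L] - 1e-15) { # violation of nonincreasing order
      merged <- (val[i] * wt[i] + val[i + 1L] * wt[i + 1L]) /
        (wt[i] + wt[i + 1L])
      val[i] <- merged
      wt[i] <- wt[i] + wt[i + 1L]
      idx[[i]] <- c(idx[[i]], idx[[i + 1L]])
      val <- val[-(i + 1L)]; wt <- wt[-(i + 1L)]; idx <- idx[-(i + 1L)]
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  out <- numeric(n)
  for (k in seq_along(val)) out[idx[[k]]] <- val[k]
  out
}

#' @export
print.lfdr_estimate <- function(x, ...) {
  cat("lFDR estimate over", length(x$pvalues), "p-values; eta0 =",
      signif(x$eta0, 4), "\n")
  invisible(x)
}
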