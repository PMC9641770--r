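#' Rank-based inverse-normal transform of a data matrix
#'
#' Transforms every column by the rank-based inverse-normal map
#' `qnorm((rank - 0.5) / n)` with average ranks for ties. Dosage columns
#' are transformed the same way, which is how mixed genotype/continuous
#' data enter all inference engines uniformly (a Gaussian-copula
#' surrogate). The transform is invariant to monotone distortions of a
#' column.
#'
#' @param data numeric matrix (samples x features).
#' @return matrix of the same shape and dimnames.
#' @export
gaussianize <- function(data) {
  data <- as.matrix(data)
  const <- which(apply(data, 2, function(col) length(unique(col)) == 1))
  if (length(const))
    stop("constant column(s): ",
         paste(colnames(data)[const], collapse = ", "))
  out <- apply(data, 2, function(col)
    qnorm((rank(col, ties.method = "average") - 0.5) / length(col)))
  dimnames(out) <- dimnames(data)
  out
}
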