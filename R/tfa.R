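#' Estimate per-sample transcription factor activities
#'
#' Models standardized expression of each sample as a linear mix of TF
#' activities through a binary TF-target incidence structure,
#' `e_s ~ C a_s`, and solves the ridge least-squares problem
#' `min ||e - C a||^2 + ridge ||a||^2` per sample in closed form. TFs
#' without any target present in the expression matrix are dropped with a
#' warning.
#'
#' @param expression samples x genes numeric matrix.
#' @param incidence genes x TFs binary matrix (1 when the gene carries a
#'   binding site of the TF in its promoter).
#' @param ridge ridge penalty (default 1e-3).
#' @return samples x TFs matrix of activities.
#' @export
estimate_tfa <- function(expression, incidence, ridge = 1e-3) {
  genes <- intersect(rownames(incidence), colnames(expression))
  if (!length(genes))
    stop("no overlap between expression genes and incidence genes")
  C <- as.matrix(incidence[genes, , drop = FALSE])
  empty <- colSums(C != 0) == 0
  if (any(empty)) {
    warning("dropping TF(s) without targets in the expression data: ",
            paste(colnames(C)[empty], collapse = ", "))
    C <- C[, !empty, drop = FALSE]
  }
  if (!ncol(C)) stop("no TF with targets left")

  E <- scale(expression[, genes, drop = FALSE]) # genes standardized
  E[is.nan(E)] <- 0
  A <- solve(crossprod(C) + ridge * diag(ncol(C)), t(C) %*% t(E))
  out <- t(A)
  dimnames(out) <- list(rownames(expression), colnames(C))
  out
}

#' Substitute TF expression columns by activity estimates
#'
#' Replaces the listed TF columns of an omics matrix by the matching
#' activity columns; every other column and the column order are untouched.
#'
#' @param data samples x nodes matrix.
#' @param tfa samples x TFs activity matrix ([estimate_tfa()]), rows
#'   aligned with `data`.
#' @param tfs TF node names to substitute (must be columns of both).
#' @export
substitute_tfa <- function(data, tfa, tfs) {
  if (!length(tfs)) return(data)
  stopifnot(all(tfs %in% colnames(data)), all(tfs %in% colnames(tfa)))
  if (nrow(data) != nrow(tfa) ||
      (!is.null(rownames(data)) && !is.null(rownames(tfa)) &&
       !identical(rownames(data), rownames(tfa))))
    stop("sample mismatch between data and TFA matrix")
  out <- data
  out[, tfs] <- tfa[, tfs]
  out
}
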