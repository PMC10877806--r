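#' Cell-type deconvolution by constrained least squares
#'
#' Estimates the cell-type composition of each bulk sample by regressing its
#' linear-scale expression over the signature matrix under a nonnegativity
#' constraint (via `pracma::lsqnonneg`), then renormalizing the coefficients
#' to proportions summing to one — in-silico flow cytometry by nonnegative
#' least squares. Expression is converted from log2 to the linear scale
#' internally (`linear_scale = FALSE` skips the conversion when the input is
#' already linear, as the signature must be).
#'
#' @param expr Genes x samples matrix. Log2 scale by default.
#' @param signature Signature genes x cell-types matrix on the linear scale,
#'   nonnegative, at least two cell types; rownames must overlap `expr`
#'   rownames by at least the number of cell types.
#' @param linear_scale Is `expr` already linear-scale? Default `FALSE`
#'   (log2 input).
#' @return A `deconvolution_result` list: `proportions` (samples x cell-types,
#'   rows on the simplex), `residual_norm` (per-sample Euclidean residual of
#'   the constrained fit), `genes_used`.
#' @export
deconvolve <- function(expr, signature, linear_scale = FALSE) {
  stopifnot(is.matrix(expr), is.matrix(signature))
  if (ncol(signature) < 2) abort("signature must contain >= 2 cell types")
  if (any(signature < 0)) abort("signature entries must be nonnegative")
  genes <- intersect(rownames(expr), rownames(signature))
  if (length(genes) < ncol(signature)) {
    abort("signature/expression gene overlap smaller than number of cell types")
  }
  S <- signature[genes, , drop = FALSE]
  if (qr(S)$rank < ncol(S)) {
    cc <- which(abs(cor(S)) > 0.999999 & upper.tri(cor(S)), arr.ind = TRUE)
    pairs <- if (nrow(cc)) {
      paste(colnames(S)[cc[, 1]], colnames(S)[cc[, 2]], sep = " ~ ",
            collapse = ", ")
    } else "unidentified columns"
    abort(paste0("signature matrix is rank deficient (collinear cell types: ",
                 pairs, ")"))
  }
  E <- expr[genes, , drop = FALSE]
  if (!linear_scale) E <- 2^E
  n_types <- ncol(S)
  props <- matrix(NA_real_, ncol(E), n_types,
                  dimnames = list(colnames(E), colnames(S)))
  resid <- numeric(ncol(E))
  for (j in seq_len(ncol(E))) {
    fit <- pracma::lsqnonneg(S, E[, j])
    w <- fit$x
    resid[j] <- sqrt(fit$resid.norm)
    if (sum(w) == 0) {
      warn(paste0("deconvolve: sample '", colnames(E)[j],
                  "' fit entirely to zero; uniform proportions reported"))
      props[j, ] <- 1 / n_types
    } else {
      props[j, ] <- w / sum(w)
    }
  }
  structure(list(proportions = props,
                 residual_norm = setNames(resid, colnames(E)),
                 genes_used = genes),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat("<deconvolution_result>", nrow(x$proportions), "samples x",
      ncol(x$proportions), "cell types\n")
  cat("  mean proportions:",
      paste(sprintf("%s=%.3f", colnames(x$proportions),
                    colMeans(x$proportions)), collapse = ", "), "\n")
  invisible(x)
}
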