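#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution given
#' by the mean of order statistics across samples, preserving within-sample
#' ranks; tied entries receive the mean of the corresponding reference
#' quantiles. Delegates to `limma::normalizeQuantiles(ties = TRUE)`.
#'
#' @param mat Numeric matrix, features x samples (log2 intensities), no
#'   missing values (imputation is out of scope and an error).
#' @return Matrix of the same shape and dimnames, all columns sharing the
#'   identical empirical distribution.
#' @export
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (ncol(mat) < 2) abort("quantile normalization needs >= 2 samples")
  if (anyNA(mat)) abort("expression matrix contains missing values")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Collapse probes to one row per gene by maximum IQR
#'
#' For each gene, the probe with the largest interquartile range across
#' samples is retained (the most informative probe); IQR ties are broken by
#' the lexicographically smallest probe id. Probes absent from the map are
#' dropped with a message.
#'
#' @param mat Numeric matrix, probes x samples, with probe ids as rownames.
#' @param probe_map Data frame with columns `probe` and `gene` (many probes
#'   per gene allowed).
#' @return Matrix with one row per distinct mapped gene (gene symbols as
#'   rownames), same columns. The retained probe per gene is attached as
#'   attribute `"selected_probe"`.
#' @export
collapse_probes_max_iqr <- function(mat, probe_map) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), is.data.frame(probe_map),
            all(c("probe", "gene") %in% names(probe_map)))
  pm <- probe_map[!is.na(probe_map$gene) & probe_map$probe %in% rownames(mat), ]
  if (nrow(pm) == 0) abort("no overlap between matrix probes and probe map")
  n_unmapped <- sum(!rownames(mat) %in% pm$probe)
  if (n_unmapped > 0) {
    inform(paste0("collapse_probes_max_iqr: dropped ", n_unmapped,
                  " unmapped probe(s)"))
  }
  iqr <- apply(mat[pm$probe, , drop = FALSE], 1, IQR)
  ord <- order(pm$gene, -iqr, pm$probe)  # per gene: max IQR, then smallest id
  pm <- pm[ord, ]
  keep <- pm[!duplicated(pm$gene), ]
  out <- mat[keep$probe, , drop = FALSE]
  rownames(out) <- keep$gene
  structure(out, selected_probe = setNames(keep$probe, keep$gene))
}

#' Read an expression matrix from TSV
#'
#' First column is the feature id; remaining columns are samples.
#'
#' @param path TSV file path.
#' @return Numeric matrix, features x samples.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write an expression-like matrix to TSV
#'
#' @param mat Matrix with rownames.
#' @param path Output path.
#' @param id_col Name for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature") {
  df <- tibble::as_tibble(mat, rownames = id_col)
  readr::write_tsv(df, path)
  invisible(path)
}
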