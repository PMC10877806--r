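#' Rank genes by association with a deconvolved cell fraction
#'
#' Ranks genes by the significance of their correlation (Spearman by
#' default; Pearson available) with a per-sample cell-type fraction — used
#' to extract the most monocyte-specific genes from a bulk matrix — and
#' returns the top `k`.
#'
#' @param expr Genes x samples matrix (log2 scale), sample ids as colnames.
#' @param cell_fraction Named numeric vector of per-sample fractions (names =
#'   sample ids), e.g. the monocyte column of [deconvolve()] proportions.
#' @param k Number of genes to return; default 30.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Tibble of the top `k` genes: `gene`, `R`, `p`, `rank` — ordered by
#'   increasing p, ties broken by decreasing |R| then gene id.
#' @export
select_top_marker_genes <- function(expr, cell_fraction,
                                    k = frailomics_defaults$top_k,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(is.matrix(expr), !is.null(colnames(expr)))
  if (!is.numeric(k) || k <= 0) abort("k must be a positive integer")
  if (k > nrow(expr)) abort("k exceeds the number of genes")
  ids <- intersect(colnames(expr), names(cell_fraction))
  if (length(ids) < 3) abort("fewer than 3 aligned samples")
  f <- cell_fraction[ids]
  E <- expr[, ids, drop = FALSE]
  stats_tab <- t(apply(E, 1, function(g) {
    if (sd(g) == 0) return(c(R = NA_real_, p = NA_real_))
    ct <- suppressWarnings(cor.test(g, f, method = method, exact = FALSE))
    c(R = unname(ct$estimate), p = ct$p.value)
  }))
  tab <- tibble::tibble(gene = rownames(E), R = unname(stats_tab[, "R"]),
                        p = unname(stats_tab[, "p"]))
  tab <- tab[order(tab$p, -abs(tab$R), tab$gene, na.last = TRUE), ]
  tab$rank <- seq_len(nrow(tab))
  tab[seq_len(k), ]
}

#' Standardized gene x biomarker association matrix
#'
#' For each (gene, biomarker) pair, z-scores both variables (mean zero, SD
#' one, over the complete cases of the pair), fits a linear model of the
#' standardized gene expression on the standardized biomarker adjusted for
#' the covariates (default age and BMI), and stores the standardized
#' coefficient with significance stars. Rows (genes) and columns
#' (biomarkers) are ordered by hierarchical clustering on Euclidean
#' distance, ready for a heatmap.
#'
#' @param expr Genes x samples matrix restricted to the genes of interest
#'   (e.g. the top monocyte markers).
#' @param panel Biomarker panel (`id` + marker columns; the scale does not
#'   matter up to sign/monotonicity since each pair is z-scored, but the
#'   transformed panel matches the published analysis).
#' @param cohort Cohort table supplying covariates.
#' @param covariates Adjustment set; default `c("age", "BMI")`.
#' @param markers Marker columns; default all non-id panel columns.
#' @return A `marker_panel_matrix` list: `beta` (genes x markers standardized
#'   coefficients), `p`, `stars` (`""`, `"*"`, `"**"`, `"***"` at
#'   0.05/0.01/0.001), `row_order`, `col_order` (hclust orders), `n` (per-pair
#'   sample counts).
#' @export
marker_biomarker_matrix <- function(expr, panel, cohort,
                                    covariates = c("age", "BMI"),
                                    markers = NULL) {
  stopifnot(is.matrix(expr), !is.null(colnames(expr)))
  if (is.null(markers)) markers <- setdiff(names(panel), "id")
  if (nrow(expr) < 1 || length(markers) < 1) {
    abort("need >= 1 gene and >= 1 biomarker")
  }
  dat <- dplyr::inner_join(tibble::as_tibble(panel),
                           tibble::as_tibble(cohort)[, c("id", covariates)],
                           by = "id")
  dat <- dat[dat$id %in% colnames(expr), ]
  genes <- rownames(expr)
  B <- P <- N <- matrix(NA_real_, length(genes), length(markers),
                        dimnames = list(genes, markers))
  min_n <- length(covariates) + 4
  for (m in markers) {
    for (g in genes) {
      d <- tibble::tibble(y = expr[g, dat$id], x = dat[[m]])
      for (cv in covariates) d[[cv]] <- dat[[cv]]
      d <- d[complete.cases(d), ]
      N[g, m] <- nrow(d)
      if (nrow(d) < min_n || sd(d$y) == 0 || sd(d$x) == 0) next
      d$y <- as.numeric(scale(d$y)); d$x <- as.numeric(scale(d$x))
      fml <- as.formula(paste("y ~ x +", paste(covariates, collapse = "+")))
      sm <- summary(lm(fml, data = d))$coefficients
      B[g, m] <- sm["x", "Estimate"]
      P[g, m] <- sm["x", "Pr(>|t|)"]
    }
  }
  stars <- matrix("", nrow(B), ncol(B), dimnames = dimnames(B))
  stars[!is.na(P) & P < 0.05] <- "*"
  stars[!is.na(P) & P < 0.01] <- "**"
  stars[!is.na(P) & P < 0.001] <- "***"
  B0 <- B; B0[is.na(B0)] <- 0  # clustering tolerates missing pairs
  row_order <- if (nrow(B) > 2) hclust(dist(B0))$order else seq_len(nrow(B))
  col_order <- if (ncol(B) > 2) hclust(dist(t(B0)))$order else seq_len(ncol(B))
  structure(list(beta = B, p = P, stars = stars, n = N,
                 row_order = row_order, col_order = col_order),
            class = "marker_panel_matrix")
}

#' @export
print.marker_panel_matrix <- function(x, ...) {
  cat("<marker_panel_matrix>", nrow(x$beta), "genes x", ncol(x$beta),
      "biomarkers\n")
  b <- abs(x$beta[!is.na(x$beta)])
  cat(sprintf("  |standardized beta|: median %.3f, IQR %.3f-%.3f\n",
              median(b), quantile(b, 0.25), quantile(b, 0.75)))
  cat("  significant pairs:", sum(x$stars != ""), "of", length(x$stars), "\n")
  invisible(x)
}
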