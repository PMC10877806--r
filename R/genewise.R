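# Mass OLS over many response columns sharing one design matrix.
# Y: n x G responses; X: n x p full-rank design. Returns per-response
# coefficient, SE, t and two-sided p for every design column.
fit_mass_lm <- function(Y, X) {
  stopifnot(is.matrix(Y), is.matrix(X), nrow(Y) == nrow(X))
  n <- nrow(X); p <- ncol(X)
  df <- n - p
  if (df < 1) abort("mass lm: fewer observations than parameters")
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) {
    abort("mass lm: design matrix is rank deficient")
  })
  XtXinv <- chol2inv(ch)
  coefs <- XtXinv %*% crossprod(X, Y)          # p x G
  rownames(coefs) <- colnames(X)
  res <- Y - X %*% coefs
  sigma2 <- colSums(res^2) / df                # G
  se <- sqrt(outer(diag(XtXinv), sigma2))      # p x G
  rownames(se) <- colnames(X)
  tval <- coefs / se
  pval <- 2 * pt(-abs(tval), df = df)
  list(coef = coefs, se = se, t = tval, p = pval, df = df,
       sigma2 = sigma2)
}

tier_counts <- function(p, tiers = frailomics_defaults$p_tiers) {
  setNames(vapply(tiers, function(th) sum(p < th, na.rm = TRUE), integer(1)),
           paste0("p<", tiers))
}

#' Per-gene linear models of expression on the FI score
#'
#' Fits, for every gene, an ordinary least squares model with the gene's
#' expression as response and the FI score as the main exposure, adjusted for
#' the requested covariates (default age and BMI). Three adjustment variants
#' mirror the standard analysis: `"adjusted"` (age + BMI), `"crude"`
#' (FI only), and `"cell_adjusted"` (age + BMI + monocyte and lymphocyte
#' proportions, requiring `cell_props`).
#'
#' @param expr Genes x samples numeric matrix (log2 scale), sample ids as
#'   colnames.
#' @param fi An `fi_result` with ids matching the sample ids; excluded
#'   subjects are dropped.
#' @param cohort Cohort table supplying covariates (by `id`).
#' @param covariates Covariates for the adjusted model; default
#'   `c("age", "BMI")`.
#' @param model Which adjustment variant to fit.
#' @param cell_props Samples x cell-types proportion matrix (rownames = ids)
#'   with columns `monocytes` and `lymphocytes`; only used by
#'   `"cell_adjusted"`.
#' @param fdr_method Multiple-testing method for the q-value column; default
#'   Benjamini-Hochberg (`"BH"`), `"bonferroni"` available.
#' @return A `gene_assoc` tibble: `gene`, `beta` (expression change per unit
#'   FI), `se`, `p` (two-sided), `q`, `neg_log10_p`. Attributes:
#'   `tier_counts` (genes with p < 0.05 / 0.01 / 0.001), `n_samples`,
#'   `n_zero_variance`, `model`.
#' @export
genewise_fi_models <- function(expr, fi, cohort, covariates = c("age", "BMI"),
                               model = c("adjusted", "crude", "cell_adjusted"),
                               cell_props = NULL, fdr_method = "BH") {
  model <- match.arg(model)
  stopifnot(is.matrix(expr), !is.null(colnames(expr)))
  fi_tab <- tibble::as_tibble(fi)
  if ("excluded" %in% names(fi_tab)) fi_tab <- fi_tab[!fi_tab$excluded, ]
  covs <- switch(model, crude = character(0), adjusted = covariates,
                 cell_adjusted = covariates)
  dat <- dplyr::inner_join(fi_tab[, c("id", "fi_score")],
                           tibble::as_tibble(cohort)[, unique(c("id", covs))],
                           by = "id")
  dat <- dat[dat$id %in% colnames(expr), ]
  if (model == "cell_adjusted") {
    if (is.null(cell_props)) abort("cell_adjusted model requires cell_props")
    cp <- cell_props[dat$id, c("monocytes", "lymphocytes"), drop = FALSE]
    dat$monocytes <- cp[, "monocytes"]; dat$lymphocytes <- cp[, "lymphocytes"]
    covs <- c(covs, "monocytes", "lymphocytes")
  }
  dat <- dat[complete.cases(dat), ]
  if (nrow(dat) < length(covs) + 3) {
    abort("too few aligned samples for the per-gene models")
  }
  Y <- t(expr[, dat$id, drop = FALSE])        # n x G
  X <- cbind(1, dat$fi_score)
  for (cv in covs) X <- cbind(X, dat[[cv]])
  colnames(X) <- c("(Intercept)", "fi_score", covs)
  fit <- fit_mass_lm(Y, X)
  beta <- fit$coef["fi_score", ]
  se <- fit$se["fi_score", ]
  p <- fit$p["fi_score", ]
  zero_var <- apply(Y, 2, function(v) var(v) == 0)
  p[zero_var] <- NA_real_
  if (any(zero_var)) {
    inform(paste0("genewise_fi_models: ", sum(zero_var),
                  " zero-variance gene(s); p set missing"))
  }
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- p.adjust(p[!is.na(p)], method = fdr_method)
  out <- tibble::tibble(gene = colnames(Y), beta = unname(beta),
                        se = unname(se), p = unname(p), q = unname(q),
                        neg_log10_p = -log10(unname(p)))
  structure(out, tier_counts = tier_counts(p), n_samples = nrow(dat),
            n_zero_variance = sum(zero_var), model = model,
            class = c("gene_assoc", class(out)))
}

#' Linear models of deconvolved cell-type proportions on the FI score
#'
#' For each cell type, fits the proportion as response with FI score as the
#' exposure, both crude and adjusted for the requested covariates, returning
#' a forest-plot-ready table.
#'
#' @param proportions Samples x cell-types matrix of proportions (rownames =
#'   subject ids), e.g. from [deconvolve()].
#' @param fi An `fi_result`; excluded subjects dropped.
#' @param cohort Cohort table supplying covariates.
#' @param covariates Adjustment set; default `c("age", "BMI")`.
#' @return Tibble: `cell_type`, `model` (`"crude"`/`"adjusted"`), `beta`,
#'   `ci_low`, `ci_high`, `p`, `n`, `degenerate` (constant proportion
#'   column).
#' @export
celltype_fi_models <- function(proportions, fi, cohort,
                               covariates = c("age", "BMI")) {
  stopifnot(is.matrix(proportions), !is.null(rownames(proportions)))
  fi_tab <- tibble::as_tibble(fi)
  if ("excluded" %in% names(fi_tab)) fi_tab <- fi_tab[!fi_tab$excluded, ]
  dat <- dplyr::inner_join(fi_tab[, c("id", "fi_score")],
                           tibble::as_tibble(cohort)[, c("id", covariates)],
                           by = "id")
  dat <- dat[dat$id %in% rownames(proportions), ]
  dat <- dat[complete.cases(dat), ]
  rows <- list()
  for (ct in colnames(proportions)) {
    y <- proportions[dat$id, ct]
    degen <- var(y) == 0
    for (mod in c("crude", "adjusted")) {
      if (degen) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          cell_type = ct, model = mod, beta = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, p = NA_real_, n = length(y), degenerate = TRUE)
        next
      }
      d <- cbind(dat, y = y)
      fml <- if (mod == "crude") y ~ fi_score else {
        as.formula(paste("y ~ fi_score +", paste(covariates, collapse = "+")))
      }
      fit <- lm(fml, data = d)
      sm <- summary(fit)$coefficients
      ci <- confint(fit)["fi_score", ]
      rows[[length(rows) + 1]] <- tibble::tibble(
        cell_type = ct, model = mod, beta = sm["fi_score", "Estimate"],
        ci_low = ci[1], ci_high = ci[2], p = sm["fi_score", "Pr(>|t|)"],
        n = nrow(d), degenerate = FALSE)
    }
  }
  dplyr::bind_rows(rows)
}
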