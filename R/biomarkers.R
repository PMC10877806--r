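#' Biomarker panel constants
#'
#' The six circulating inflammatory markers handled by the pipeline, with
#' their concentration units.
#'
#' @return Named character vector of units keyed by marker column name.
#' @export
biomarker_units <- function() {
  c(IL6 = "pg/ml", CRP = "mg/L", IGF1 = "ng/ml",
    cystatin_C = "ng/ml", cathepsin_S = "pg/ml", gp_acetyls = "mmol/L")
}

#' Transform policy for biomarker analyses
#'
#' Declares which markers are natural-log transformed before correlation /
#' regression (skewed acute-phase markers) and the CRP upper exclusion limit:
#' CRP values at or above the limit indicate acute infection rather than
#' chronic low-grade inflammation and are excluded from CRP analyses only.
#'
#' @param log_markers Markers to natural-log transform. Default: CRP, IL-6,
#'   cystatin C.
#' @param crp_limit CRP exclusion limit in mg/L (inclusive); default 50.
#' @return A `transform_policy` list.
#' @export
transform_policy <- function(log_markers = frailomics_defaults$log_markers,
                             crp_limit = frailomics_defaults$crp_limit) {
  if (!is.numeric(crp_limit) || crp_limit <= 0) {
    abort("crp_limit must be a positive number")
  }
  structure(list(log_markers = log_markers, crp_limit = crp_limit),
            class = "transform_policy")
}

#' Apply the transform policy to a biomarker panel
#'
#' CRP values at or above the exclusion limit are set missing (the subject's
#' other markers are untouched); the policy's markers are then natural-log
#' transformed. Non-positive values under the log are set missing with a
#' logged count (an assay floor signal), never an error.
#'
#' @param panel Data frame with an `id` column and marker columns (linear
#'   concentration scale).
#' @param policy A [transform_policy()].
#' @return The panel with policy markers on the natural-log scale. Attributes:
#'   `log_markers` (which columns are now ln-scale), `n_crp_excluded`,
#'   `n_nonpositive` (per-marker counts set missing under the log).
#' @export
apply_transform_policy <- function(panel, policy = transform_policy()) {
  stopifnot(is.data.frame(panel), inherits(policy, "transform_policy"))
  out <- tibble::as_tibble(panel)
  n_crp <- 0L
  if ("CRP" %in% names(out)) {
    drop <- !is.na(out$CRP) & out$CRP >= policy$crp_limit
    n_crp <- sum(drop)
    out$CRP[drop] <- NA_real_
    if (n_crp > 0) {
      inform(paste0("apply_transform_policy: ", n_crp, " CRP value(s) >= ",
                    policy$crp_limit, " mg/L set missing for CRP analyses"))
    }
  }
  n_nonpos <- integer(0)
  for (m in intersect(policy$log_markers, names(out))) {
    v <- out[[m]]
    bad <- !is.na(v) & v <= 0
    if (any(bad)) {
      n_nonpos[m] <- sum(bad)
      v[bad] <- NA_real_
    }
    out[[m]] <- log(v)
  }
  if (length(n_nonpos)) {
    inform(paste0("apply_transform_policy: non-positive values set missing ",
                  "before log: ",
                  paste(names(n_nonpos), n_nonpos, sep = "=", collapse = ", ")))
  }
  structure(out,
            log_markers = intersect(policy$log_markers, names(out)),
            n_crp_excluded = n_crp, n_nonpositive = n_nonpos)
}

#' Spearman correlation of FI with biomarkers, overall and by stratum
#'
#' Uses pairwise-complete observations per marker; a stratum with fewer than
#' three complete pairs is reported as not estimable. Because Spearman
#' correlation is rank-based it is invariant to the log transform, so it is
#' computed on whatever scale the panel is on.
#'
#' @param fi An `fi_result` (or data frame with `id` and `fi_score`).
#' @param panel Biomarker panel with `id` and marker columns.
#' @param markers Marker columns to correlate; default all panel columns
#'   except `id`.
#' @param strata Optional named list of logical vectors (aligned to the merged
#'   rows) or a column name in `panel` (e.g. `"sex"`) defining strata; the
#'   overall column is always reported.
#' @return Tibble with `marker`, `stratum`, `R`, `p`, `n`.
#' @export
spearman_assoc <- function(fi, panel, markers = NULL, strata = NULL) {
  stopifnot(is.data.frame(fi), "fi_score" %in% names(fi))
  dat <- dplyr::inner_join(
    tibble::as_tibble(fi)[, c("id", "fi_score")],
    tibble::as_tibble(panel), by = "id")
  if (is.null(markers)) {
    markers <- setdiff(names(panel), c("id", "sex"))
    markers <- markers[vapply(dat[markers], is.numeric, logical(1))]
  }
  groups <- list(overall = rep(TRUE, nrow(dat)))
  if (is.character(strata) && length(strata) == 1) {
    stopifnot(strata %in% names(dat))
    for (lev in sort(unique(stats::na.omit(dat[[strata]])))) {
      groups[[as.character(lev)]] <- !is.na(dat[[strata]]) & dat[[strata]] == lev
    }
  } else if (is.list(strata)) {
    groups <- c(groups, strata)
  }
  rows <- list()
  for (m in markers) {
    for (g in names(groups)) {
      sel <- groups[[g]]
      x <- dat$fi_score[sel]; y <- dat[[m]][sel]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          marker = m, stratum = g, R = NA_real_, p = NA_real_, n = sum(ok))
        next
      }
      ct <- suppressWarnings(
        cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      rows[[length(rows) + 1]] <- tibble::tibble(
        marker = m, stratum = g, R = unname(ct$estimate), p = ct$p.value,
        n = sum(ok))
    }
  }
  dplyr::bind_rows(rows)
}

#' Covariate-adjusted linear model of FI on a biomarker
#'
#' Ordinary least squares with the FI score as the dependent variable, the
#' (possibly ln-transformed) marker as the exposure, and the adjustment set
#' (default age, sex, BMI, smoking) as covariates, on listwise-complete rows.
#' When the marker is on the natural-log scale, the estimate and CI are
#' additionally reported multiplied by ln(1.1): the change in FI score per
#' 10% increase in the marker concentration.
#'
#' @param data Data frame containing `fi_score`, the marker column, and the
#'   covariate columns (merge of FI result, transformed panel, and cohort).
#' @param marker Name of the marker column.
#' @param covariates Character vector of covariate column names; default
#'   `c("age", "sex", "BMI", "smoking")`.
#' @param log_transformed Is the marker column on the natural-log scale? When
#'   `NULL` (default) this is read from the `log_markers` attribute left by
#'   [apply_transform_policy()] if present, else `FALSE`.
#' @return One-row tibble (two rows when back-transformed): `marker`,
#'   `estimate`, `ci_low`, `ci_high`, `p`, `n`, `adjustment`, `scale`
#'   (`"per unit"` on the fitted scale, plus `"per 10% increase"` for
#'   ln-markers).
#' @export
adjusted_linear_model <- function(data, marker,
                                  covariates = c("age", "sex", "BMI", "smoking"),
                                  log_transformed = NULL) {
  stopifnot(is.data.frame(data), marker %in% names(data),
            "fi_score" %in% names(data))
  miss_cov <- setdiff(covariates, names(data))
  if (length(miss_cov)) {
    abort(paste0("covariates not found: ", paste(miss_cov, collapse = ", ")))
  }
  if (is.null(log_transformed)) {
    log_transformed <- marker %in% (attr(data, "log_markers") %||% character(0))
  }
  cols <- c("fi_score", marker, covariates)
  cc <- data[complete.cases(data[, cols]), cols, drop = FALSE]
  p_par <- length(covariates) + 2  # intercept + marker + covariates
  if (nrow(cc) < p_par + 2) {
    abort(paste0("insufficient complete rows (", nrow(cc), ") for model on '",
                 marker, "'"))
  }
  # zero-variance / collinear columns fail loudly rather than silently drop
  X <- stats::model.matrix(
    as.formula(paste("~", paste(sprintf("`%s`", c(marker, covariates)),
                                collapse = " + "))), data = cc)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort(paste0("collinear or constant predictor(s): ",
                 paste(bad, collapse = ", ")))
  }
  fml <- as.formula(paste("fi_score ~",
                          paste(sprintf("`%s`", c(marker, covariates)),
                                collapse = " + ")))
  fit <- lm(fml, data = cc)
  sm <- summary(fit)$coefficients
  term <- rownames(sm)[2]  # marker is the first term after the intercept
  est <- sm[term, "Estimate"]; se <- sm[term, "Std. Error"]
  pval <- sm[term, "Pr(>|t|)"]
  tcrit <- qt(0.975, df = fit$df.residual)
  out <- tibble::tibble(
    marker = marker, estimate = est,
    ci_low = est - tcrit * se, ci_high = est + tcrit * se,
    p = pval, n = nrow(cc),
    adjustment = paste(covariates, collapse = "+"),
    scale = if (log_transformed) "per ln unit" else "per unit")
  if (log_transformed) {
    k <- log(1.1)
    out <- dplyr::bind_rows(out, dplyr::mutate(
      out, estimate = .data$estimate * k, ci_low = .data$ci_low * k,
      ci_high = .data$ci_high * k, scale = "per 10% increase"))
  }
  out
}

#' Run the adjusted model for every marker in a panel
#'
#' Convenience wrapper over [adjusted_linear_model()]: merges the FI result,
#' the (transformed) panel, and the cohort covariates, and returns one tidy
#' table across markers.
#'
#' @inheritParams adjusted_linear_model
#' @param fi An `fi_result`; excluded subjects are dropped.
#' @param panel Transformed biomarker panel (see [apply_transform_policy()]).
#' @param cohort Cohort table supplying the covariates.
#' @param markers Markers to model; default every non-id panel column.
#' @return Tibble of stacked [adjusted_linear_model()] rows.
#' @export
biomarker_associations <- function(fi, panel, cohort,
                                   covariates = c("age", "sex", "BMI", "smoking"),
                                   markers = NULL) {
  log_markers <- attr(panel, "log_markers") %||% character(0)
  dat <- tibble::as_tibble(fi)
  if ("excluded" %in% names(dat)) dat <- dat[!dat$excluded, ]
  dat <- dat[, c("id", "fi_score")] |>
    dplyr::inner_join(tibble::as_tibble(panel), by = "id") |>
    dplyr::inner_join(tibble::as_tibble(cohort)[, c("id", covariates)],
                      by = "id")
  if (is.null(markers)) markers <- setdiff(names(panel), "id")
  attr(dat, "log_markers") <- log_markers
  dplyr::bind_rows(lapply(markers, function(m) {
    adjusted_linear_model(dat, m, covariates = covariates)
  }))
}
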