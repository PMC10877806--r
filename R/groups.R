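is_normalish <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || sd(x) == 0) return(FALSE)
  if (length(x) > 5000) x <- sample(x, 5000)  # Shapiro-Wilk size limit
  shapiro.test(x)$p.value > alpha
}

fmt_mean_sd <- function(x, digits = 1) {
  sprintf("%.*f ± %.*f", digits, mean(x, na.rm = TRUE),
          digits, sd(x, na.rm = TRUE))
}

fmt_median_range <- function(x, digits = 1) {
  sprintf("%.*f (%.*f–%.*f)", digits, median(x, na.rm = TRUE),
          digits, min(x, na.rm = TRUE), digits, max(x, na.rm = TRUE))
}

fmt_n_pct <- function(x, level) {
  n <- sum(x == level, na.rm = TRUE)
  sprintf("%d (%.0f)", n, 100 * n / sum(!is.na(x)))
}

#' Compare a variable between two groups with automatic test selection
#'
#' Continuous variables use the independent-samples t-test when a
#' Shapiro-Wilk test accepts normality (alpha = 0.05) in both groups, and the
#' Mann-Whitney U test otherwise. Categorical variables use the Pearson
#' chi-square test, switching to Fisher's exact test when any expected cell
#' count is below 5. All tests are two-sided. Summaries follow the same
#' normality rule: mean +/- SD when normal, median (min-max) otherwise,
#' n (%) for categorical variables.
#'
#' @param data Data frame holding the variable and the grouping column.
#' @param variable Column to compare.
#' @param group Grouping column with exactly two non-missing levels (e.g. the
#'   `frail` flag, or sex).
#' @param type `"auto"` (default), `"continuous"` or `"categorical"`.
#' @param normal Optional logical overriding the Shapiro-Wilk decision for a
#'   continuous variable.
#' @return One-row tibble: `variable`, the two group labels and formatted
#'   summaries, `test` (`"t"`, `"mann-whitney"`, `"chi-square"`, `"fisher"`,
#'   or `"degenerate"`), and two-sided `p`.
#' @export
compare_groups <- function(data, variable, group, type = c("auto", "continuous",
                                                           "categorical"),
                           normal = NULL) {
  type <- match.arg(type)
  stopifnot(is.data.frame(data), variable %in% names(data),
            group %in% names(data))
  g <- data[[group]]; v <- data[[variable]]
  keep <- !is.na(g)
  g <- g[keep]; v <- v[keep]
  levs <- sort(unique(g))
  if (length(levs) != 2) abort("grouping column must have exactly two levels")
  x1 <- v[g == levs[1]]; x2 <- v[g == levs[2]]
  if (all(is.na(x1)) || all(is.na(x2))) abort("a group has no observations")
  if (type == "auto") {
    type <- if (is.numeric(v) && length(unique(stats::na.omit(v))) > 2) {
      "continuous"
    } else "categorical"
  }
  if (type == "continuous") {
    s1 <- x1[!is.na(x1)]; s2 <- x2[!is.na(x2)]
    if (sd(s1) == 0 && sd(s2) == 0) {
      return(tibble::tibble(
        variable = variable, group1 = as.character(levs[1]),
        group2 = as.character(levs[2]),
        summary1 = fmt_mean_sd(s1), summary2 = fmt_mean_sd(s2),
        test = "degenerate", p = NA_real_))
    }
    norm <- if (is.null(normal)) is_normalish(s1) && is_normalish(s2) else normal
    if (norm) {
      tt <- t.test(s1, s2)
      tibble::tibble(variable = variable, group1 = as.character(levs[1]),
                     group2 = as.character(levs[2]),
                     summary1 = fmt_mean_sd(s1), summary2 = fmt_mean_sd(s2),
                     test = "t", p = tt$p.value)
    } else {
      wt <- suppressWarnings(wilcox.test(s1, s2))
      tibble::tibble(variable = variable, group1 = as.character(levs[1]),
                     group2 = as.character(levs[2]),
                     summary1 = fmt_median_range(s1),
                     summary2 = fmt_median_range(s2),
                     test = "mann-whitney", p = wt$p.value)
    }
  } else {
    tab <- table(factor(g), factor(v))
    if (any(dim(tab) < 2)) {
      return(tibble::tibble(
        variable = variable, group1 = as.character(levs[1]),
        group2 = as.character(levs[2]),
        summary1 = NA_character_, summary2 = NA_character_,
        test = "degenerate", p = NA_real_))
    }
    expected <- suppressWarnings(chisq.test(tab, correct = FALSE))$expected
    lev_hi <- colnames(tab)[ncol(tab)]  # last level summarised, e.g. TRUE/yes
    if (any(expected < 5)) {
      ft <- fisher.test(tab)
      tibble::tibble(variable = variable, group1 = as.character(levs[1]),
                     group2 = as.character(levs[2]),
                     summary1 = fmt_n_pct(x1, lev_hi),
                     summary2 = fmt_n_pct(x2, lev_hi),
                     test = "fisher", p = ft$p.value)
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      tibble::tibble(variable = variable, group1 = as.character(levs[1]),
                     group2 = as.character(levs[2]),
                     summary1 = fmt_n_pct(x1, lev_hi),
                     summary2 = fmt_n_pct(x2, lev_hi),
                     test = "chi-square", p = ct$p.value)
    }
  }
}

#' Descriptive cohort summary by frailty group
#'
#' Builds a descriptive table comparing frail and non-frail subjects for the
#' requested variables, with formats and tests selected by the rules in
#' [compare_groups()] and an overall column.
#'
#' @param cohort Cohort table with `id` and the variables.
#' @param fi An `fi_result` supplying the `frail` flag (excluded subjects
#'   dropped).
#' @param variables Columns of `cohort` to summarise; defaults to every
#'   column except `id`.
#' @return Tibble: `variable`, `overall`, `frail`, `non_frail`, `test`, `p`.
#' @export
summarize_population <- function(cohort, fi, variables = NULL) {
  dat <- dplyr::inner_join(tibble::as_tibble(cohort),
                           tibble::as_tibble(fi)[!fi$excluded,
                                                 c("id", "fi_score", "frail")],
                           by = "id")
  if (is.null(variables)) variables <- setdiff(names(cohort), "id")
  rows <- lapply(variables, function(v) {
    cmp <- compare_groups(dat, v, "frail")
    x <- dat[[v]]
    overall <- if (is.numeric(x) && length(unique(stats::na.omit(x))) > 2) {
      if (is_normalish(x)) fmt_mean_sd(x) else fmt_median_range(x)
    } else {
      lev <- sort(unique(stats::na.omit(as.character(x))))
      fmt_n_pct(as.character(x), lev[length(lev)])
    }
    # compare_groups orders levels FALSE < TRUE: group2 is the frail column
    tibble::tibble(variable = v, overall = overall, frail = cmp$summary2,
                   non_frail = cmp$summary1, test = cmp$test, p = cmp$p)
  })
  dplyr::bind_rows(rows)
}

#' Render a tibble as a markdown pipe table
#'
#' @param df Data frame to render.
#' @param digits Significant digits for numeric columns.
#' @return Character scalar of markdown.
#' @export
render_markdown_table <- function(df, digits = 3) {
  cells <- vapply(df, function(col) {
    if (is.numeric(col)) as.character(signif(col, digits)) else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  cells <- matrix(as.character(cells), nrow = nrow(df))
  cells[is.na(cells)] <- ""
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}
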