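#' Compute the frailty index
#'
#' The frailty index (FI) for a subject is the sum of their coded deficit
#' values divided by the number of deficits actually measured for them, so a
#' subject with one missing deficit in a 38-deficit index is scored over 37.
#' Scores lie in \[0, 1\]. Subjects with fewer than `min_completeness` of the
#' deficits measured are flagged `excluded` and should not enter downstream
#' analyses; their score is still reported for transparency (unless zero
#' deficits were measured, in which case the score is `NA`).
#'
#' @param coded A `coded_deficit_matrix` from [encode_deficits()] (or any
#'   data frame with an `id` column and numeric deficit columns in \[0, 1\]).
#' @param min_completeness Minimum fraction of deficits that must be measured
#'   per subject; default 0.80 (i.e. subjects missing 20% or more of the
#'   deficits are excluded).
#' @param cutoff Frailty cutoff passed to [categorize_frailty()]; default 0.25.
#' @return An `fi_result` tibble: `id`, `fi_score`, `n_measured`,
#'   `deficit_sum`, `frail`, `excluded`. The cutoff and the number of
#'   deficits in the matrix are attached as attributes `cutoff` and
#'   `n_deficits`.
#' @export
#' @examples
#' coded <- tibble::tibble(id = "s1", !!!setNames(as.list(c(rep(1, 5),
#'   rep(0, 32), NA)), paste0("d", 1:38)))
#' class(coded) <- c("coded_deficit_matrix", class(coded))
#' compute_fi(coded)$fi_score  # 5 present, 37 measured -> 5/37
compute_fi <- function(coded, min_completeness = 0.80, cutoff = 0.25) {
  stopifnot(is.data.frame(coded), "id" %in% names(coded))
  if (!is.numeric(min_completeness) || min_completeness < 0 ||
      min_completeness > 1) {
    abort("min_completeness must lie in [0, 1]")
  }
  vals <- as.matrix(as.data.frame(coded)[, setdiff(names(coded), "id"),
                                         drop = FALSE])
  storage.mode(vals) <- "double"
  if (ncol(vals) == 0) abort("coded matrix has no deficit columns")
  if (any(!is.na(vals))) {
    rng <- range(vals, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) {
      abort("coded deficit values must lie in [0, 1]")
    }
  }
  n_deficits <- ncol(vals)
  n_measured <- rowSums(!is.na(vals))
  deficit_sum <- rowSums(vals, na.rm = TRUE)
  fi <- ifelse(n_measured > 0, deficit_sum / n_measured, NA_real_)
  excluded <- n_measured < min_completeness * n_deficits
  if (any(n_measured == 0)) {
    inform(paste0("compute_fi: ", sum(n_measured == 0),
                  " subject(s) with zero measured deficits excluded"))
  }
  res <- tibble::tibble(
    id = as.character(coded$id),
    fi_score = unname(fi),
    n_measured = unname(as.integer(n_measured)),
    deficit_sum = unname(deficit_sum),
    excluded = unname(excluded)
  )
  res <- categorize_frailty(res, cutoff = cutoff)
  attr(res, "n_deficits") <- n_deficits
  res
}

#' Label subjects frail / non-frail by an FI cutoff
#'
#' The cutoff is inclusive: a score exactly at the cutoff is labelled frail.
#'
#' @param fi An `fi_result` (or any data frame with an `fi_score` column).
#' @param cutoff FI cutoff in (0, 1); default 0.25.
#' @return `fi` with a logical `frail` column and attribute `cutoff`; frail
#'   and non-frail counts are attached as attribute `counts`.
#' @export
categorize_frailty <- function(fi, cutoff = 0.25) {
  stopifnot(is.data.frame(fi), "fi_score" %in% names(fi))
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= 1) {
    abort("cutoff must lie in (0, 1)")
  }
  ok <- !is.na(fi$fi_score)
  if (any(fi$fi_score[ok] < 0 | fi$fi_score[ok] > 1)) {
    abort("fi_score values must lie in [0, 1]")
  }
  fi$frail <- fi$fi_score >= cutoff
  out <- structure(fi, cutoff = cutoff,
                   counts = c(frail = sum(fi$frail, na.rm = TRUE),
                              non_frail = sum(!fi$frail, na.rm = TRUE)))
  if (!inherits(out, "fi_result")) class(out) <- c("fi_result", class(out))
  out
}

#' Write FI results to TSV
#'
#' Columns: `id`, `fi_score` (full precision), `n_measured`, `deficit_sum`,
#' `frail`.
#'
#' @param fi An `fi_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fi <- function(fi, path) {
  stopifnot(inherits(fi, "fi_result"))
  readr::write_tsv(fi[, c("id", "fi_score", "n_measured", "deficit_sum",
                          "frail")], path)
  invisible(path)
}
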