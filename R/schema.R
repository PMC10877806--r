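#' Deficit schema: load and validate
#'
#' A deficit schema declares, for each health deficit in the index, its name,
#' one of six category labels, the cohort column it is read from, and a coding
#' map from raw levels to values in \[0, 1\] (binary deficits map to 0/1,
#' graded deficits to intermediate values). The frailty index is defined
#' entirely by this document.
#'
#' @param path Path to a JSON or YAML schema file with top level
#'   `{version, deficits: [{name, category, source_variable, coding}]}`.
#' @return A `deficit_schema` object: a list with `version` and a tibble
#'   `deficits` (columns `name`, `category`, `source_variable`, and a
#'   list-column `coding` of named numeric vectors).
#' @details A warning (not an error) is emitted when the schema holds fewer
#'   than 30 deficits, the accepted lower bound for a stable
#'   deficit-accumulation index.
#' @export
#' @examples
#' sch <- load_schema(default_schema_path())
#' sch
load_schema <- function(path) {
  stopifnot(is.character(path), length(path) == 1)
  if (!file.exists(path)) abort(paste0("schema file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  new_deficit_schema(raw, source = path)
}

deficit_categories <- c(
  "Self-reported disease or condition",
  "General daily function",
  "Physical function and activity level",
  "Self-reported health",
  "Mood/State of mind",
  "Cognitive function (MMSE)"
)

new_deficit_schema <- function(raw, source = NULL) {
  if (is.null(raw$deficits) || length(raw$deficits) == 0) {
    abort("schema must declare at least one deficit")
  }
  defs <- lapply(raw$deficits, function(d) {
    for (fld in c("name", "category", "source_variable", "coding")) {
      if (is.null(d[[fld]])) {
        abort(paste0("deficit '", d$name %||% "<unnamed>",
                     "': missing field '", fld, "'"))
      }
    }
    coding <- unlist(d$coding)
    if (!is.numeric(coding) || length(coding) < 2) {
      abort(paste0("deficit '", d$name, "': coding must map >= 2 levels to numbers"))
    }
    if (any(coding < 0 | coding > 1)) {
      abort(paste0("deficit '", d$name, "': coded value outside [0, 1] (",
                   paste(coding[coding < 0 | coding > 1], collapse = ", "), ")"))
    }
    if (!d$category %in% deficit_categories) {
      abort(paste0("deficit '", d$name, "': unknown category label '",
                   d$category, "'"))
    }
    tibble::tibble(name = d$name, category = d$category,
                   source_variable = d$source_variable, coding = list(coding))
  })
  deficits <- dplyr::bind_rows(defs)
  if (anyDuplicated(deficits$name)) {
    dup <- unique(deficits$name[duplicated(deficits$name)])
    abort(paste0("duplicate deficit names: ", paste(dup, collapse = ", ")))
  }
  if (nrow(deficits) < 30) {
    warn(paste0("schema has only ", nrow(deficits),
                " deficits; at least 30-40 are recommended for a stable index"))
  }
  structure(
    list(version = raw$version %||% "unversioned", deficits = deficits,
         source = source),
    class = "deficit_schema"
  )
}

#' @export
print.deficit_schema <- function(x, ...) {
  cat("<deficit_schema> version:", x$version, "\n")
  cat(" ", nrow(x$deficits), "deficits in",
      length(unique(x$deficits$category)), "categories\n")
  tab <- table(x$deficits$category)
  for (nm in names(tab)) cat("   -", nm, ":", tab[[nm]], "\n")
  invisible(x)
}

#' Encode raw cohort variables as deficit values
#'
#' Maps each deficit's source column through its coding map, producing a
#' subjects x deficits grid of values in \[0, 1\]. Raw values that are missing
#' stay missing; raw levels absent from the coding map are, by default, set
#' missing with a logged count (set `unmapped = "error"` to fail instead).
#'
#' @param cohort A data frame with an `id` column and one column per
#'   `source_variable` in the schema.
#' @param schema A `deficit_schema`.
#' @param unmapped `"missing"` (default) or `"error"`: what to do with raw
#'   levels not present in a deficit's coding map.
#' @return A `coded_deficit_matrix`: tibble with `id` plus one numeric column
#'   per deficit, all values in \[0, 1\] or `NA`. The per-deficit count of
#'   unmapped levels is attached as attribute `"unmapped_counts"`.
#' @export
encode_deficits <- function(cohort, schema, unmapped = c("missing", "error")) {
  unmapped <- match.arg(unmapped)
  stopifnot(inherits(schema, "deficit_schema"), is.data.frame(cohort))
  if (!"id" %in% names(cohort)) abort("cohort table must have an 'id' column")
  missing_cols <- setdiff(schema$deficits$source_variable, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("cohort table lacks source columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  unmapped_counts <- integer(nrow(schema$deficits))
  names(unmapped_counts) <- schema$deficits$name
  out <- tibble::tibble(id = as.character(cohort$id))
  for (i in seq_len(nrow(schema$deficits))) {
    def <- schema$deficits[i, ]
    coding <- def$coding[[1]]
    raw <- as.character(cohort[[def$source_variable]])
    coded <- unname(coding[raw])          # NA for missing or unmapped
    n_unmapped <- sum(!is.na(raw) & !(raw %in% names(coding)))
    if (n_unmapped > 0) {
      if (unmapped == "error") {
        abort(paste0("deficit '", def$name, "': ", n_unmapped,
                     " raw value(s) absent from coding map"))
      }
      unmapped_counts[def$name] <- n_unmapped
    }
    out[[def$name]] <- coded
  }
  if (any(unmapped_counts > 0)) {
    inform(paste0("encode_deficits: ", sum(unmapped_counts),
                  " unmapped raw value(s) set missing across ",
                  sum(unmapped_counts > 0), " deficit(s)"))
  }
  structure(out, unmapped_counts = unmapped_counts,
            class = c("coded_deficit_matrix", class(out)))
}

#' Screen deficits by missingness (with advisory diagnostics)
#'
#' Removes deficits missing in at least `missing_threshold` of subjects (the
#' comparison is inclusive: a deficit missing in exactly 20% of a cohort is
#' excluded at the default threshold). Optional diagnostics — Spearman
#' correlation of each deficit with age (deficits should generally increase
#' with age) and near-saturated prevalence — are reported but never exclude a
#' deficit on their own.
#'
#' @param coded A `coded_deficit_matrix` from [encode_deficits()].
#' @param schema The `deficit_schema` the matrix was coded from.
#' @param missing_threshold Fraction in (0, 1]; default 0.20.
#' @param age Optional numeric vector of subject ages (same order as `coded`)
#'   enabling the age-association diagnostic.
#' @param saturation_limit Prevalence (mean coded value among measured
#'   subjects) above which a deficit is flagged as saturated; default 0.95.
#' @return A list with `schema` (retained deficits only) and `report`, a
#'   tibble with one row per deficit: `name`, `missing_frac`, `retained`,
#'   `reason`, and diagnostic columns `prevalence`, `saturated`,
#'   `age_spearman` (NA when `age` not supplied).
#' @export
screen_deficits <- function(coded, schema, missing_threshold = 0.20,
                            age = NULL, saturation_limit = 0.95) {
  stopifnot(inherits(coded, "coded_deficit_matrix"),
            inherits(schema, "deficit_schema"))
  if (!is.numeric(missing_threshold) || missing_threshold <= 0 ||
      missing_threshold > 1) {
    abort("missing_threshold must lie in (0, 1]")
  }
  vals <- as.data.frame(coded[, schema$deficits$name, drop = FALSE])
  n <- nrow(vals)
  if (n == 0) abort("coded matrix has no subjects")
  miss <- vapply(vals, function(v) mean(is.na(v)), numeric(1))
  prev <- vapply(vals, function(v) {
    m <- mean(v, na.rm = TRUE)
    if (is.nan(m)) NA_real_ else m
  }, numeric(1))
  age_rho <- rep(NA_real_, length(miss))
  if (!is.null(age)) {
    stopifnot(length(age) == n)
    age_rho <- vapply(vals, function(v) {
      ok <- !is.na(v) & !is.na(age)
      if (sum(ok) < 3 || sd(v[ok]) == 0) return(NA_real_)
      suppressWarnings(cor(v[ok], age[ok], method = "spearman"))
    }, numeric(1))
  }
  retained <- miss < missing_threshold
  report <- tibble::tibble(
    name = schema$deficits$name,
    missing_frac = unname(miss),
    retained = unname(retained),
    reason = ifelse(retained, NA_character_,
                    sprintf("missing in %.1f%% of subjects (>= %.0f%%)",
                            100 * miss, 100 * missing_threshold)),
    prevalence = unname(prev),
    saturated = unname(!is.na(prev) & prev > saturation_limit),
    age_spearman = unname(age_rho)
  )
  kept <- schema
  kept$deficits <- schema$deficits[retained, , drop = FALSE]
  if (!all(retained)) {
    inform(paste0("screen_deficits: excluded ", sum(!retained),
                  " deficit(s) for missingness >= ",
                  missing_threshold, ": ",
                  paste(report$name[!retained], collapse = ", ")))
  }
  list(schema = kept, report = report)
}
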