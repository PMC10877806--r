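#' Read a cohort table from CSV/TSV
#'
#' One row per subject; a mandatory `id` column; empty strings and `"NA"`
#' are treated as missing. The delimiter is taken from the file extension
#' (`.csv` vs anything else = tab).
#'
#' @param path File path.
#' @param col_types Optional readr column specification.
#' @return Tibble with a character `id` column.
#' @export
read_cohort <- function(path, col_types = NULL) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  reader <- if (tolower(tools::file_ext(path)) == "csv") {
    readr::read_csv
  } else readr::read_tsv
  df <- reader(path, na = c("", "NA"), show_col_types = FALSE,
               col_types = col_types)
  if (!"id" %in% names(df)) abort("cohort file lacks an 'id' column")
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    dup <- unique(df$id[duplicated(df$id)])
    abort(paste0("duplicate subject id(s): ", paste(dup, collapse = ", ")))
  }
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(paste0("type coercion failed at row(s) ",
                 paste(unique(prob$row), collapse = ", "), " of ", path))
  }
  df
}

#' Write a deficit schema to JSON
#'
#' @param schema A `deficit_schema`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "deficit_schema"))
  defs <- lapply(seq_len(nrow(schema$deficits)), function(i) {
    d <- schema$deficits[i, ]
    list(name = d$name, category = d$category,
         source_variable = d$source_variable,
         coding = as.list(d$coding[[1]]))
  })
  jsonlite::write_json(list(version = schema$version, deficits = defs),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a full synthetic-study fixture set to a directory
#'
#' Writes the cohort table (demographics + raw deficits + biomarkers, TSV),
#' the schema (JSON), the expression and signature matrices (TSV), and the
#' ground truth (JSON) produced by [simulate_study()].
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_study_fixtures <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    cohort = file.path(dir, "cohort.tsv"),
    schema = file.path(dir, "schema.json"),
    expression = file.path(dir, "expression.tsv"),
    signature = file.path(dir, "signature.tsv"),
    truth = file.path(dir, "truth.json"))
  cohort_full <- dplyr::left_join(study$cohort, study$panel, by = "id")
  readr::write_tsv(cohort_full, paths["cohort"])
  write_schema(study$schema, paths["schema"])
  write_matrix_tsv(study$expr, paths["expression"], id_col = "gene")
  write_matrix_tsv(study$signature, paths["signature"], id_col = "gene")
  jsonlite::write_json(
    list(latent = study$truth$latent,
         biomarkers = study$truth$biomarkers,
         planted_genes = study$truth$planted_genes,
         monocyte_fi_slope = study$truth$monocyte_fi_slope,
         seed = study$config$seed),
    paths["truth"], digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
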