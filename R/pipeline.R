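#' Pipeline configuration
#'
#' Collects the file paths, thresholds and adjustment sets that drive
#' [run_pipeline()]. Thresholds are validated against their documented
#' ranges. A config can also be read from a YAML or JSON file with the same
#' field names via `pipeline_config_from_file()`.
#'
#' @param cohort Path to the cohort CSV/TSV (demographics, raw deficits,
#'   biomarkers).
#' @param schema Path to the deficit schema (JSON/YAML); default the
#'   packaged replica.
#' @param out_dir Output directory.
#' @param expression,signature Optional paths to the expression matrix and
#'   the cell-type signature (TSV); both required for the transcriptome
#'   stage.
#' @param probe_map Optional path to a two-column TSV (`probe`, `gene`) for
#'   probe collapse; omit when the matrix is already one row per gene.
#' @param missing_threshold,frailty_cutoff,crp_limit,fdr_level,top_k
#'   Analysis thresholds (defaults 0.20, 0.25, 50 mg/L, 0.05, 30).
#' @param covariates_fi Adjustment set for the biomarker models; default
#'   age, sex, BMI, smoking.
#' @param covariates_expr Adjustment set for the transcriptome models;
#'   default age, BMI (the expression subgroup is single-sex, so sex is not
#'   adjusted for by default).
#' @param seed Seed recorded in the manifest and used for any sampling.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort, schema = default_schema_path(), out_dir,
                            expression = NULL, signature = NULL,
                            probe_map = NULL,
                            missing_threshold = 0.20, frailty_cutoff = 0.25,
                            crp_limit = 50, fdr_level = 0.05, top_k = 30,
                            covariates_fi = c("age", "sex", "BMI", "smoking"),
                            covariates_expr = c("age", "BMI"), seed = 1L) {
  if (missing_threshold <= 0 || missing_threshold > 1) {
    abort("missing_threshold must lie in (0, 1]")
  }
  if (frailty_cutoff <= 0 || frailty_cutoff >= 1) {
    abort("frailty_cutoff must lie in (0, 1)")
  }
  if (crp_limit <= 0) abort("crp_limit must be positive")
  if (fdr_level <= 0 || fdr_level >= 1) abort("fdr_level must lie in (0, 1)")
  if (top_k < 1) abort("top_k must be >= 1")
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML or JSON config file.
#' @export
pipeline_config_from_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path) else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Chains the stages end to end: load schema, encode and screen deficits,
#' compute the FI and frailty labels, run the biomarker stage (transform
#' policy, Spearman correlations overall and by sex, descriptive table,
#' adjusted models with per-10% back-transformation), and — when expression
#' inputs are configured — the transcriptome stage (optional probe collapse,
#' quantile normalization, per-gene FI models, deconvolution, cell-type
#' models, top marker genes, marker x biomarker matrix). All stage outputs
#' are written as TSV into `out_dir` together with a JSON run manifest
#' (package version, seed, thresholds, input digests, record counts).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and `files`,
#'   the paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  out_file <- function(name) file.path(config$out_dir, name)
  files <- character(0)

  inform("[stage 1/3] frailty index")
  cohort <- read_cohort(config$cohort)
  schema <- load_schema(config$schema)
  coded <- encode_deficits(cohort, schema)
  age <- if ("age" %in% names(cohort)) cohort$age else NULL
  scr <- screen_deficits(coded, schema,
                         missing_threshold = config$missing_threshold,
                         age = age)
  coded_kept <- coded[, c("id", scr$schema$deficits$name)]
  class(coded_kept) <- class(coded)
  fi <- compute_fi(coded_kept, cutoff = config$frailty_cutoff)
  readr::write_tsv(scr$report, out_file("screening_report.tsv"))
  write_fi(fi, out_file("fi_scores.tsv"))
  files <- c(files, out_file("screening_report.tsv"), out_file("fi_scores.tsv"))

  inform("[stage 2/3] biomarker associations")
  markers <- intersect(names(biomarker_units()), names(cohort))
  results <- list(fi = fi, screening = scr$report)
  if (length(markers) > 0) {
    panel <- cohort[, c("id", markers)]
    tpanel <- apply_transform_policy(
      panel, transform_policy(crp_limit = config$crp_limit))
    fi_ok <- fi[!fi$excluded, ]
    corr <- spearman_assoc(
      fi_ok, dplyr::left_join(tpanel, cohort[, c("id", "sex")], by = "id"),
      markers = markers,
      strata = if ("sex" %in% names(cohort)) "sex" else NULL)
    assoc <- biomarker_associations(fi, tpanel, cohort,
                                    covariates = config$covariates_fi)
    desc_vars <- intersect(c("age", "sex", "BMI", "smoking", "living_alone"),
                           names(cohort))
    desc <- summarize_population(
      cohort[, c("id", desc_vars)], fi, variables = desc_vars)
    readr::write_tsv(corr, out_file("spearman_correlations.tsv"))
    readr::write_tsv(assoc, out_file("adjusted_models.tsv"))
    readr::write_tsv(desc, out_file("descriptive_table.tsv"))
    writeLines(render_markdown_table(desc), out_file("descriptive_table.md"))
    files <- c(files, out_file("spearman_correlations.tsv"),
               out_file("adjusted_models.tsv"),
               out_file("descriptive_table.tsv"),
               out_file("descriptive_table.md"))
    results <- c(results, list(correlations = corr, associations = assoc,
                               descriptives = desc, panel = tpanel))
  }

  if (!is.null(config$expression)) {
    inform("[stage 3/3] transcriptome associations")
    expr <- read_expression(config$expression)
    if (!is.null(config$probe_map)) {
      pm <- readr::read_tsv(config$probe_map, show_col_types = FALSE)
      expr <- collapse_probes_max_iqr(expr, pm)
    }
    expr <- quantile_normalize(expr)
    gw <- genewise_fi_models(expr, fi, cohort,
                             covariates = config$covariates_expr)
    readr::write_tsv(gw, out_file("genewise_models.tsv"))
    files <- c(files, out_file("genewise_models.tsv"))
    results$genewise <- gw
    if (!is.null(config$signature)) {
      sig <- read_expression(config$signature)
      dec <- deconvolve(expr, sig)
      ct <- celltype_fi_models(dec$proportions, fi, cohort,
                               covariates = config$covariates_expr)
      top <- select_top_marker_genes(expr, dec$proportions[, "monocytes"],
                                     k = config$top_k)
      markers_panel <- cohort[, c("id", markers)]
      tpanel2 <- apply_transform_policy(
        markers_panel, transform_policy(crp_limit = config$crp_limit))
      mm <- marker_biomarker_matrix(expr[top$gene, , drop = FALSE], tpanel2,
                                    cohort, covariates = config$covariates_expr)
      write_matrix_tsv(dec$proportions, out_file("cell_proportions.tsv"),
                       id_col = "id")
      readr::write_tsv(ct, out_file("celltype_models.tsv"))
      readr::write_tsv(top, out_file("top_marker_genes.tsv"))
      write_matrix_tsv(mm$beta[mm$row_order, mm$col_order, drop = FALSE],
                       out_file("marker_biomarker_beta.tsv"), id_col = "gene")
      files <- c(files, out_file("cell_proportions.tsv"),
                 out_file("celltype_models.tsv"),
                 out_file("top_marker_genes.tsv"),
                 out_file("marker_biomarker_beta.tsv"))
      results <- c(results, list(deconvolution = dec, celltype_models = ct,
                                 top_markers = top, marker_matrix = mm))
    }
  }

  inputs <- c(cohort = config$cohort, schema = config$schema,
              expression = config$expression %||% NA,
              signature = config$signature %||% NA)
  inputs <- inputs[!is.na(inputs)]
  manifest <- list(
    package = "frailomics",
    version = as.character(utils::packageVersion("frailomics")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    thresholds = list(missing_threshold = config$missing_threshold,
                      frailty_cutoff = config$frailty_cutoff,
                      crp_limit = config$crp_limit,
                      fdr_level = config$fdr_level, top_k = config$top_k),
    input_md5 = as.list(tools::md5sum(unname(inputs))),
    counts = list(
      subjects = nrow(cohort),
      subjects_excluded = sum(fi$excluded),
      deficits_retained = nrow(scr$schema$deficits),
      deficits_excluded = sum(!scr$report$retained),
      frail = sum(fi$frail[!fi$excluded], na.rm = TRUE)))
  jsonlite::write_json(manifest, out_file("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, out_file("run_manifest.json"))
  results$manifest <- manifest
  results$files <- files
  invisible(results)
}
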