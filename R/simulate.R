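#' Simulation configuration for synthetic cohorts
#'
#' Bundles and validates every parameter of the synthetic-cohort generator.
#' Defaults emulate a home-dwelling elderly cohort: about 400 subjects aged
#' 70-93 (median near 74), 52% women, BMI around 26.2 +/- 3.9 kg/m2, 6%
#' daily smokers; a latent frailty construct (Beta-distributed, mean rising
#' with age, population mean FI near 0.15); 38 graded deficits; six
#' log-normal inflammatory biomarkers whose levels rise with latent frailty
#' (IGF-1 with a null-to-negative slope); and a bulk PBMC expression matrix
#' generated as signature x mixing proportions with multiplicative noise, in
#' which the monocyte proportion increases with the FI score and 50 planted
#' monocyte-specific genes track it. The latent construct is a test harness,
#' not a claim about biology.
#'
#' @param n_subjects Cohort size; default 400.
#' @param seed Integer seed; mandatory for reproducible runs (may be `NULL`
#'   to use the current RNG stream).
#' @param n_expression_samples Size of the expression subgroup (women only,
#'   mirroring a typical transcriptomics subset); default 89.
#' @param age_min,age_max Age range; default 70-93.
#' @param age_median_offset Exponential median (years above `age_min`) of the
#'   age distribution; default 4 (median age 74).
#' @param sex_female_p Proportion women; default 0.52.
#' @param bmi_mean,bmi_sd BMI distribution; default 26.2, 3.9.
#' @param smoking_p Daily-smoking probability; default 0.06.
#' @param living_alone_base Baseline probability of living alone; default 0.3.
#' @param latent_base_mean Latent frailty mean at `age_min`; default 0.127
#'   (with the age slope this places the population mean FI near 0.15).
#' @param latent_age_slope Increase in latent mean per year of age; 0.004.
#' @param latent_concentration Beta concentration of the latent draw; 30.
#' @param deficit_steepness Logistic steepness linking latent frailty to
#'   deficit presence probability (1 = identity on the probability scale).
#' @param missing_rate Completely-at-random missingness rate injected into
#'   the raw deficit variables; default 0.02.
#' @param biomarker_params Data frame with columns `marker`, `intercept`
#'   (ln concentration at latent frailty 0), `beta` (slope of ln marker on
#'   latent frailty), `sd` (log-scale noise); defaults land medians and
#'   rank correlations near published inflammageing scales.
#' @param n_genes,n_planted Number of genes and of planted monocyte-specific
#'   genes; defaults 5000, 50.
#' @param cell_types,baseline_props Cell types and their baseline mixing
#'   proportions (simplex).
#' @param monocyte_fi_slope Slope of the monocyte proportion on the FI
#'   score; default 0.25.
#' @param prop_noise_sd SD of the noise on the monocyte proportion; 0.03.
#' @param expr_noise_sd SD of multiplicative log-normal expression noise;
#'   0.05.
#' @param planted_monocyte_level,planted_background_level Linear-scale
#'   signature expression of planted genes in monocytes vs other types.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 400, seed = NULL,
                       n_expression_samples = 89,
                       age_min = 70, age_max = 93, age_median_offset = 4,
                       sex_female_p = 0.52, bmi_mean = 26.2, bmi_sd = 3.9,
                       smoking_p = 0.06, living_alone_base = 0.3,
                       latent_base_mean = 0.127, latent_age_slope = 0.004,
                       latent_concentration = 30, deficit_steepness = 1,
                       missing_rate = 0.02,
                       biomarker_params = default_biomarker_params(),
                       n_genes = 5000, n_planted = 50,
                       cell_types = c("monocytes", "T_CD4", "T_CD8",
                                      "B_cells", "NK_cells"),
                       baseline_props = c(0.20, 0.35, 0.20, 0.12, 0.13),
                       monocyte_fi_slope = 0.25, prop_noise_sd = 0.03,
                       expr_noise_sd = 0.05,
                       planted_monocyte_level = 500,
                       planted_background_level = 5) {
  stopifnot(n_subjects >= 1, n_genes >= 1, n_planted >= 0,
            n_planted <= n_genes, age_min < age_max,
            length(cell_types) == length(baseline_props))
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("missing_rate must lie in [0, 1)")
  }
  if (any(biomarker_params$sd < 0)) abort("biomarker noise SDs must be >= 0")
  if (abs(sum(baseline_props) - 1) > 1e-8 || any(baseline_props <= 0)) {
    abort("baseline_props must be positive and sum to 1")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Default biomarker simulation parameters
#'
#' Slopes of ln(concentration) on latent frailty and log-scale noise SDs,
#' with intercepts placing the simulated medians near typical elderly-cohort
#' values (IL-6 ~1.4 pg/ml, CRP ~1.5 mg/L, IGF-1 ~86 ng/ml, cystatin C
#' ~780 ng/ml, cathepsin S ~8000 pg/ml, Gp-acetyls ~1.26 mmol/L). IGF-1
#' carries a negative slope (its frailty association is null to negative).
#'
#' @return Tibble with columns `marker`, `intercept`, `beta`, `sd`.
#' @export
default_biomarker_params <- function() {
  tibble::tribble(
    ~marker,        ~intercept, ~beta,  ~sd,
    "CRP",          log(1.5),    1.8,  0.85,
    "IL6",          log(1.4),    2.0,  0.45,
    "IGF1",         log(86),    -0.3,  0.28,
    "cystatin_C",   log(780),    1.3,  0.20,
    "cathepsin_S",  log(8000),   0.8,  0.24,
    "gp_acetyls",   log(1.26),   0.45, 0.13
  )
}

#' Simulate a cohort table with a latent frailty construct
#'
#' Draws demographics (age with median near 74 truncated to the configured
#' range, sex, BMI, smoking, living alone) and a per-subject latent frailty
#' value from a Beta distribution whose mean increases with age. Living
#' alone is made more likely at higher latent frailty. Fully deterministic
#' under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List: `cohort` (tibble `id`, `age`, `sex`, `BMI`, `smoking`,
#'   `living_alone`) and `truth` (list with `latent`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  age <- config$age_min +
    pmin(rexp(n, rate = log(2) / config$age_median_offset),
         config$age_max - config$age_min)
  age <- round(age)
  sex <- ifelse(runif(n) < config$sex_female_p, "female", "male")
  bmi <- pmax(rnorm(n, config$bmi_mean, config$bmi_sd), 15)
  smoking <- as.integer(runif(n) < config$smoking_p)
  mu <- pmin(pmax(config$latent_base_mean +
                    config$latent_age_slope * (age - config$age_min),
                  0.01), 0.95)
  k <- config$latent_concentration
  latent <- rbeta(n, mu * k, (1 - mu) * k)
  living_alone <- as.integer(
    runif(n) < plogis(qlogis(config$living_alone_base) + 2 * (latent - mean(latent))))
  cohort <- tibble::tibble(
    id = sprintf("S%04d", seq_len(n)), age = age, sex = sex, BMI = bmi,
    smoking = smoking, living_alone = living_alone)
  list(cohort = cohort, truth = list(latent = latent))
}

#' Simulate raw deficit variables for a schema
#'
#' For each deficit, the coded levels are ordered by severity and a level is
#' drawn as Binomial(k - 1, p) over them, where p is a logistic-steepness
#' transform of the subject's latent frailty (steepness 1 reproduces the
#' latent value as the presence probability, so the expected FI equals the
#' expected latent frailty). Missingness is injected completely at random.
#'
#' @param latent Numeric vector of latent frailty values in (0, 1).
#' @param schema A `deficit_schema` whose coding maps supply the raw levels.
#' @param config A [sim_config()] (steepness and missingness rate).
#' @return Tibble of raw character columns, one per deficit source variable.
#' @export
simulate_deficits <- function(latent, schema, config = sim_config()) {
  stopifnot(inherits(schema, "deficit_schema"), all(latent > 0 & latent < 1))
  if (config$missing_rate < 0 || config$missing_rate >= 1) {
    abort("missing_rate must lie in [0, 1)")
  }
  n <- length(latent)
  s <- config$deficit_steepness
  p <- plogis(s * qlogis(latent))
  out <- tibble::tibble(.rows = n)
  for (i in seq_len(nrow(schema$deficits))) {
    def <- schema$deficits[i, ]
    coding <- sort(def$coding[[1]])            # levels ordered by severity
    k <- length(coding)
    idx <- rbinom(n, size = k - 1, prob = p) + 1
    raw <- names(coding)[idx]
    if (config$missing_rate > 0) {
      raw[runif(n) < config$missing_rate] <- NA_character_
    }
    out[[def$source_variable]] <- raw
  }
  out
}

#' Simulate the six-biomarker inflammation panel
#'
#' ln(concentration) = intercept + beta x latent frailty + Gaussian noise,
#' exponentiated to the concentration scale, per marker.
#'
#' @param latent Latent frailty vector.
#' @param config A [sim_config()]; `config$biomarker_params` must cover all
#'   six markers.
#' @param ids Subject ids for the panel's `id` column.
#' @return List: `panel` (tibble `id` + marker columns, linear scale) and
#'   `truth` (the parameter table used).
#' @export
simulate_biomarkers <- function(latent, config = sim_config(),
                                ids = sprintf("S%04d", seq_along(latent))) {
  bp <- config$biomarker_params
  if (any(bp$sd < 0)) abort("biomarker noise SDs must be >= 0")
  panel <- tibble::tibble(id = ids)
  for (i in seq_len(nrow(bp))) {
    lnval <- bp$intercept[i] + bp$beta[i] * latent +
      rnorm(length(latent), 0, bp$sd[i])
    panel[[bp$marker[i]]] <- exp(lnval)
  }
  list(panel = panel, truth = bp)
}

# Dirichlet draw via independent gammas.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Simulate a bulk PBMC expression matrix with known cell mixing
#'
#' Generates per-sample cell-type proportions with the monocyte fraction
#' increasing in the FI score (baseline + slope x FI + noise, clipped and
#' renormalized; the remaining mass is split over the other cell types by a
#' Dirichlet draw around their baselines), a nonnegative signature matrix
#' in which the planted genes are strongly monocyte-specific, and the bulk
#' matrix signature x proportions with multiplicative log-normal noise,
#' returned on the log2 scale.
#'
#' @param fi_scores Named numeric vector of FI scores (names = subject ids)
#'   for the samples to simulate.
#' @param config A [sim_config()].
#' @return List: `expr` (genes x samples, log2), `signature` (genes x cell
#'   types, linear scale, the planted + a marker subset of background genes),
#'   `proportions` (samples x cell types, true mixing), `planted_genes`,
#'   `truth` (slope used).
#' @export
simulate_expression <- function(fi_scores, config = sim_config()) {
  stopifnot(!is.null(names(fi_scores)), all(is.finite(fi_scores)))
  n <- length(fi_scores)
  G <- config$n_genes
  types <- config$cell_types
  Tn <- length(types)
  base <- config$baseline_props
  names(base) <- types

  mono <- base["monocytes"] + config$monocyte_fi_slope * fi_scores +
    rnorm(n, 0, config$prop_noise_sd)
  clipped <- mono < 0.01 | mono > 0.90
  if (any(mono < 0)) {
    warn(paste0("simulate_expression: ", sum(mono < 0),
                " negative monocyte proportion(s) clipped and renormalized"))
  }
  mono <- pmin(pmax(mono, 0.01), 0.90)
  others <- setdiff(types, "monocytes")
  P <- matrix(0, n, Tn, dimnames = list(names(fi_scores), types))
  P[, "monocytes"] <- mono
  alpha_oth <- 50 * base[others] / sum(base[others])
  for (i in seq_len(n)) {
    P[i, others] <- (1 - mono[i]) * rdirichlet1(alpha_oth)
  }

  gene_ids <- sprintf("G%05d", seq_len(G))
  planted <- if (config$n_planted > 0) gene_ids[seq_len(config$n_planted)] else character(0)
  # background genes: independent log-normal loadings per cell type
  S <- matrix(exp(rnorm(G * Tn, mean = log(50), sd = 1)), G, Tn,
              dimnames = list(gene_ids, types))
  if (length(planted)) {
    S[planted, ] <- config$planted_background_level
    S[planted, "monocytes"] <- config$planted_monocyte_level
  }
  E <- S %*% t(P)                                       # genes x samples
  E <- E * exp(matrix(rnorm(G * n, 0, config$expr_noise_sd), G, n))
  expr <- log2(E)
  colnames(expr) <- names(fi_scores)
  list(expr = expr, signature = S, proportions = P, planted_genes = planted,
       truth = list(monocyte_fi_slope = config$monocyte_fi_slope,
                    clipped = sum(clipped)))
}

#' Simulate a full synthetic study with ground truth
#'
#' Chains the generator stages under one seed: cohort and latent frailty,
#' raw deficits for the packaged replica schema, the biomarker panel, the FI
#' computed through the package pipeline, and an expression matrix for a
#' women-only subgroup whose monocyte fraction tracks the computed FI.
#'
#' @param config A [sim_config()].
#' @param schema Deficit schema; default the packaged 38-deficit replica.
#' @return List: `cohort` (demographics + raw deficit columns), `schema`,
#'   `panel`, `fi`, `expr`, `signature`, `truth` (latent frailty, biomarker
#'   parameters, true proportions, planted genes, monocyte-FI slope),
#'   `config`.
#' @export
simulate_study <- function(config = sim_config(seed = 1),
                           schema = load_schema(default_schema_path())) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg_noseed <- config
  cfg_noseed$seed <- NULL
  cs <- simulate_cohort(cfg_noseed)
  cohort <- cs$cohort
  latent <- cs$truth$latent
  deficits <- simulate_deficits(latent, schema, cfg_noseed)
  cohort <- dplyr::bind_cols(cohort, deficits)
  bm <- simulate_biomarkers(latent, cfg_noseed, ids = cohort$id)
  coded <- encode_deficits(cohort, schema)
  fi <- compute_fi(coded)
  women <- cohort$id[cohort$sex == "female" & !fi$excluded]
  n_expr <- min(config$n_expression_samples, length(women))
  sub <- sample(women, n_expr)
  fsub <- setNames(fi$fi_score[match(sub, fi$id)], sub)
  ex <- simulate_expression(fsub, cfg_noseed)
  list(cohort = cohort, schema = schema, panel = bm$panel, fi = fi,
       expr = ex$expr, signature = ex$signature,
       truth = list(latent = latent, biomarkers = bm$truth,
                    proportions = ex$proportions,
                    planted_genes = ex$planted_genes,
                    monocyte_fi_slope = config$monocyte_fi_slope),
       config = config)
}

#' Generate data under the adjusted regression model (recovery harness)
#'
#' Draws covariates and a log-normal marker, then generates the FI score
#' directly from the linear model that [adjusted_linear_model()] fits:
#' FI = intercept + beta x ln(marker) + covariate effects + Gaussian noise.
#' Because the generating model and the fitted model coincide, `beta` is the
#' exact estimand, which is what calibration and coverage experiments need.
#' Scores are not clamped to \[0, 1\] (clamping would bias the estimand);
#' with the default effect sizes they rarely leave it.
#'
#' @param n Sample size; default 400.
#' @param beta True coefficient of FI on ln(marker); default 0.02.
#' @param intercept Model intercept; default 0.05.
#' @param gamma Named covariate effects (`age`, `sex`, `BMI`, `smoking`).
#' @param noise_sd Residual SD of the FI score; default 0.05.
#' @param lnm_mean,lnm_sd Distribution of ln(marker); defaults 0.4, 0.9.
#' @param seed Optional seed.
#' @return List: `data` (tibble with `fi_score`, `ln_marker`, covariates)
#'   and `truth`.
#' @export
simulate_regression_truth <- function(n = 400, beta = 0.02, intercept = 0.05,
                                      gamma = c(age = 0.003, sex = 0.01,
                                                BMI = 0.002, smoking = 0.02),
                                      noise_sd = 0.05,
                                      lnm_mean = 0.4, lnm_sd = 0.9,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  age <- runif(n, 70, 93)
  sex <- as.integer(runif(n) < 0.52)
  bmi <- rnorm(n, 26.2, 3.9)
  smoking <- as.integer(runif(n) < 0.06)
  ln_marker <- rnorm(n, lnm_mean, lnm_sd)
  fi <- intercept + beta * ln_marker + gamma["age"] * (age - 70) +
    gamma["sex"] * sex + gamma["BMI"] * (bmi - 26.2) +
    gamma["smoking"] * smoking + rnorm(n, 0, noise_sd)
  list(data = tibble::tibble(fi_score = fi, ln_marker = ln_marker, age = age,
                             sex = sex, BMI = bmi, smoking = smoking),
       truth = list(beta = beta, intercept = intercept, gamma = gamma,
                    noise_sd = noise_sd))
}
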