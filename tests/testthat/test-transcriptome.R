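test_that("quantile normalization maps columns to rank means and is idempotent", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "b"]), c(2.5, 3.5, 4.5))

  same <- cbind(x = c(3, 1, 7), y = c(3, 1, 7))
  expect_equal(quantile_normalize(same), same)

  set.seed(31)
  big <- matrix(rnorm(200 * 8), 200, 8,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:8)))
  qn2 <- quantile_normalize(big)
  sorted <- apply(qn2, 2, sort)
  for (j in 2:ncol(sorted)) expect_equal(sorted[, j], sorted[, 1])
  # ranks within each sample preserved
  for (j in 1:ncol(big)) expect_equal(order(qn2[, j]), order(big[, j]))
  expect_error(quantile_normalize(big[, 1, drop = FALSE]), ">= 2 samples")
  big[1, 1] <- NA
  expect_error(quantile_normalize(big), "missing")
})

test_that("ties receive the mean of the corresponding reference quantiles", {
  m <- cbind(a = c(1, 1, 5), b = c(2, 4, 6))
  qn <- quantile_normalize(m)
  ref <- (sort(m[, 1]) + sort(m[, 2])) / 2  # 1.5, 2.5, 5.5
  expect_equal(unname(qn[, "a"]), c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
  expect_equal(unname(qn[, "b"]), ref)
})

test_that("probe collapse keeps the max-IQR probe with lexicographic ties", {
  samples <- paste0("s", 1:8)
  m <- rbind(
    p_wide = c(0, 10, 0, 10, 0, 10, 0, 10),  # IQR 10
    p_flat = c(5, 5, 5, 5, 5, 6, 4, 5),      # small IQR
    p_only = rnorm(8),
    tie_b  = c(1, 2, 3, 4, 5, 6, 7, 8),
    tie_a  = c(8, 7, 6, 5, 4, 3, 2, 1),      # same IQR as tie_b
    p_unmapped = rnorm(8))
  colnames(m) <- samples
  pm <- tibble::tibble(
    probe = c("p_wide", "p_flat", "p_only", "tie_a", "tie_b"),
    gene = c("G1", "G1", "G2", "G3", "G3"))
  out <- suppressMessages(collapse_probes_max_iqr(m, pm))
  expect_setequal(rownames(out), c("G1", "G2", "G3"))
  sel <- attr(out, "selected_probe")
  expect_equal(sel[["G1"]], "p_wide")
  expect_equal(sel[["G2"]], "p_only")
  expect_equal(sel[["G3"]], "tie_a")  # lexicographically smallest on tie
  # oracle: every retained probe attains its gene's maximal IQR
  iqr <- apply(m[pm$probe, ], 1, IQR)
  for (g in rownames(out)) {
    probes_g <- pm$probe[pm$gene == g]
    expect_equal(iqr[[sel[[g]]]], max(iqr[probes_g]))
  }
  expect_error(collapse_probes_max_iqr(m, tibble::tibble(probe = "zz",
                                                         gene = "G9")),
               "no overlap")
})

test_that("per-gene models match an lm() loop oracle", {
  set.seed(32)
  n <- 40; G <- 25
  ids <- sprintf("s%02d", 1:n)
  cohort <- tibble::tibble(id = ids, age = runif(n, 70, 93),
                           BMI = rnorm(n, 26, 4))
  fi <- categorize_frailty(tibble::tibble(
    id = ids, fi_score = runif(n, 0, 0.5), excluded = FALSE))
  expr <- matrix(rnorm(G * n), G, n,
                 dimnames = list(paste0("g", 1:G), ids))
  expr[3, ] <- expr[3, ] + 2 * fi$fi_score  # one real signal
  res <- genewise_fi_models(expr, fi, cohort)
  for (g in c(1, 3, 10, 25)) {
    fit <- lm(expr[g, ids] ~ fi$fi_score + cohort$age + cohort$BMI)
    sm <- summary(fit)$coefficients
    expect_equal(res$beta[g], sm[2, "Estimate"], tolerance = 1e-10)
    expect_equal(res$p[g], sm[2, "Pr(>|t|)"], tolerance = 1e-10)
  }
  expect_equal(res$q, p.adjust(res$p, "BH"))
  expect_true(all(res$q >= res$p))
})

test_that("planted FI gene attains minimum p and survives BH", {
  set.seed(33)
  n <- 89; G <- 800
  ids <- sprintf("s%03d", 1:n)
  cohort <- tibble::tibble(id = ids, age = runif(n, 70, 93),
                           BMI = rnorm(n, 26, 4))
  fi <- categorize_frailty(tibble::tibble(
    id = ids, fi_score = runif(n, 0, 0.5), excluded = FALSE))
  expr <- matrix(rnorm(G * n), G, n,
                 dimnames = list(sprintf("g%03d", 1:G), ids))
  expr["g001", ] <- expr["g001", ] + 8 * fi$fi_score
  res <- genewise_fi_models(expr, fi, cohort)
  expect_equal(res$gene[which.min(res$p)], "g001")
  expect_lt(res$q[res$gene == "g001"], 0.05)
  # tier counts nested
  tc <- attr(res, "tier_counts")
  expect_true(tc[["p<0.001"]] <= tc[["p<0.01"]] &&
                tc[["p<0.01"]] <= tc[["p<0.05"]])
})

test_that("zero-variance genes are flagged, crude and cell-adjusted variants run", {
  set.seed(34)
  n <- 30; G <- 10
  ids <- sprintf("s%02d", 1:n)
  cohort <- tibble::tibble(id = ids, age = runif(n, 70, 93),
                           BMI = rnorm(n, 26, 4))
  fi <- categorize_frailty(tibble::tibble(
    id = ids, fi_score = runif(n, 0, 0.5), excluded = FALSE))
  expr <- matrix(rnorm(G * n), G, n,
                 dimnames = list(paste0("g", 1:G), ids))
  expr[5, ] <- 7  # constant gene
  res <- suppressMessages(genewise_fi_models(expr, fi, cohort))
  expect_true(is.na(res$p[5]))
  expect_equal(attr(res, "n_zero_variance"), 1L)
  crude <- suppressMessages(genewise_fi_models(expr, fi, cohort,
                                               model = "crude"))
  expect_equal(attr(crude, "model"), "crude")
  props <- matrix(runif(n * 2, 0.2, 0.8), n, 2,
                  dimnames = list(ids, c("monocytes", "lymphocytes")))
  cell <- suppressMessages(genewise_fi_models(expr, fi, cohort,
                                              model = "cell_adjusted",
                                              cell_props = props))
  expect_equal(attr(cell, "model"), "cell_adjusted")
  expect_error(genewise_fi_models(expr, fi, cohort, model = "cell_adjusted"),
               "cell_props")
})

test_that("deconvolution: pure samples, noiseless mixtures, simplex invariants", {
  set.seed(35)
  G <- 60
  S <- matrix(exp(rnorm(G * 3, log(100), 1)), G, 3,
              dimnames = list(paste0("g", 1:G),
                              c("monocytes", "T_cells", "B_cells")))
  # pure monocyte sample
  expr_lin <- cbind(pure = S[, "monocytes"])
  rownames(expr_lin) <- rownames(S)
  dec <- deconvolve(expr_lin, S, linear_scale = TRUE)
  expect_equal(unname(dec$proportions["pure", ]), c(1, 0, 0), tolerance = 1e-9)

  # noiseless mixture 0.3 A + 0.7 B recovered to 1e-9 (log2 input path)
  mix <- 0.3 * S[, 1] + 0.7 * S[, 2]
  dec2 <- deconvolve(cbind(m = log2(mix)), S)
  expect_equal(unname(dec2$proportions["m", ]), c(0.3, 0.7, 0),
               tolerance = 1e-9)
  expect_lt(dec2$residual_norm[["m"]], 1e-6)

  # random positive mixtures: rows on the simplex, nonnegative
  P <- t(replicate(6, { w <- runif(3); w / sum(w) }))
  E <- S %*% t(P)
  colnames(E) <- paste0("s", 1:6)
  dec3 <- deconvolve(E, S, linear_scale = TRUE)
  expect_true(all(dec3$proportions >= 0))
  expect_equal(unname(rowSums(dec3$proportions)), rep(1, 6), tolerance = 1e-9)
  expect_equal(unname(dec3$proportions), unname(P), tolerance = 1e-9)
})

test_that("deconvolution agrees with the simplex grid-search oracle", {
  set.seed(36)
  G <- 40
  S <- matrix(exp(rnorm(G * 3, log(50), 1)), G, 3,
              dimnames = list(paste0("g", 1:G), c("A", "B", "C")))
  for (rep in 1:5) {
    w <- runif(3); w <- w / sum(w)
    y <- as.vector(S %*% w) * exp(rnorm(G, 0, 0.1))  # noisy mixture
    ym <- cbind(s = y)
    rownames(ym) <- rownames(S)
    dec <- deconvolve(ym, S, linear_scale = TRUE)
    oracle <- grid_deconv_oracle(S, y, step = 0.01)
    expect_lt(max(abs(unname(dec$proportions["s", ]) - oracle)), 0.011)
  }
})

test_that("deconvolution validates its inputs", {
  S <- matrix(exp(rnorm(30, log(50), 1)), 10, 3,
              dimnames = list(paste0("g", 1:10), c("A", "B", "C")))
  Sdup <- S; Sdup[, 3] <- 2 * Sdup[, 1]  # collinear cell types
  expect_error(deconvolve(cbind(s = S[, 1]), Sdup, linear_scale = TRUE),
               "rank deficient")
  expect_error(deconvolve(cbind(s = S[, 1]), S[, 1, drop = FALSE],
                          linear_scale = TRUE), ">= 2 cell types")
  Sneg <- S; Sneg[1, 1] <- -1
  expect_error(deconvolve(cbind(s = S[, 1]), Sneg, linear_scale = TRUE),
               "nonnegative")
})

test_that("cell-type models recover a positive monocyte-FI slope", {
  set.seed(37)
  n <- 90
  ids <- sprintf("s%03d", 1:n)
  cohort <- tibble::tibble(id = ids, age = runif(n, 70, 93),
                           BMI = rnorm(n, 26, 4))
  fi <- categorize_frailty(tibble::tibble(
    id = ids, fi_score = runif(n, 0, 0.5), excluded = FALSE))
  b_true <- 0.25
  mono <- 0.2 + b_true * fi$fi_score + rnorm(n, 0, 0.03)
  props <- cbind(monocytes = mono, rest = 1 - mono)
  rownames(props) <- ids
  res <- celltype_fi_models(props, fi, cohort)
  adj <- res[res$cell_type == "monocytes" & res$model == "adjusted", ]
  expect_gt(adj$beta, 0)
  expect_true(adj$ci_low <= b_true && b_true <= adj$ci_high)
  # covariates independent of both: crude ~ adjusted
  crude <- res[res$cell_type == "monocytes" & res$model == "crude", ]
  expect_equal(crude$beta, adj$beta, tolerance = 0.05)
  # constant proportions flagged degenerate
  props2 <- cbind(monocytes = rep(0.2, n), rest = rep(0.8, n))
  rownames(props2) <- ids
  res2 <- celltype_fi_models(props2, fi, cohort)
  expect_true(all(res2$degenerate))
})

test_that("permuted FI yields approximately uniform cell-type p-values", {
  set.seed(38)
  n <- 80
  ids <- sprintf("s%03d", 1:n)
  cohort <- tibble::tibble(id = ids, age = runif(n, 70, 93),
                           BMI = rnorm(n, 26, 4))
  mono <- 0.2 + rnorm(n, 0, 0.04)
  props <- cbind(monocytes = mono, rest = 1 - mono)
  rownames(props) <- ids
  ps <- replicate(200, {
    fi <- categorize_frailty(tibble::tibble(
      id = ids, fi_score = sample(runif(n, 0, 0.5)), excluded = FALSE))
    res <- celltype_fi_models(props, fi, cohort)
    res$p[res$cell_type == "monocytes" & res$model == "crude"]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})

test_that("top marker selection ranks a perfect correlate first and handles k", {
  set.seed(39)
  n <- 50
  ids <- sprintf("s%02d", 1:n)
  frac <- setNames(runif(n, 0.1, 0.4), ids)
  expr <- matrix(rnorm(20 * n), 20, n,
                 dimnames = list(sprintf("g%02d", 1:20), ids))
  expr["g07", ] <- frac  # identical to the fraction vector
  top <- select_top_marker_genes(expr, frac, k = 5)
  expect_equal(top$gene[1], "g07")
  expect_equal(top$R[1], 1)
  all_ranked <- select_top_marker_genes(expr, frac, k = 20)
  expect_equal(nrow(all_ranked), 20)
  expect_equal(all_ranked$rank, 1:20)
  expect_error(select_top_marker_genes(expr, frac, k = 0), "positive")
  expect_error(select_top_marker_genes(expr, frac, k = 99), "exceeds")
})

test_that("planted monocyte genes are recovered from simulated expression", {
  set.seed(40)
  cfg <- sim_config(n_subjects = 150, n_genes = 600, n_planted = 40,
                    n_expression_samples = 60)
  fi_scores <- setNames(runif(60, 0.02, 0.45), sprintf("s%02d", 1:60))
  ex <- simulate_expression(fi_scores, cfg)
  dec <- deconvolve(ex$expr, ex$signature)
  top <- select_top_marker_genes(ex$expr, dec$proportions[, "monocytes"],
                                 k = 30)
  recall <- mean(top$gene %in% ex$planted_genes)
  expect_gte(recall, 0.9)
})

test_that("marker-biomarker matrix: self-pair beta is 1, nulls center at 0", {
  set.seed(41)
  n <- 70
  ids <- sprintf("s%02d", 1:n)
  cohort <- tibble::tibble(id = ids, age = runif(n, 70, 93),
                           BMI = rnorm(n, 26, 4))
  v <- rnorm(n)
  panel <- tibble::tibble(id = ids, IL6 = v, CRP = rnorm(n))
  expr <- rbind(same_as_il6 = v, noise1 = rnorm(n), noise2 = rnorm(n))
  colnames(expr) <- ids
  mm <- suppressWarnings(marker_biomarker_matrix(expr, panel, cohort))
  expect_equal(mm$beta["same_as_il6", "IL6"], 1, tolerance = 1e-8)
  expect_equal(mm$stars["same_as_il6", "IL6"], "***")
  expect_equal(dim(mm$beta), c(3, 2))
  expect_setequal(mm$row_order, 1:3)

  # independent pairs: beta centred at zero over replicates
  betas <- replicate(60, {
    g <- rnorm(n); b <- rnorm(n)
    p2 <- tibble::tibble(id = ids, M = b)
    e2 <- matrix(g, 1, n, dimnames = list("g1", ids))
    marker_biomarker_matrix(e2, p2, cohort)$beta[1, 1]
  })
  expect_lt(abs(mean(betas)), 0.05)
})

test_that("marker-biomarker rows/columns carry hierarchical clustering orders", {
  set.seed(42)
  n <- 60
  ids <- sprintf("s%02d", 1:n)
  cohort <- tibble::tibble(id = ids, age = runif(n, 70, 93),
                           BMI = rnorm(n, 26, 4))
  panel <- tibble::tibble(id = ids, IL6 = rnorm(n), CRP = rnorm(n),
                          IGF1 = rnorm(n))
  expr <- matrix(rnorm(5 * n), 5, n,
                 dimnames = list(paste0("g", 1:5), ids))
  mm <- marker_biomarker_matrix(expr, panel, cohort)
  expect_setequal(mm$row_order, 1:5)
  expect_setequal(mm$col_order, 1:3)
  # orders reproduce a direct hclust on the (zero-filled) beta matrix
  expect_equal(mm$row_order, hclust(dist(mm$beta))$order)
})
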