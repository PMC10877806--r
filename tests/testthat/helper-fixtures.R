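# Shared fixture builders. All randomness is seeded by the caller.

# Coded deficit matrix from a plain numeric matrix (subjects x deficits).
make_coded <- function(values, ids = sprintf("s%03d", seq_len(nrow(values)))) {
  colnames(values) <- colnames(values) %||% paste0("d", seq_len(ncol(values)))
  out <- tibble::as_tibble(as.data.frame(values))
  out <- dplyr::bind_cols(tibble::tibble(id = ids), out)
  class(out) <- c("coded_deficit_matrix", class(out))
  out
}

# Independent brute-force FI oracle: explicit per-subject loop.
fi_oracle <- function(values) {
  apply(values, 1, function(row) {
    s <- 0; m <- 0L
    for (v in row) {
      if (!is.na(v)) { s <- s + v; m <- m + 1L }
    }
    if (m == 0) NA_real_ else s / m
  })
}

# Independent Spearman oracle: Pearson correlation on midranks.
spearman_oracle <- function(x, y) {
  cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# Brute-force simplex grid search oracle for <=3-type deconvolution of
# RELATIVE proportions: for each grid point p on the simplex the best
# nonnegative overall scale c is solved in closed form, and the p with the
# smallest residual ||y - c S p|| wins. The free scale makes the enumeration
# the exact counterpart of nonnegative least squares followed by
# renormalisation to proportions.
grid_deconv_oracle <- function(S, y, step = 0.01) {
  stopifnot(ncol(S) <= 3)
  grid <- seq(0, 1, by = step)
  yy <- sum(y^2)
  best <- NULL; best_err <- Inf
  score <- function(p) {
    v <- S %*% p
    vv <- sum(v^2)
    if (vv == 0) return(yy)
    c_opt <- max(sum(v * y) / vv, 0)
    yy - 2 * c_opt * sum(v * y) + c_opt^2 * vv
  }
  if (ncol(S) == 2) {
    for (a in grid) {
      p <- c(a, 1 - a)
      err <- score(p)
      if (err < best_err) { best_err <- err; best <- p }
    }
  } else {
    for (a in grid) for (b in grid) {
      if (a + b > 1 + 1e-12) next
      p <- c(a, b, 1 - a - b)
      err <- score(p)
      if (err < best_err) { best_err <- err; best <- p }
    }
  }
  best
}

# Minimal schema object for tests, built from a list of coding maps.
make_schema <- function(codings, categories = NULL) {
  categories <- categories %||%
    rep("Self-reported disease or condition", length(codings))
  raw <- list(version = "test", deficits = lapply(seq_along(codings), function(i) {
    list(name = names(codings)[i], category = categories[i],
         source_variable = names(codings)[i], coding = as.list(codings[[i]]))
  }))
  frailomics:::new_deficit_schema(raw)
}

`%||%` <- rlang::`%||%`
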