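#' Covariates of the standard adjustment model
#'
#' The 6-month value of each microbial feature is modeled as milk-consumption
#' group plus maternal age, maternal pre-pregnancy BMI, delivery mode,
#' maternal current BMI, infant sex, infant age in days, infant weight, and
#' the same feature at 1 month (baseline).
#'
#' @export
eq_covariates <- c("mother_age", "prepregnancy_bmi", "delivery_mode",
                   "current_bmi", "sex", "age_days", "weight_kg")

#' Significance star codes
#'
#' `"*"` for p < 0.05, `"**"` for p < 0.01, `"***"` for p < 0.001,
#' `"****"` for p < 0.0001 (strict inequalities; exactly 0.05 gets no star).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes (empty string when not significant).
#' @export
star_code <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

# design matrices used throughout inference; reference coding is group = BB,
# delivery = vaginal, sex = female (enforced by factor level order)
build_designs <- function(metadata, covariates = eq_covariates) {
  meta <- metadata
  meta$group <- factor(as.character(meta$group),
                       levels = intersect(milk_groups,
                                          unique(as.character(meta$group))))
  if ("delivery_mode" %in% names(meta)) {
    meta$delivery_mode <- factor(as.character(meta$delivery_mode),
                                 levels = c("vaginal", "c-section"))
  }
  if ("sex" %in% names(meta)) {
    meta$sex <- factor(as.character(meta$sex), levels = c("female", "male"))
  }
  covariates <- intersect(covariates, names(meta))
  x_cov <- if (length(covariates) > 0) {
    model.matrix(stats::reformulate(covariates), data = meta)
  } else {
    matrix(1, nrow(meta), 1, dimnames = list(NULL, "(Intercept)"))
  }
  g <- model.matrix(~group, data = meta)[, -1, drop = FALSE]
  list(x_cov = x_cov, g = g, group = meta$group)
}

#' Fit the covariate-adjusted linear model for one feature
#'
#' Ordinary least squares of the 6-month feature on milk-consumption group,
#' the standard covariates ([eq_covariates]) and, when supplied, the same
#' feature at 1 month. Rows with missing values are dropped with a reported
#' count (listwise deletion, no imputation).
#'
#' @param data Tibble holding the response, covariates and `group`.
#' @param response Name of the response column.
#' @param baseline Optional name of the 1-month baseline column.
#' @param covariates Covariate column names (default [eq_covariates]).
#' @return An `lm` fit (with the data actually used attached as
#'   `model_data`).
#' @export
fit_feature_model <- function(data, response, baseline = NULL,
                              covariates = eq_covariates) {
  covariates <- intersect(covariates, names(data))
  used <- c(response, baseline, covariates, "group")
  cc <- complete.cases(data[used])
  if (any(!cc)) {
    inform(sprintf("fit_feature_model: dropped %d row(s) with missing values",
                   sum(!cc)))
  }
  d <- data[cc, used]
  d$group <- factor(as.character(d$group),
                    levels = intersect(milk_groups, unique(as.character(d$group))))
  if ("delivery_mode" %in% names(d)) {
    d$delivery_mode <- factor(as.character(d$delivery_mode),
                              levels = c("vaginal", "c-section"))
  }
  if ("sex" %in% names(d)) {
    d$sex <- factor(as.character(d$sex), levels = c("female", "male"))
  }
  singles <- names(which(table(d$group) == 1))
  if (length(singles) > 0) {
    warn(paste0("Group(s) with a single infant: ",
                paste(singles, collapse = ", ")))
  }
  rhs <- c("group", covariates,
           if (!is.null(baseline)) sprintf("`%s`", baseline))
  form <- stats::reformulate(rhs, response = sprintf("`%s`", response))
  fit <- lm(form, data = d)
  if (fit$rank < ncol(model.matrix(fit))) {
    collinear <- colnames(model.matrix(fit))[is.na(stats::coef(fit))]
    abort(paste0("Rank-deficient design; collinear column(s): ",
                 paste(collinear, collapse = ", ")),
          class = "milkphen_model_error")
  }
  if (nrow(d) <= fit$rank) {
    abort("More parameters than observations", class = "milkphen_model_error")
  }
  fit$model_data <- d
  fit
}

#' F-test comparing nested full and reduced models
#'
#' `F = [(RSS_reduced - RSS_full) / d_df] / [RSS_full / df_full]` with the
#' p-value from the F distribution. The reduced model's terms must be a
#' subset of the full model's and both must be fit to the same rows.
#'
#' @param full,reduced `lm` fits on the same data.
#' @return A one-row tibble with `statistic`, `df1`, `df2`, `p_value`.
#' @export
anova_full_vs_reduced <- function(full, reduced) {
  t_full <- attr(stats::terms(full), "term.labels")
  t_red <- attr(stats::terms(reduced), "term.labels")
  if (!all(t_red %in% t_full)) {
    abort("Models are not nested", class = "milkphen_model_error")
  }
  if (length(resid(full)) != length(resid(reduced))) {
    abort("Models were fit to different numbers of rows",
          class = "milkphen_model_error")
  }
  rss_f <- sum(resid(full)^2)
  rss_r <- sum(resid(reduced)^2)
  df1 <- full$rank - reduced$rank
  df2 <- full$df.residual
  if (df1 == 0) {
    return(tibble(statistic = 0, df1 = 0L, df2 = df2, p_value = 1))
  }
  f <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  f <- max(f, 0)
  tibble(statistic = f, df1 = df1, df2 = df2,
         p_value = pf(f, df1, df2, lower.tail = FALSE))
}

#' Tukey-Kramer honestly-significant-difference contrasts
#'
#' All pairwise group comparisons using the studentized-range distribution,
#' in the Tukey-Kramer generalization for unbalanced groups:
#' `q = |m_g - m_h| / sqrt(s^2/2 * (1/n_g + 1/n_h))` with the pooled
#' within-group variance `s^2` on `n - k` degrees of freedom. Contrasts are
#' reported as second-listed minus first-listed level under the declared
#' level order, i.e. a contrast named `"X-Y"` estimates `mean(X) - mean(Y)`.
#'
#' @param values Numeric response (raw or covariate-adjusted).
#' @param groups Group labels; level order fixes the contrast layout.
#' @return A tibble with `contrast`, `estimate`, `se`, `statistic` (q),
#'   `adj_p_value`, `stars`.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  k <- nlevels(groups)
  if (k < 2) {
    abort("tukey_hsd needs at least two groups", class = "milkphen_input_error")
  }
  ns <- tabulate(groups)
  if (any(ns == 1)) {
    warn("Group(s) of size 1 contribute a mean but no variance to the pool")
  }
  means <- tapply(values, groups, mean)
  df <- length(values) - k
  if (df <= 0) abort("No residual degrees of freedom for the variance pool",
                     class = "milkphen_input_error")
  s2 <- sum((values - means[groups])^2) / df
  lv <- levels(groups)
  # report layout: for each second-listed level, all earlier levels first
  # (BP-BB, TF-BB, TF-BP, ASF-BB, ASF-BP, ASF-TF for the four milk groups)
  pairs <- do.call(cbind, lapply(2:k, function(j) rbind(seq_len(j - 1), j)))
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    est <- unname(means[i2] - means[i1])
    se <- sqrt(s2 / 2 * (1 / ns[i1] + 1 / ns[i2]))
    q <- abs(est) / se
    p <- ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    tibble(contrast = paste0(lv[i2], "-", lv[i1]),
           estimate = est, se = se, statistic = q,
           adj_p_value = p, stars = star_code(p))
  })
}

# ---- fast nested-F engine (used by the FDR permutations) -------------------

rss_of <- function(x, y) {
  fit <- stats::lm.fit(x, y)
  sum(fit$residuals^2)
}

# Full-vs-reduced group p-value for every feature column of y6.
# x_cov includes the intercept; y1 (same columns as y6) is optional.
nested_group_pvalues <- function(y6, y1, x_cov, g) {
  n <- nrow(y6)
  m <- ncol(y6)
  df1 <- ncol(g)
  vapply(seq_len(m), function(j) {
    xr <- if (is.null(y1)) x_cov else cbind(x_cov, y1[, j])
    xf <- cbind(xr, g)
    rss_r <- rss_of(xr, y6[, j])
    rss_f <- rss_of(xf, y6[, j])
    df2 <- n - qr(xf)$rank
    f <- max(0, ((rss_r - rss_f) / df1) / (rss_f / df2))
    pf(f, df1, df2, lower.tail = FALSE)
  }, numeric(1))
}

#' Per-feature group p-values under label permutation
#'
#' Re-runs the full-vs-reduced group test for every feature after permuting
#' the group labels (jointly across features, preserving inter-feature
#' correlation; covariates and baselines stay attached to their samples).
#' Row 0 of the conceptual stack is the observed labeling, returned
#' separately.
#'
#' @param features Feature tibble (`sample_id` + feature columns) at 6 months.
#' @param metadata Cohort metadata aligned by `infant_id`.
#' @param baseline Optional feature tibble at 1 month (same columns).
#' @param covariates Covariate names (default [eq_covariates]).
#' @param n_permutations Number of permutations.
#' @param seed Integer seed.
#' @return A list with `observed_p` (named numeric, one per feature) and
#'   `perm_p` (`n_permutations` x features matrix).
#' @export
permuted_group_pvalues <- function(features, metadata, baseline = NULL,
                                   covariates = eq_covariates,
                                   n_permutations = 1000, seed = 1L) {
  al <- align_features(features, metadata, baseline)
  ds <- build_designs(al$metadata, covariates)
  y6 <- al$y6
  y1 <- al$y1
  obs <- nested_group_pvalues(y6, y1, ds$x_cov, ds$g)
  names(obs) <- colnames(y6)
  perm <- with_seed(seed, {
    pm <- vapply(seq_len(n_permutations), function(b) {
      idx <- sample(nrow(ds$g))
      nested_group_pvalues(y6, y1, ds$x_cov, ds$g[idx, , drop = FALSE])
    }, numeric(ncol(y6)))
    matrix(pm, nrow = n_permutations, ncol = ncol(y6), byrow = TRUE)
  })
  colnames(perm) <- colnames(y6)
  list(observed_p = obs, perm_p = perm)
}

# listwise-aligned numeric matrices for the inference engine
align_features <- function(features, metadata, baseline = NULL) {
  stopifnot("sample_id" %in% names(features))
  meta <- metadata[match(features$sample_id, metadata$infant_id), ]
  if (anyNA(meta$infant_id)) {
    abort("Feature sample IDs missing from metadata",
          class = "milkphen_input_error")
  }
  y6 <- as_feature_matrix(features)
  y1 <- NULL
  if (!is.null(baseline)) {
    b <- baseline[match(features$sample_id, baseline$sample_id), ]
    if (anyNA(b$sample_id)) {
      abort("Baseline table is missing sample(s) present at 6 months",
            class = "milkphen_input_error")
    }
    y1 <- as_feature_matrix(b)[, colnames(y6), drop = FALSE]
  }
  cc <- complete.cases(meta[intersect(c("group", eq_covariates), names(meta))]) &
    stats::complete.cases(y6) &
    (if (is.null(y1)) TRUE else stats::complete.cases(y1))
  if (any(!cc)) {
    inform(sprintf("Listwise deletion dropped %d sample(s)", sum(!cc)))
  }
  list(y6 = y6[cc, , drop = FALSE],
       y1 = if (is.null(y1)) NULL else y1[cc, , drop = FALSE],
       metadata = meta[cc, ])
}

#' Permutation-based false discovery rate with confidence interval
#'
#' At p-value threshold `threshold`, the FDR estimate is the mean number of
#' discoveries across label-permuted reruns divided by the observed number
#' of discoveries, capped at 1. The confidence interval uses a normal
#' approximation on the log-ratio scale with the permutation-derived
#' variance of the per-permutation discovery counts. With zero observed
#' discoveries the FDR is undefined and reported as missing; with a positive
#' estimate but zero permutation discoveries the upper limit reflects at
#' most one discovery in all permutations.
#'
#' @param observed_p Observed per-feature p-values.
#' @param perm_p Permutations-by-features matrix of permuted p-values.
#' @param threshold Discovery threshold (default 0.05).
#' @param ci Confidence level (default 0.95).
#' @return A one-row tibble with `n_discoveries`, `fdr_estimate`,
#'   `fdr_ci_lower`, `fdr_ci_upper`.
#' @export
fdr_ci <- function(observed_p, perm_p, threshold = 0.05, ci = 0.95) {
  n_disc <- sum(observed_p <= threshold, na.rm = TRUE)
  if (n_disc == 0) {
    return(tibble(n_discoveries = 0L, fdr_estimate = NA_real_,
                  fdr_ci_lower = NA_real_, fdr_ci_upper = NA_real_))
  }
  r_b <- rowSums(perm_p <= threshold, na.rm = TRUE)
  b <- length(r_b)
  rbar <- mean(r_b)
  z <- qnorm(1 - (1 - ci) / 2)
  if (rbar == 0) {
    upper <- min(1, 1 / (b * n_disc))
    return(tibble(n_discoveries = n_disc, fdr_estimate = 0,
                  fdr_ci_lower = 0, fdr_ci_upper = upper))
  }
  est <- min(1, rbar / n_disc)
  se_log <- sd(r_b) / (sqrt(b) * rbar)
  tibble(n_discoveries = n_disc,
         fdr_estimate = est,
         fdr_ci_lower = max(0, est * exp(-z * se_log)),
         fdr_ci_upper = min(1, est * exp(z * se_log)))
}

#' Pairwise raw mean differences in the six-contrast layout
#'
#' Computes `mean(X) - mean(Y)` for every group pair from a table of
#' per-group means, laid out in the standard contrast order (for the four
#' feeding groups: BP-BB, TF-BB, TF-BP, ASF-BB, ASF-BP, ASF-TF). Useful for
#' summary-level inputs where only group means are published.
#'
#' @param group_means Tibble with columns `feature`, `group`, `mean`.
#' @return A tibble with one row per feature and one `diff_X_Y` column per
#'   contrast.
#' @export
pairwise_raw_differences <- function(group_means) {
  lv <- intersect(milk_groups, unique(as.character(group_means$group)))
  if (length(lv) < 2) {
    abort("Need at least two groups", class = "milkphen_input_error")
  }
  wide <- tidyr::pivot_wider(group_means, id_cols = "feature",
                             names_from = "group", values_from = "mean")
  k <- length(lv)
  pairs <- do.call(cbind, lapply(2:k, function(j) rbind(seq_len(j - 1), j)))
  out <- tibble(feature = wide$feature)
  for (j in seq_len(ncol(pairs))) {
    a <- lv[pairs[1, j]]; b <- lv[pairs[2, j]]
    out[[paste0("diff_", b, "_", a)]] <- wide[[b]] - wide[[a]]
  }
  out
}

#' Covariate-adjusted per-feature group comparison table
#'
#' The full inference procedure for one family of features: per-group raw
#' means and SDs, an overall p-value from the full-versus-reduced F-test
#' (full model: group + covariates + 1-month baseline; reduced: the same
#' without group), Tukey-Kramer pairwise contrasts, a permutation FDR
#' confidence interval computed once for the whole family at the discovery
#' threshold, and the dual significance rule (overall p below
#' `p_threshold` AND FDR CI upper limit below `fdr_upper_threshold`).
#'
#' In `mode = "adjusted"` (default) the Tukey contrasts act on the
#' covariate-adjusted response: the residuals of the reduced (no-group)
#' model, which retain the group effects the reduced model cannot absorb.
#' In `mode = "raw"` contrasts are computed from the raw feature values, so
#' the pairwise estimates equal raw group mean differences.
#'
#' @param features Feature tibble (`sample_id` + feature columns) at
#'   6 months; an optional `categories` attribute is carried into the output.
#' @param metadata Cohort metadata (one row per infant, `infant_id`,
#'   `group`, covariates).
#' @param baseline Optional 1-month feature tibble (same columns as
#'   `features`).
#' @param mode `"adjusted"` or `"raw"` (see Details).
#' @param covariates Covariate names (default [eq_covariates]); ignored in
#'   raw mode.
#' @param n_permutations Permutations for the FDR CI (default 1000); set to 0
#'   to skip the FDR computation.
#' @param seed Integer seed for the permutations.
#' @param p_threshold,fdr_upper_threshold Dual significance rule thresholds
#'   (defaults 0.05 and 0.25).
#' @return A tibble with one row per feature: `feature`, optional
#'   `category`, `mean_<G>`/`sd_<G>` per group, `p_value`, per-contrast
#'   `diff_*`, `p_*`, `stars_*` columns in the six-contrast layout,
#'   `fdr_estimate`, `fdr_ci_upper`, `significant`.
#' @export
comparison_table <- function(features, metadata, baseline = NULL,
                             mode = c("adjusted", "raw"),
                             covariates = eq_covariates,
                             n_permutations = 1000, seed = 1L,
                             p_threshold = 0.05, fdr_upper_threshold = 0.25) {
  mode <- match.arg(mode)
  if (mode == "raw") {
    covariates <- character(0)
    baseline <- NULL
  }
  cats <- attr(features, "categories")
  al <- align_features(features, metadata, baseline)
  ds <- build_designs(al$metadata, covariates)
  feats <- colnames(al$y6)
  group <- ds$group
  if (length(feats) == 0) {
    return(tibble(feature = character(0), p_value = numeric(0),
                  fdr_estimate = numeric(0), fdr_ci_upper = numeric(0),
                  significant = logical(0)))
  }

  # overall p per feature (full vs reduced F)
  obs_p <- nested_group_pvalues(al$y6, al$y1, ds$x_cov, ds$g)
  names(obs_p) <- feats

  rows <- purrr::map_dfr(feats, function(f) {
    y <- al$y6[, f]
    means <- tapply(y, group, mean)
    sds <- tapply(y, group, sd)
    resp <- if (mode == "raw") {
      y
    } else {
      xr <- if (is.null(al$y1)) ds$x_cov else cbind(ds$x_cov, al$y1[, f])
      stats::lm.fit(xr, y)$residuals
    }
    tk <- tukey_hsd(resp, group)
    stats_row <- tibble(feature = f)
    if (!is.null(cats)) stats_row$category <- unname(cats[f])
    for (g in levels(group)) {
      stats_row[[paste0("mean_", g)]] <- unname(means[g])
      stats_row[[paste0("sd_", g)]] <- unname(sds[g])
    }
    stats_row$p_value <- unname(obs_p[f])
    for (j in seq_len(nrow(tk))) {
      key <- gsub("-", "_", tk$contrast[j])
      stats_row[[paste0("diff_", key)]] <- tk$estimate[j]
      stats_row[[paste0("p_", key)]] <- tk$adj_p_value[j]
      stats_row[[paste0("stars_", key)]] <- tk$stars[j]
    }
    stats_row
  })

  if (n_permutations > 0) {
    pg <- permuted_group_pvalues(features, metadata, baseline,
                                 covariates = covariates,
                                 n_permutations = n_permutations, seed = seed)
    fc <- fdr_ci(pg$observed_p, pg$perm_p, threshold = p_threshold)
    rows$fdr_estimate <- fc$fdr_estimate
    rows$fdr_ci_upper <- fc$fdr_ci_upper
    rows$significant <- !is.na(rows$p_value) & rows$p_value < p_threshold &
      !is.na(fc$fdr_ci_upper) & fc$fdr_ci_upper < fdr_upper_threshold
  } else {
    rows$fdr_estimate <- NA_real_
    rows$fdr_ci_upper <- NA_real_
    rows$significant <- NA
  }
  rows
}
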