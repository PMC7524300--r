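# deterministic toy cohort data for model tests
toy_cohort <- function(n_per_group = 25, seed = 1, effect = c(BB = 0, BP = 0,
                                                              TF = 0, ASF = 0),
                       noise_sd = 1) {
  cfg <- cohort_config(group_sizes = setNames(rep(n_per_group, 4),
                                              milk_groups),
                       seed = seed)
  meta <- simulate_metadata(cfg)
  set.seed(seed + 1000)
  y1 <- rnorm(nrow(meta))
  y6 <- 0.5 * y1 + effect[as.character(meta$group)] +
    0.02 * meta$mother_age + rnorm(nrow(meta), sd = noise_sd)
  data <- dplyr::bind_cols(meta, tibble::tibble(y6 = y6, y1 = y1))
  data
}

test_that("the covariate-adjusted model recovers known coefficients", {
  set.seed(201)
  cfg <- cohort_config(group_sizes = c(BB = 125, BP = 125, TF = 125,
                                       ASF = 125), seed = 9)
  meta <- simulate_metadata(cfg)
  n <- nrow(meta)
  y1 <- rnorm(n)
  truth <- c(BB = 0, BP = 0.4, TF = 0.8, ASF = 1.2)
  y6 <- 1 + truth[as.character(meta$group)] + 0.05 * meta$mother_age -
    0.03 * meta$current_bmi + 0.6 * y1 + rnorm(n, sd = 0.1)
  d <- dplyr::bind_cols(meta, tibble::tibble(y6 = y6, y1 = y1))
  fit <- fit_feature_model(d, "y6", baseline = "y1")
  est <- coef(summary(fit))
  for (term in c("groupBP", "groupTF", "groupASF")) {
    truth_val <- truth[sub("group", "", term)]
    expect_lt(abs(est[term, "Estimate"] - truth_val),
              3 * est[term, "Std. Error"])
  }
  expect_lt(abs(est["y1", "Estimate"] - 0.6), 3 * est["y1", "Std. Error"])
})

test_that("degenerate designs are caught and single-member groups warned", {
  d <- toy_cohort(seed = 3)
  # response duplicated as its own baseline predictor: perfect fit
  d$same <- d$y6
  fit <- suppressMessages(fit_feature_model(d, "y6", baseline = "same"))
  expect_lt(max(abs(resid(fit))), 1e-8)

  # collinear covariate -> rank-deficient design error
  d2 <- toy_cohort(seed = 4)
  d2$dup_age <- d2$mother_age
  expect_error(
    fit_feature_model(d2, "y6", covariates = c("mother_age", "dup_age")),
    class = "milkphen_model_error")

  # a group with a single infant still fits, with a warning
  d3 <- toy_cohort(seed = 5)
  d3 <- d3[c(which(d3$group != "BB"), which(d3$group == "BB")[1]), ]
  expect_warning(fit_feature_model(d3, "y6"), "single infant")
})

test_that("full-vs-reduced F matches hand computation and edge cases", {
  # 10-row nested fixture, F computed from residual sums of squares by hand
  d <- tibble::tibble(
    y = c(2.1, 3.9, 6.2, 7.8, 10.1, 12.2, 13.8, 16.1, 18.0, 19.9),
    x1 = 1:10,
    x2 = c(0.5, -0.3, 0.8, -0.1, 0.4, -0.6, 0.2, 0.1, -0.4, 0.3)
  )
  full <- lm(y ~ x1 + x2, data = d)
  reduced <- lm(y ~ x1, data = d)
  res <- anova_full_vs_reduced(full, reduced)
  rss_f <- sum(resid(full)^2); rss_r <- sum(resid(reduced)^2)
  f_hand <- ((rss_r - rss_f) / 1) / (rss_f / 7)
  expect_equal(res$statistic, f_hand, tolerance = 1e-12)
  expect_equal(res$p_value, pf(f_hand, 1, 7, lower.tail = FALSE))
  # agreement with stats::anova as an independent route
  expect_equal(res$p_value, anova(reduced, full)$`Pr(>F)`[2])

  same <- anova_full_vs_reduced(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(anova_full_vs_reduced(reduced, lm(y ~ x2, data = d)),
               class = "milkphen_model_error")
})

test_that("group F-test p is invariant to affine rescaling of the response", {
  d <- toy_cohort(seed = 11)
  full <- fit_feature_model(d, "y6", baseline = "y1")
  red <- lm(stats::reformulate(c(eq_covariates, "y1"), "y6"), data = d)
  p1 <- anova_full_vs_reduced(full, red)$p_value
  d2 <- d; d2$y6 <- 100 * d$y6 - 7
  full2 <- fit_feature_model(d2, "y6", baseline = "y1")
  red2 <- lm(stats::reformulate(c(eq_covariates, "y1"), "y6"), data = d2)
  p2 <- anova_full_vs_reduced(full2, red2)$p_value
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("Tukey-Kramer reduces to the pooled t-test for two groups", {
  set.seed(31)
  x <- c(rnorm(12, 0), rnorm(17, 0.7))
  g <- rep(c("A", "B"), c(12, 17))
  tk <- tukey_hsd(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(tk$adj_p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(tk$statistic, sqrt(2) * abs(unname(tt$statistic)),
               tolerance = 1e-10)
  expect_equal(tk$estimate, unname(diff(tapply(x, g, mean))))
})

test_that("Tukey-Kramer agrees with TukeyHSD and the integration oracle", {
  set.seed(32)
  x <- c(rnorm(10, 0), rnorm(10, 0.8), rnorm(10, 1.6))
  g <- factor(rep(c("A", "B", "C"), each = 10))
  tk <- tukey_hsd(x, g)
  hsd <- TukeyHSD(aov(x ~ g))$g
  expect_equal(tk$adj_p_value,
               hsd[c("B-A", "C-A", "C-B"), "p adj"], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(tk$estimate, hsd[c("B-A", "C-A", "C-B"), "diff"],
               tolerance = 1e-10, ignore_attr = TRUE)
  # independent oracle: nested numerical integration of the studentized
  # range distribution
  for (j in seq_len(nrow(tk))) {
    p_oracle <- studentized_range_tail(tk$statistic[j], k = 3, df = 27)
    expect_equal(tk$adj_p_value[j], p_oracle, tolerance = 1e-4)
  }
})

test_that("Tukey adjustment is conservative relative to unadjusted t-tests", {
  set.seed(33)
  x <- rnorm(40)
  g <- factor(rep(c("A", "B", "C", "D"), each = 10))
  tk <- tukey_hsd(x, g)
  for (j in seq_len(nrow(tk))) {
    pair <- strsplit(tk$contrast[j], "-")[[1]]
    keep <- g %in% pair
    p_t <- t.test(x[keep] ~ droplevels(g[keep]), var.equal = TRUE)$p.value
    expect_gte(tk$adj_p_value[j] + 1e-12, p_t)
  }
  # exactly equal group means -> all adjusted p equal to 1
  tk0 <- tukey_hsd(rep(rnorm(10), 4), g)
  expect_true(all(tk0$adj_p_value == 1))
})

test_that("star codes follow the strict inequality thresholds", {
  expect_equal(star_code(c(0.05, 0.049, 0.01, 0.0099, 1e-3, 9e-4, 1e-4, 9e-5)),
               c("", "*", "*", "**", "**", "***", "***", "****"))
  expect_true(is.na(star_code(NA_real_)))
})

test_that("fdr_ci honors its contracts on toy inputs", {
  # zero discoveries -> missing, not zero
  res <- fdr_ci(c(0.2, 0.9), matrix(runif(20), 10, 2))
  expect_equal(res$n_discoveries, 0L)
  expect_true(is.na(res$fdr_estimate))

  # all permutation p tiny -> estimate capped at 1
  res2 <- fdr_ci(c(0.01, 0.2), matrix(1e-6, 10, 2))
  expect_equal(res2$fdr_estimate, 1)
  expect_equal(res2$fdr_ci_upper, 1)

  # no permutation discoveries -> near-zero FDR with a bounded upper limit
  res3 <- fdr_ci(c(0.01, 0.01), matrix(0.9, 10, 2))
  expect_equal(res3$fdr_estimate, 0)
  expect_lt(res3$fdr_ci_upper, 0.2)
})

test_that("comparison_table lays out six contrasts and the dual rule", {
  co <- cohort_family_features(small_config(seed = 51))
  ct <- comparison_table(co$log6, co$metadata, baseline = co$log1,
                         n_permutations = 100, seed = 2)
  expect_equal(nrow(ct), ncol(co$log6) - 1)
  contrast_cols <- grep("^diff_", names(ct), value = TRUE)
  expect_equal(contrast_cols,
               paste0("diff_", c("BP_BB", "TF_BB", "TF_BP", "ASF_BB",
                                 "ASF_BP", "ASF_TF")))
  # stars consistent with adjusted p
  for (ct_name in c("BP_BB", "ASF_BB")) {
    expect_equal(ct[[paste0("stars_", ct_name)]],
                 star_code(ct[[paste0("p_", ct_name)]]))
  }
  # dual rule never flags more than raw p alone
  expect_true(all(which(ct$significant) %in% which(ct$p_value < 0.05)))
  # known strong effects come out with the right sign
  expect_gt(ct$diff_ASF_BB[ct$feature == "Lachnospiraceae"], 0)
  expect_lt(ct$diff_ASF_BB[ct$feature == "Bifidobacteriaceae"], 0)
})

test_that("raw-means mode reports exact group mean differences", {
  co <- cohort_family_features(small_config(seed = 53))
  ct <- comparison_table(co$log6, co$metadata, mode = "raw",
                         n_permutations = 0)
  m <- as.matrix(co$log6[-1])
  for (f in c("Lachnospiraceae", "Bifidobacteriaceae")) {
    gm <- tapply(m[, f], co$metadata$group, mean)
    expect_equal(ct$diff_ASF_BB[ct$feature == f],
                 unname(gm["ASF"] - gm["BB"]), tolerance = 1e-12)
    expect_equal(ct$mean_TF[ct$feature == f], unname(gm["TF"]),
                 tolerance = 1e-12)
  }
})

test_that("pairwise_raw_differences computes the six-contrast layout", {
  gm <- tidyr::expand_grid(feature = c("f1", "f2"), group = milk_groups)
  gm$mean <- c(1, 2, 4, 8, 10, 20, 40, 80)
  out <- pairwise_raw_differences(gm)
  expect_equal(out$diff_BP_BB, c(1, 10))
  expect_equal(out$diff_ASF_TF, c(4, 40))
  expect_equal(names(out)[-1],
               paste0("diff_", c("BP_BB", "TF_BB", "TF_BP", "ASF_BB",
                                 "ASF_BP", "ASF_TF")))
})
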