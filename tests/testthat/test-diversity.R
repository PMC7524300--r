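test_that("alpha diversity matches hand-evaluated formulas", {
  uniform <- tibble::tibble(sample_id = "u", a = 5, b = 5, c = 5, d = 5)
  au <- alpha_diversity(uniform)
  expect_equal(au$shannon, log(4))
  expect_equal(au$simpson, 0.75)
  expect_equal(au$evenness, 1)

  single <- tibble::tibble(sample_id = "s", a = 10)
  as_ <- alpha_diversity(single)
  expect_equal(as_$shannon, 0)
  expect_equal(as_$simpson, 0)
  expect_equal(as_$richness, 1L)
  expect_equal(as_$evenness, 0)

  mixed <- tibble::tibble(sample_id = "m", a = 1, b = 1, c = 2)
  am <- alpha_diversity(mixed)
  expect_equal(am$shannon, 1.0397, tolerance = 1e-4)
  expect_equal(am$simpson, 0.625)

  expect_warning(a0 <- alpha_diversity(tiny_counts()), "Zero-depth")
  expect_true(is.na(a0$shannon[a0$sample_id == "s2"]))
})

test_that("alpha metrics satisfy their bounds and agree with vegan", {
  skip_if_not_installed("vegan")
  cfg <- small_config(seed = 17)
  co <- simulate_cohort(cfg)
  a <- alpha_diversity(co$month6)
  expect_true(all(a$evenness >= 0 & a$evenness <= 1))
  expect_true(all(a$shannon <= log(a$richness) + 1e-12))
  expect_true(all(a$simpson >= 0 & a$simpson < 1))
  m <- as.matrix(co$month6[-1])
  expect_equal(a$shannon, unname(vegan::diversity(m, index = "shannon")))
  expect_equal(a$simpson, unname(vegan::diversity(m, index = "simpson")))
})

test_that("rclr matches hand evaluation and is scale invariant", {
  x <- tibble::tibble(sample_id = "s1", a = 1, b = exp(1), c = exp(2))
  expect_equal(unname(rclr_transform(x)[1, ]), c(-1, 0, 1))

  cfg <- small_config(seed = 19)
  co <- simulate_cohort(cfg)
  r1 <- rclr_transform(co$month6)
  scaled <- co$month6
  scaled[-1] <- scaled[-1] * 7.3
  expect_equal(rclr_transform(scaled), r1, tolerance = 1e-12)

  one <- tibble::tibble(sample_id = "s1", a = 0, b = 5, c = 0)
  r <- rclr_transform(one)
  expect_equal(unname(r[1, "b"]), 0)
  expect_true(all(is.na(r[1, c("a", "c")])))
})

test_that("rpca on dense data equals classical clr-PCA", {
  set.seed(101)
  m <- matrix(rpois(30 * 12, 40) + 1, 30, 12,
              dimnames = list(paste0("s", 1:30), paste0("t", 1:12)))
  counts <- milkphen:::matrix_to_tibble(m)
  ord <- rpca(rclr_transform(counts), rank = 3)
  expect_true(ord$converged)

  clr <- t(apply(log(m), 1, function(r) r - mean(r)))
  pc <- prcomp(clr, center = TRUE, scale. = FALSE)
  expect_lt(procrustes_error(ord$sample_scores[-1], pc$x[, 1:3]), 1e-6)

  expect_equal(sum(ord$proportion_explained), 1, tolerance = 1e-6)
  expect_equal(order(ord$proportion_explained, decreasing = TRUE), 1:3)
})

test_that("rpca flags rank deficiency and rejects impossible ranks", {
  set.seed(7)
  u <- matrix(rnorm(40), 20, 2)
  v <- matrix(rnorm(16), 8, 2)
  x <- u %*% t(v)           # exactly rank 2, dense
  dimnames(x) <- list(paste0("s", 1:20), paste0("t", 1:8))
  ord <- rpca(x, rank = 3)
  expect_lt(ord$proportion_explained[3], 1e-8)
  expect_error(rpca(x, rank = 25), class = "milkphen_input_error")
})

test_that("rpca completes missing entries of a low-rank matrix", {
  set.seed(23)
  u <- matrix(rnorm(60), 30, 2)
  v <- matrix(rnorm(20), 10, 2)
  x <- u %*% t(v)
  dimnames(x) <- list(paste0("s", 1:30), paste0("t", 1:10))
  x_missing <- x
  x_missing[sample(length(x), 30)] <- NA
  ord <- suppressWarnings(rpca(x_missing, rank = 2, max_iter = 500))
  full <- rpca(x, rank = 2)
  expect_lt(procrustes_error(ord$sample_scores[-1], full$sample_scores[-1]),
            0.05)
})

test_that("aitchison distance is a metric on score rows", {
  scores <- rbind(a = c(0, 0), b = c(3, 4))
  d <- aitchison_distance(scores)
  expect_equal(d["a", "b"], 5)
  expect_equal(diag(d), c(a = 0, b = 0))

  cfg <- small_config(seed = 29)
  co <- simulate_cohort(cfg)
  ord <- suppressWarnings(rpca(rclr_transform(co$month6)))
  d <- aitchison_distance(ord)
  expect_equal(d, t(d))
  # permuting samples permutes rows/cols consistently
  idx <- sample(nrow(d))
  sc2 <- ord$sample_scores[idx, ]
  d2 <- aitchison_distance(sc2)
  expect_equal(d2, d[idx, idx])
})

test_that("permanova matches vegan and honors its invariants", {
  skip_if_not_installed("vegan")
  cfg <- small_config(seed = 37)
  co <- simulate_cohort(cfg)
  ord <- suppressWarnings(rpca(rclr_transform(co$month6)))
  sc <- as.matrix(ord$sample_scores[-1])
  d <- aitchison_distance(ord)
  pm <- permanova(d, co$metadata$group, n_permutations = 999, seed = 4)
  av <- vegan::adonis2(stats::dist(sc) ~ group, data = co$metadata,
                       permutations = 99)
  expect_equal(pm$pseudo_F, av$F[1], tolerance = 1e-10)
  expect_equal(pm$r_squared, av$R2[1], tolerance = 1e-10)
  expect_gte(pm$p_value, 1 / 1000)
  expect_true(pm$r_squared >= 0 && pm$r_squared <= 1)

  # R^2 invariant to distance scaling
  pm2 <- permanova(3.7 * d, co$metadata$group, n_permutations = 99, seed = 4)
  expect_equal(pm2$r_squared, pm$r_squared, tolerance = 1e-12)

  # identical results under identical seeds
  pm3 <- permanova(d, co$metadata$group, n_permutations = 999, seed = 4)
  expect_identical(pm3$p_value, pm$p_value)
})

test_that("permanova separates point masses and rejects degenerate input", {
  d <- as.matrix(stats::dist(rep(c(0, 10), each = 10)))
  dimnames(d) <- list(paste0("s", 1:20), paste0("s", 1:20))
  labels <- rep(c("A", "B"), each = 10)
  pm <- permanova(d, labels, n_permutations = 199, seed = 1)
  expect_gt(pm$r_squared, 0.999)
  expect_equal(pm$p_value, 1 / 200)
  expect_error(permanova(d, rep("A", 20)), class = "milkphen_input_error")
})

test_that("axis anova reduces to the squared t-test with two groups", {
  set.seed(55)
  x <- rnorm(40)
  g <- rep(c("A", "B"), each = 20)
  res <- axis_anova(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)

  sep <- axis_anova(as.numeric(g == "A") + rnorm(40, sd = 1e-3), g)
  expect_lt(sep$p_value, 1e-6)

  f <- factor(rep(c("A", "B"), each = 20), levels = c("A", "B", "C"))
  expect_warning(axis_anova(x, f), "empty group")
})
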