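#' Robust centered log-ratio transform
#'
#' For each sample, nonzero counts map to
#' `ln(count) - mean(ln(count) over that sample's nonzero taxa)`; zeros
#' become `NA` (missing, not imputed). The result is invariant to per-sample
#' rescaling, so counts and relative abundances give identical output.
#'
#' @param counts Wide count tibble (`sample_id` + taxa columns).
#' @return A samples-by-taxa numeric matrix with `NA` at zero entries.
#' @export
rclr_transform <- function(counts) {
  m <- as_feature_matrix(counts)
  logm <- log(m)
  logm[!is.finite(logm)] <- NA
  sweep(logm, 1, rowMeans(logm, na.rm = TRUE), "-")
}

# double centering: subtract row means, column means, add grand mean
double_center <- function(x) {
  rm_ <- rowMeans(x)
  cm_ <- colMeans(x)
  gm_ <- mean(x)
  x - outer(rm_, rep(1, ncol(x))) - outer(rep(1, nrow(x)), cm_) + gm_
}

#' Robust Aitchison ordination by low-rank matrix completion
#'
#' A DEICODE-style rank-`r` principal component analysis of the rclr matrix
#' that treats zeros as missing. Missing entries are initialized with
#' observed column means, then the fit alternates between (i) truncated SVD
#' of the double-centered completed matrix and (ii) re-imputation of missing
#' entries from the current rank-`r` reconstruction, until the relative
#' change in imputed values falls below `tol`. On a dense matrix (no zeros)
#' this reduces in one step to classical PCA of the clr-transformed data.
#'
#' `proportion_explained` is computed over the rank-`r` model (squared
#' singular values of the final fit normalized to the retained axes), so the
#' `rank` axes always account for 100% of the modeled variation; this
#' convention is stated explicitly because full-rank PCA conventions differ.
#'
#' @param rclr_matrix Matrix from [rclr_transform()] (`NA` = missing).
#' @param rank Number of axes (default 3).
#' @param max_iter,tol Iteration controls (relative change in the completed
#'   matrix).
#' @return An object of class `milkphen_rpca` with elements `sample_scores`
#'   (tibble: `sample_id`, `PC1..PCr`), `taxon_loadings` (tibble),
#'   `proportion_explained`, `singular_values`, `converged`, `n_iter`.
#' @export
rpca <- function(rclr_matrix, rank = 3, max_iter = 200, tol = 1e-6) {
  x <- as.matrix(rclr_matrix)
  if (rank < 1 || rank > min(dim(x))) {
    abort("rank must be between 1 and min(dim)",
          class = "milkphen_input_error")
  }
  obs <- !is.na(x)
  if (any(rowSums(obs) == 0)) {
    abort("Samples with no observed taxa cannot be ordinated",
          class = "milkphen_input_error")
  }
  # initialize missing entries with observed column means (0 if a taxon is
  # entirely absent)
  col_mu <- colMeans(x, na.rm = TRUE)
  col_mu[is.nan(col_mu)] <- 0
  filled <- x
  for (j in seq_len(ncol(x))) filled[!obs[, j], j] <- col_mu[j]

  converged <- FALSE
  n_iter <- 0L
  sv <- NULL
  for (it in seq_len(max_iter)) {
    n_iter <- it
    centered <- double_center(filled)
    sv <- svd(centered, nu = rank, nv = rank)
    d <- sv$d[seq_len(rank)]
    approx_c <- sv$u %*% (d * t(sv$v))
    # undo centering to get completions on the original scale
    recon <- approx_c + (filled - centered)
    new_filled <- filled
    new_filled[!obs] <- recon[!obs]
    delta <- sqrt(sum((new_filled - filled)^2)) /
      max(sqrt(sum(filled^2)), .Machine$double.eps)
    filled <- new_filled
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && any(!obs)) {
    warn(sprintf("rpca did not converge in %d iterations (returning best iterate)",
                 max_iter))
  } else if (!any(!obs)) {
    converged <- TRUE
  }
  centered <- double_center(filled)
  sv <- svd(centered, nu = rank, nv = rank)
  d <- sv$d[seq_len(rank)]
  prop <- d^2 / sum(d^2)
  axes <- paste0("PC", seq_len(rank))
  scores <- sv$u %*% diag(d, rank, rank)
  dimnames(scores) <- list(rownames(x), axes)
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(x), axes)
  structure(
    list(
      sample_scores = matrix_to_tibble(scores),
      taxon_loadings = bind_cols(tibble(taxon = colnames(x)),
                                 as_tibble(loadings)),
      proportion_explained = setNames(prop, axes),
      singular_values = d,
      converged = converged,
      n_iter = n_iter
    ),
    class = "milkphen_rpca"
  )
}

#' @export
print.milkphen_rpca <- function(x, ...) {
  cat("Robust Aitchison ordination (rank", length(x$singular_values), ")\n")
  cat("Proportion explained:",
      paste(sprintf("%s %.1f%%", names(x$proportion_explained),
                    100 * x$proportion_explained), collapse = ", "), "\n")
  cat(if (x$converged) "Converged" else "Did not converge",
      "after", x$n_iter, "iteration(s)\n")
  invisible(x)
}

#' Aitchison distance between samples
#'
#' Euclidean distance between ordination score rows; with a full-rank fit
#' of a dense clr matrix this is the Aitchison distance, and at rank 3 its
#' low-rank approximation.
#'
#' @param ordination A `milkphen_rpca` object, or a samples-by-axes score
#'   matrix / tibble with a `sample_id` column.
#' @return A symmetric distance matrix with sample IDs as dimnames.
#' @export
aitchison_distance <- function(ordination) {
  scores <- if (inherits(ordination, "milkphen_rpca")) {
    as_feature_matrix(ordination$sample_scores)
  } else if (is.data.frame(ordination)) {
    as_feature_matrix(ordination)
  } else {
    as.matrix(ordination)
  }
  as.matrix(dist(scores))
}

# sum over groups of (within-group sum of squared distances) / group size
permanova_ss_within <- function(d2, groups) {
  ss <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss <- ss + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss
}

#' Permutational multivariate analysis of variance
#'
#' Partitions squared inter-sample distances into between- and within-group
#' components (the standard Gower-centered decomposition):
#' `SS_total = sum(d^2)/n`, `SS_within = sum over groups of within-group
#' sum(d^2)/n_g`, `R^2 = SS_between / SS_total`, and
#' `pseudo-F = (SS_between/(a-1)) / (SS_within/(n-a))`. Significance comes
#' from label permutations with the add-one estimator
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)`, which is never zero.
#'
#' @param dist_matrix Symmetric distance matrix (or `dist` object).
#' @param labels Group labels, one per sample.
#' @param n_permutations Number of label permutations (default 10000).
#' @param seed Integer seed for the permutations.
#' @return An object of class `milkphen_permanova` with `pseudo_F`,
#'   `r_squared`, `p_value`, `n_permutations`, `seed`, `df`.
#' @export
permanova <- function(dist_matrix, labels, n_permutations = 10000, seed = 1L) {
  d <- as.matrix(dist_matrix)
  labels <- as.character(labels)
  n <- nrow(d)
  stopifnot(length(labels) == n)
  a <- length(unique(labels))
  if (a < 2) {
    abort("permanova needs at least two groups", class = "milkphen_input_error")
  }
  d2 <- d^2
  ss_total <- sum(d2) / (2 * n)
  f_stat <- function(gr) {
    ss_w <- permanova_ss_within(d2, gr)
    ss_b <- ss_total - ss_w
    (ss_b / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- f_stat(labels)
  ss_w_obs <- permanova_ss_within(d2, labels)
  r2 <- (ss_total - ss_w_obs) / ss_total
  f_perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) f_stat(sample(labels)),
           numeric(1))
  })
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)
  structure(
    list(pseudo_F = f_obs, r_squared = r2, p_value = p,
         n_permutations = n_permutations, seed = seed,
         df = c(between = a - 1, within = n - a)),
    class = "milkphen_permanova"
  )
}

#' @export
print.milkphen_permanova <- function(x, ...) {
  cat(sprintf("perMANOVA: pseudo-F = %.3f, R^2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$r_squared, x$p_value, x$n_permutations))
  invisible(x)
}

#' One-way ANOVA of a single ordination axis against group labels
#'
#' @param scores_axis Numeric vector of per-sample scores on one axis.
#' @param labels Group labels, one per sample; levels with zero members are
#'   dropped with a warning.
#' @return A one-row tibble with `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
axis_anova <- function(scores_axis, labels) {
  labels <- as.factor(labels)
  empty <- levels(labels)[table(labels) == 0]
  if (length(empty) > 0) {
    warn(paste0("Dropping empty group(s): ", paste(empty, collapse = ", ")))
    labels <- droplevels(labels)
  }
  if (nlevels(labels) < 2) {
    abort("axis_anova needs at least two groups", class = "milkphen_input_error")
  }
  fit <- lm(scores_axis ~ labels)
  av <- anova(fit)
  tibble(statistic = av$`F value`[1], df1 = av$Df[1], df2 = av$Df[2],
         p_value = av$`Pr(>F)`[1])
}
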