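# small fixtures built in code, shared across test files

tiny_counts <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    taxonA = c(2, 0, 1),
    taxonB = c(2, 0, 2),
    taxonC = c(4, 0, 1)
  )
}

# two species in one family plus a family-only taxon, for collapse tests
tiny_taxonomy <- function() {
  tibble::tibble(
    taxon_id = c("taxonA", "taxonB", "taxonC"),
    lineage = c(
      "Bacteria;Firmicutes;Clostridia;Lachnospirales;Lachnospiraceae;Blautia;Blautia wexlerae",
      "Bacteria;Firmicutes;Clostridia;Lachnospirales;Lachnospiraceae;Blautia;Blautia luti",
      "Bacteria;Firmicutes;Clostridia;Oscillospirales;Ruminococcaceae;unclassified;unclassified"
    )
  )
}

# a small cohort config for fast simulation-based tests
small_config <- function(seed = 1, null_effects = FALSE, ...) {
  taxa <- milkphen::default_taxa()
  eff <- if (null_effects) NULL else milkphen::default_effect_table(taxa)
  milkphen::cohort_config(taxa = taxa, effect_table = eff, seed = seed, ...)
}

# family-level log-normalized features for one simulated cohort
cohort_family_features <- function(config) {
  co <- simulate_cohort(config)
  fam1 <- collapse_to_rank(co$month1, co$taxonomy, "family")
  fam6 <- collapse_to_rank(co$month6, co$taxonomy, "family")
  list(
    metadata = co$metadata,
    log1 = log_normalize(relative_abundance(fam1)),
    log6 = log_normalize(relative_abundance(fam6)),
    fam6 = fam6
  )
}

# Procrustes-style alignment error between two score matrices (allows
# rotation/reflection, not scaling): orthogonal-Procrustes residual norm
procrustes_error <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  s <- svd(crossprod(b, a))
  r <- s$u %*% t(s$v)
  sqrt(sum((a - b %*% r)^2)) / sqrt(sum(a^2))
}

# independent studentized-range tail probability by nested numerical
# integration: P(Q > q) for k means and df error degrees of freedom
studentized_range_tail <- function(q, k, df) {
  inner <- function(s) {
    # P(range of k std normals > q*s)
    f <- function(z) {
      stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - q * s))^(k - 1)
    }
    cdf <- k * stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
    1 - cdf
  }
  # density of s = sqrt(chi2_df / df)
  fs <- function(s) {
    2 * s * df * stats::dchisq(df * s^2, df)
  }
  stats::integrate(function(s) {
    vapply(s, function(si) fs(si) * inner(si), numeric(1))
  }, 0, Inf, rel.tol = 1e-9)$value
}
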