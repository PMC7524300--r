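#' Configuration for a full pipeline run
#'
#' Exactly one of `synthetic` (a [cohort_config()]) or `paths` (a named list
#' with `month1`, `month6`, `taxonomy`, `metadata`, `phenotype_ref` TSV
#' paths) must be supplied.
#'
#' @param synthetic A [cohort_config()], or `NULL`.
#' @param paths Named list of input TSV paths, or `NULL`.
#' @param collapse_rank Taxonomic rank for the abundance analysis (default
#'   `"family"`).
#' @param ordination_rank Number of ordination axes (default 3).
#' @param n_perm_permanova Permutations for perMANOVA (default 10000).
#' @param n_perm_fdr Permutations for the FDR CIs (default 1000).
#' @param p_threshold,fdr_upper_threshold Dual significance rule thresholds.
#' @param min_mapped_fraction CPI mapping threshold (default 0.5).
#' @param seed Integer master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, paths = NULL,
                       collapse_rank = "family", ordination_rank = 3,
                       n_perm_permanova = 10000, n_perm_fdr = 1000,
                       p_threshold = 0.05, fdr_upper_threshold = 0.25,
                       min_mapped_fraction = 0.5, seed = 1L) {
  if (is.null(synthetic) == is.null(paths)) {
    abort("Supply exactly one of `synthetic` or `paths`",
          class = "milkphen_config_error")
  }
  if (!is.null(paths)) {
    needed <- c("month1", "month6", "taxonomy", "metadata", "phenotype_ref")
    missing <- setdiff(needed, names(paths))
    if (length(missing) > 0) {
      abort(paste0("Missing input path(s): ", paste(missing, collapse = ", "),
                   " (the 1-month table is required for baseline adjustment)"),
            class = "milkphen_config_error")
    }
  }
  structure(list(synthetic = synthetic, paths = paths,
                 collapse_rank = collapse_rank,
                 ordination_rank = ordination_rank,
                 n_perm_permanova = n_perm_permanova, n_perm_fdr = n_perm_fdr,
                 p_threshold = p_threshold,
                 fdr_upper_threshold = fdr_upper_threshold,
                 min_mapped_fraction = min_mapped_fraction,
                 seed = as.integer(seed)),
            class = "run_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "milkphen_pipeline_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Executes load-or-simulate, taxonomic collapse, relative-abundance and
#' log-normalization, alpha diversity, robust Aitchison ordination with
#' perMANOVA, CPI profiling, and the covariate-adjusted group comparison for
#' the three feature families (alpha diversity, collapsed taxa, CPI). When
#' `out_dir` is given, report TSVs and a JSON manifest (seeds, stage row
#' counts, thresholds) are written; outputs are byte-identical for identical
#' configs.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return Invisibly, a list of results: `metadata`, `alpha`, `ordination`,
#'   `permanova`, `axis_tests`, `cpi`, reports for the three families, and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stages <- character(0)

  inputs <- pipeline_stage("load", {
    if (!is.null(config$synthetic)) {
      simulate_cohort(config$synthetic)
    } else {
      p <- config$paths
      tax <- readr::read_tsv(p$taxonomy, show_col_types = FALSE)
      list(metadata = read_metadata(p$metadata),
           month1 = read_feature_table(p$month1),
           month6 = read_feature_table(p$month6),
           taxonomy = tax,
           phenotype_ref = read_phenotype_matrix(p$phenotype_ref))
    }
  })
  stages <- c(stages, "load")

  collapsed <- pipeline_stage("collapse", {
    list(
      month1 = collapse_to_rank(inputs$month1, inputs$taxonomy,
                                config$collapse_rank),
      month6 = collapse_to_rank(inputs$month6, inputs$taxonomy,
                                config$collapse_rank)
    )
  })
  stages <- c(stages, "collapse")

  abundance <- pipeline_stage("abundance", {
    rel1 <- relative_abundance(collapsed$month1)
    rel6 <- relative_abundance(collapsed$month6)
    list(rel1 = rel1, rel6 = rel6,
         log1 = log_normalize(rel1), log6 = log_normalize(rel6))
  })
  stages <- c(stages, "abundance")

  alpha <- pipeline_stage("alpha", alpha_diversity(collapsed$month6))
  stages <- c(stages, "alpha")

  beta <- pipeline_stage("beta", {
    ord <- rpca(rclr_transform(collapsed$month6),
                rank = config$ordination_rank)
    d <- aitchison_distance(ord)
    pm <- permanova(d, inputs$metadata$group,
                    n_permutations = config$n_perm_permanova,
                    seed = config$seed + 10L)
    axes <- names(ord$proportion_explained)
    axis_tests <- purrr::map_dfr(axes, function(ax) {
      res <- axis_anova(ord$sample_scores[[ax]], inputs$metadata$group)
      bind_cols(tibble(axis = ax), res)
    })
    list(ordination = ord, dist = d, permanova = pm, axis_tests = axis_tests)
  })
  stages <- c(stages, "beta")

  cpi <- pipeline_stage("cpi", {
    res <- community_phenotype_index(
      abundance$rel6, inputs$phenotype_ref,
      min_mapped_fraction = config$min_mapped_fraction)
    list(cpi = res, features = cpi_report(res, inputs$metadata),
         cpi1 = community_phenotype_index(
           abundance$rel1, inputs$phenotype_ref,
           min_mapped_fraction = config$min_mapped_fraction))
  })
  stages <- c(stages, "cpi")

  inference <- pipeline_stage("inference", {
    alpha_features <- alpha[c("sample_id", "shannon", "simpson", "richness",
                              "evenness", "depth")]
    cpi1_features <- cpi$cpi1[setdiff(names(cpi$cpi1), "mapped_fraction")]
    list(
      alpha = comparison_table(
        alpha_features, inputs$metadata,
        n_permutations = config$n_perm_fdr, seed = config$seed + 20L,
        p_threshold = config$p_threshold,
        fdr_upper_threshold = config$fdr_upper_threshold),
      taxa = comparison_table(
        abundance$log6, inputs$metadata, baseline = abundance$log1,
        n_permutations = config$n_perm_fdr, seed = config$seed + 21L,
        p_threshold = config$p_threshold,
        fdr_upper_threshold = config$fdr_upper_threshold),
      cpi = comparison_table(
        cpi$features, inputs$metadata, baseline = cpi1_features,
        n_permutations = config$n_perm_fdr, seed = config$seed + 22L,
        p_threshold = config$p_threshold,
        fdr_upper_threshold = config$fdr_upper_threshold)
    )
  })
  stages <- c(stages, "inference")

  manifest <- list(
    package_version = as.character(utils::packageVersion("milkphen")),
    seed = config$seed,
    stages = stages,
    n_samples = nrow(inputs$metadata),
    n_taxa_collapsed = ncol(collapsed$month6) - 1L,
    n_phenotypes = ncol(inputs$phenotype_ref) - 1L,
    collapse_rank = config$collapse_rank,
    ordination_rank = config$ordination_rank,
    n_perm_permanova = config$n_perm_permanova,
    n_perm_fdr = config$n_perm_fdr,
    thresholds = list(p = config$p_threshold,
                      fdr_ci_upper = config$fdr_upper_threshold),
    permanova = list(r_squared = beta$permanova$r_squared,
                     p_value = beta$permanova$p_value)
  )

  results <- list(metadata = inputs$metadata, collapsed = collapsed,
                  abundance = abundance, alpha = alpha,
                  ordination = beta$ordination, dist = beta$dist,
                  permanova = beta$permanova, axis_tests = beta$axis_tests,
                  cpi = cpi$cpi, reports = inference, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(make_report(inference$alpha), file.path(out_dir, "report_alpha.tsv"))
    write_feature_table(make_report(inference$taxa), file.path(out_dir, "report_taxa.tsv"))
    write_feature_table(make_report(inference$cpi), file.path(out_dir, "report_cpi.tsv"))
    write_feature_table(beta$ordination$sample_scores, file.path(out_dir, "ordination_scores.tsv"))
    write_feature_table(beta$ordination$taxon_loadings,
                        file.path(out_dir, "ordination_loadings.tsv"))
    write_distance_matrix(beta$dist, file.path(out_dir, "aitchison_distance.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(results)
}

#' Render a comparison table in the published layout
#'
#' Formats a [comparison_table()] result with `Mean (SD)` strings per group
#' and star-annotated pairwise differences, one column per contrast.
#'
#' @param comparison A tibble from [comparison_table()].
#' @param digits Significant digits for the formatted numbers.
#' @return A tibble ready to write as a report TSV.
#' @export
make_report <- function(comparison, digits = 3) {
  if (nrow(comparison) == 0) {
    return(tibble(feature = character(0), p_value = numeric(0),
                  fdr_estimate = numeric(0), fdr_ci_upper = numeric(0),
                  significant = logical(0)))
  }
  fmt <- function(x) ifelse(is.na(x), "NA", signif(x, digits))
  groups <- sub("^mean_", "",
                grep("^mean_", names(comparison), value = TRUE))
  contrasts <- sub("^diff_", "",
                   grep("^diff_", names(comparison), value = TRUE))
  out <- tibble(feature = comparison$feature)
  if ("category" %in% names(comparison)) out$category <- comparison$category
  for (g in groups) {
    out[[paste0(g, "_mean_sd")]] <-
      paste0(fmt(comparison[[paste0("mean_", g)]]), " (",
             fmt(comparison[[paste0("sd_", g)]]), ")")
  }
  out$p_value <- comparison$p_value
  for (ct in contrasts) {
    out[[ct]] <- paste0(fmt(comparison[[paste0("diff_", ct)]]),
                        comparison[[paste0("stars_", ct)]])
  }
  out$fdr_estimate <- comparison$fdr_estimate
  out$fdr_ci_upper <- comparison$fdr_ci_upper
  out$significant <- comparison$significant
  out
}
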