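#' Construct a phenotype reference matrix
#'
#' A taxa-by-phenotype table of predicted metabolic capabilities: each entry
#' is the prevalence, in `[0, 1]`, of a phenotype among members of the taxon
#' (values need not be binary so a genus- or family-level row can encode
#' within-group prevalence). Every phenotype carries a category from the five
#' used in community phenotype reporting.
#'
#' @param tbl Tibble with a `taxon` column and one numeric column per
#'   phenotype.
#' @param categories Named character vector mapping phenotype name to one of
#'   `"carbohydrate utilization"`, `"SCFA production"`,
#'   `"amino-acid synthesis"`, `"amino-acid degradation"`,
#'   `"vitamin synthesis"`.
#' @return The tibble with class `phenotype_matrix` and a `categories`
#'   attribute.
#' @export
phenotype_matrix <- function(tbl, categories) {
  stopifnot("taxon" %in% names(tbl))
  phen <- setdiff(names(tbl), "taxon")
  vals <- as.matrix(tbl[phen])
  if (any(vals < 0 | vals > 1, na.rm = TRUE)) {
    abort("Phenotype values must lie in [0, 1]", class = "milkphen_input_error")
  }
  if (anyDuplicated(tbl$taxon) || anyDuplicated(phen)) {
    abort("Taxon and phenotype names must be unique",
          class = "milkphen_input_error")
  }
  missing_cat <- setdiff(phen, names(categories))
  if (length(missing_cat) > 0) {
    abort(paste0("Phenotypes without a category: ",
                 paste(head(missing_cat, 5), collapse = ", ")),
          class = "milkphen_input_error")
  }
  structure(as_tibble(tbl), categories = categories[phen],
            class = c("phenotype_matrix", class(as_tibble(tbl))))
}

# canonical form for taxon-name matching: strip rank prefixes, case-fold,
# collapse separators
canonical_taxon <- function(x) {
  x <- stringr::str_remove(x, "^[a-zA-Z]__")
  x <- tolower(stringr::str_trim(x))
  stringr::str_replace_all(x, "[ _]+", "_")
}

#' Match feature-table taxa against a phenotype reference
#'
#' Exact name matching after case-folding and rank-prefix stripping (no fuzzy
#' matching: a silent mis-mapping is worse than an explicit unmatched
#' report). The per-sample mapped fraction is the total relative abundance
#' carried by matched taxa.
#'
#' @param relab Relative-abundance tibble from [relative_abundance()].
#' @param reference A [phenotype_matrix()].
#' @return A list with `matched` (tibble: `feature`, `reference_taxon`),
#'   `unmatched` (character), and `mapped_fraction` (tibble: `sample_id`,
#'   `mapped_fraction`).
#' @export
match_taxa <- function(relab, reference) {
  feature_taxa <- setdiff(names(relab), "sample_id")
  key_f <- canonical_taxon(feature_taxa)
  key_r <- canonical_taxon(reference$taxon)
  hit <- match(key_f, key_r)
  matched <- tibble(feature = feature_taxa,
                    reference_taxon = reference$taxon[hit])
  unmatched <- feature_taxa[is.na(hit)]
  if (all(is.na(hit))) {
    abort(paste0("No feature taxa found in the phenotype reference. ",
                 "Top unmatched: ",
                 paste(head(feature_taxa, 5), collapse = ", ")),
          class = "milkphen_match_error")
  }
  m <- as_feature_matrix(relab)
  mf <- unname(rowSums(m[, feature_taxa[!is.na(hit)], drop = FALSE]))
  list(matched = matched[!is.na(hit), ],
       unmatched = unmatched,
       mapped_fraction = tibble(sample_id = rownames(m), mapped_fraction = mf))
}

#' Community Phenotype Index
#'
#' The abundance-weighted fraction of a community predicted to carry a
#' metabolic phenotype: for sample `s` and phenotype `p`,
#' `CPI_sp = sum_i a_si * phi_ip / sum_i a_si`, with sums over the taxa
#' matched to the reference. By default the denominator is the mapped
#' abundance (renormalization: the index reads as "fraction of cells *of
#' known phenotype*"); set `unmapped_as_negative = TRUE` to instead count
#' unmatched abundance as phenotype-negative (denominator 1). Samples whose
#' mapped fraction falls below `min_mapped_fraction` get `NA` CPIs and are
#' flagged, never silently dropped.
#'
#' @param relab Relative-abundance tibble from [relative_abundance()].
#' @param reference A [phenotype_matrix()].
#' @param min_mapped_fraction Minimum mapped abundance for a sample's CPIs to
#'   be reported (default 0.5).
#' @param unmapped_as_negative Count unmatched taxa as lacking every
#'   phenotype instead of renormalizing (default `FALSE`).
#' @return An object of class `milkphen_cpi`: a tibble with `sample_id`,
#'   `mapped_fraction`, then one CPI column per phenotype (values in
#'   `[0, 1]`); attributes `categories` and `unmatched`.
#' @export
community_phenotype_index <- function(relab, reference,
                                      min_mapped_fraction = 0.5,
                                      unmapped_as_negative = FALSE) {
  mt <- match_taxa(relab, reference)
  a <- as_feature_matrix(relab)[, mt$matched$feature, drop = FALSE]
  phi <- as.matrix(reference[setdiff(names(reference), "taxon")])
  rownames(phi) <- reference$taxon
  phi <- phi[mt$matched$reference_taxon, , drop = FALSE]
  num <- a %*% phi
  denom <- if (unmapped_as_negative) {
    rowSums(as_feature_matrix(relab))
  } else {
    rowSums(a)
  }
  cpi <- num / denom
  cpi[denom == 0, ] <- NA_real_
  mf <- mt$mapped_fraction$mapped_fraction
  low <- mf < min_mapped_fraction
  if (any(low, na.rm = TRUE)) {
    warn(paste0(sum(low), " sample(s) below min_mapped_fraction; CPIs set to NA"))
    cpi[low, ] <- NA_real_
  }
  out <- bind_cols(tibble(sample_id = rownames(a), mapped_fraction = mf),
                   as_tibble(cpi))
  structure(out, categories = attr(reference, "categories"),
            unmatched = mt$unmatched,
            class = c("milkphen_cpi", class(out)))
}

#' Prepare a CPI table for group inference
#'
#' Drops bookkeeping columns and orders phenotypes by category in the
#' standard report order (carbohydrate utilization, SCFA production,
#' amino-acid synthesis, amino-acid degradation, vitamin synthesis),
#' preserving category labels for the final report.
#'
#' @param cpi A `milkphen_cpi` object.
#' @param metadata Cohort metadata; sample IDs must align with the CPI rows.
#' @return A feature tibble (`sample_id` + one column per phenotype) with a
#'   `categories` attribute, ready for [comparison_table()].
#' @export
cpi_report <- function(cpi, metadata) {
  if (!setequal(cpi$sample_id, metadata$infant_id)) {
    abort("Sample IDs of the CPI table and metadata do not match",
          class = "milkphen_input_error")
  }
  cats <- attr(cpi, "categories")
  order_levels <- c("carbohydrate utilization", "SCFA production",
                    "amino-acid synthesis", "amino-acid degradation",
                    "vitamin synthesis")
  phen <- setdiff(names(cpi), c("sample_id", "mapped_fraction"))
  phen <- phen[order(match(cats[phen], order_levels))]
  out <- cpi[c("sample_id", phen)]
  out <- out[match(metadata$infant_id, out$sample_id), ]
  structure(as_tibble(out), categories = cats[phen], kind = "cpi")
}
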