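TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order",
                     "family", "genus", "species")

#' Parse lineage strings into a 7-rank table
#'
#' Accepts both rank-prefixed (`k__Bacteria;p__Firmicutes;...`) and plain
#' semicolon-separated lineages; the dialect is detected by the presence of
#' `"__"`. Missing trailing ranks, empty fields and the literal
#' `"unclassified"` (any case) all become `NA`.
#'
#' @param lineage Character vector of lineage strings.
#' @return A tibble with columns `kingdom` ... `species` (character, `NA`
#'   where unclassified).
#' @export
parse_lineage <- function(lineage) {
  parts <- stringr::str_split(lineage, ";")
  rows <- purrr::map(parts, function(p) {
    p <- stringr::str_trim(p)
    if (any(stringr::str_detect(p, "__"))) {
      p <- stringr::str_remove(p, "^[a-zA-Z]__")
    }
    p[p == "" | tolower(p) == "unclassified"] <- NA_character_
    length(p) <- length(TAXONOMIC_RANKS)   # pad with NA
    p
  })
  m <- do.call(rbind, rows)
  colnames(m) <- TAXONOMIC_RANKS
  as_tibble(m)
}

# Character vector of labels at `rank`, with taxa unclassified at that rank
# bucketed as "<nearest classified ancestor>{unclassified}".
lineage_rank <- function(lineage, rank) {
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  tab <- parse_lineage(lineage)
  idx <- match(rank, TAXONOMIC_RANKS)
  vapply(seq_len(nrow(tab)), function(i) {
    vals <- as.character(tab[i, seq_len(idx)])
    if (!is.na(vals[idx])) return(vals[idx])
    anc <- vals[!is.na(vals)]
    parent <- if (length(anc) > 0) anc[length(anc)] else "Unclassified"
    paste0(parent, "{unclassified}")
  }, character(1))
}

#' Collapse a taxon count table to a taxonomic rank
#'
#' Counts of taxa sharing the same lineage down to `rank` are summed. Taxa
#' unclassified at that rank are grouped under their nearest classified
#' ancestor with an `{unclassified}` suffix (for example, a taxon classified
#' only to family level collapses at genus rank into
#' `"<Family>{unclassified}"`).
#'
#' @param counts Wide count tibble (`sample_id` + one column per taxon).
#' @param taxonomy Tibble with `taxon_id` and `lineage` covering every count
#'   column.
#' @param rank One of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return A wide count tibble whose columns are the collapsed taxa.
#' @export
collapse_to_rank <- function(counts, taxonomy, rank) {
  if (!rank %in% TAXONOMIC_RANKS) {
    abort(paste0("Unknown rank: ", rank), class = "milkphen_input_error")
  }
  taxa_cols <- setdiff(names(counts), "sample_id")
  missing <- setdiff(taxa_cols, taxonomy$taxon_id)
  if (length(missing) > 0) {
    abort(paste0("Taxa missing from taxonomy: ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "milkphen_input_error")
  }
  lin <- taxonomy$lineage[match(taxa_cols, taxonomy$taxon_id)]
  bucket <- lineage_rank(lin, rank)
  m <- as_feature_matrix(counts)
  collapsed <- t(rowsum(t(m), group = bucket))
  # keep first-appearance column order rather than rowsum's alphabetical order
  collapsed <- collapsed[, unique(bucket), drop = FALSE]
  matrix_to_tibble(collapsed)
}

#' Convert counts to relative abundances
#'
#' Divides each sample's counts by its total. Zero-depth samples stay
#' all-zero and are flagged in the `zero_depth` attribute (and a warning).
#'
#' @param counts Wide count tibble (`sample_id` + taxa columns).
#' @return A wide tibble of the same shape with rows summing to 1 (or 0 for
#'   zero-depth samples); attributes `kind = "relative"` and `zero_depth`.
#' @export
relative_abundance <- function(counts) {
  m <- as_feature_matrix(counts)
  depth <- rowSums(m)
  zero <- depth == 0
  rel <- m
  rel[!zero, ] <- m[!zero, , drop = FALSE] / depth[!zero]
  if (any(zero)) {
    warn(paste0("Zero-depth sample(s) flagged: ",
                paste(rownames(m)[zero], collapse = ", ")))
  }
  out <- matrix_to_tibble(rel)
  attr(out, "kind") <- "relative"
  attr(out, "zero_depth") <- rownames(m)[zero]
  out
}

#' Log-normalize relative abundances
#'
#' The per-feature response used in group comparisons:
#' `log10(scale * p + pseudocount)`. With the defaults (`scale = 1e4`,
#' `pseudocount = 1`) an absent taxon maps to exactly 0 and a pure
#' single-taxon sample to `log10(10001) ~ 4`, reproducing the 0-3.7 range
#' typical of family-level tables. Strictly increasing in `p`.
#'
#' @param relab Relative-abundance tibble from [relative_abundance()].
#' @param scale,pseudocount Transform parameters.
#' @return A wide tibble of log-normalized values, `kind = "log-normalized"`.
#' @export
log_normalize <- function(relab, scale = 1e4, pseudocount = 1) {
  m <- as_feature_matrix(relab)
  if (any(m < 0)) {
    abort("Relative abundances must be nonnegative",
          class = "milkphen_input_error")
  }
  out <- matrix_to_tibble(log10(scale * m + pseudocount))
  attr(out, "kind") <- "log-normalized"
  out
}
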