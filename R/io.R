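#' Read and write feature/count tables as TSV
#'
#' Tables are stored samples-as-rows: a `sample_id` column followed by one
#' column per taxon or feature.
#'
#' @param path File path.
#' @return `read_feature_table()` returns a wide tibble.
#' @export
read_feature_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_feature_table
#' @param tbl Wide tibble to write.
#' @export
write_feature_table <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read cohort metadata from TSV
#'
#' Restores the factor codings the inference module expects: group levels in
#' the canonical feeding-group order, delivery reference `vaginal`, sex
#' reference `female`.
#'
#' @param path File path.
#' @return A metadata tibble.
#' @export
read_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE)
  unknown <- setdiff(unique(meta$group), milk_groups)
  if (length(unknown) > 0) {
    abort(paste0("Unknown group label(s): ", paste(unknown, collapse = ", ")),
          class = "milkphen_input_error")
  }
  meta$group <- factor(meta$group,
                       levels = intersect(milk_groups, unique(meta$group)))
  if ("delivery_mode" %in% names(meta)) {
    meta$delivery_mode <- factor(meta$delivery_mode,
                                 levels = c("vaginal", "c-section"))
  }
  if ("sex" %in% names(meta)) {
    meta$sex <- factor(meta$sex, levels = c("female", "male"))
  }
  meta
}

#' Read and write a phenotype reference matrix
#'
#' File format: first header row of phenotype names (first field `taxon`),
#' second header row of category labels (first field `category`), then one
#' row per taxon with values in `[0, 1]`.
#'
#' @param path File path.
#' @return `read_phenotype_matrix()` returns a [phenotype_matrix()].
#' @export
read_phenotype_matrix <- function(path) {
  lines <- readr::read_lines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  cats <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  body <- readr::read_tsv(I(lines[-2]), show_col_types = FALSE)
  names(body) <- header
  phenotype_matrix(body, categories = setNames(cats[-1], header[-1]))
}

#' @rdname read_phenotype_matrix
#' @param ref A [phenotype_matrix()].
#' @export
write_phenotype_matrix <- function(ref, path) {
  cats <- attr(ref, "categories")
  phen <- setdiff(names(ref), "taxon")
  lines <- c(
    paste(c("taxon", phen), collapse = "\t"),
    paste(c("category", unname(cats[phen])), collapse = "\t"),
    vapply(seq_len(nrow(ref)), function(i) {
      paste(c(ref$taxon[i], format(as.numeric(ref[i, phen]), digits = 15)),
            collapse = "\t")
    }, character(1))
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a count table from a BIOM file
#'
#' Requires the `biomformat` package. The BIOM observation table
#' (taxa-as-rows) is transposed into the package's samples-as-rows layout;
#' embedded `taxonomy` observation metadata, when present, is returned as a
#' lineage table.
#'
#' @param path Path to a BIOM file.
#' @return A list with `counts` (wide tibble) and `taxonomy` (tibble with
#'   `taxon_id`, `lineage`, or `NULL` when the file has no taxonomy
#'   metadata).
#' @export
read_taxon_table_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("Reading BIOM files requires the 'biomformat' package",
          class = "milkphen_input_error")
  }
  b <- biomformat::read_biom(path)
  m <- t(as.matrix(biomformat::biom_data(b)))
  md <- biomformat::observation_metadata(b)
  taxonomy <- NULL
  if (!is.null(md) && length(md) > 0) {
    lineages <- vapply(seq_len(ncol(m)), function(j) {
      entry <- if (is.data.frame(md)) unlist(md[j, ]) else unlist(md[[j]])
      paste(entry, collapse = ";")
    }, character(1))
    taxonomy <- tibble(taxon_id = colnames(m), lineage = lineages)
  }
  list(counts = matrix_to_tibble(m), taxonomy = taxonomy)
}

#' Write a square distance matrix as TSV
#'
#' @param d Distance matrix with sample IDs as dimnames.
#' @param path File path.
#' @export
write_distance_matrix <- function(d, path) {
  readr::write_tsv(matrix_to_tibble(as.matrix(d)), path)
  invisible(path)
}
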