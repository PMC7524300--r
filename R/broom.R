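#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ordination: one row per sample per axis
#'
#' @param x A `milkphen_rpca` object.
#' @param matrix `"scores"` (default) or `"loadings"`.
#' @param ... Unused.
#' @return A long tibble with `sample_id` (or `taxon`), `axis`, `score`,
#'   `proportion_explained`.
#' @export
tidy.milkphen_rpca <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  prop <- tibble(axis = names(x$proportion_explained),
                 proportion_explained = unname(x$proportion_explained))
  if (matrix == "scores") {
    out <- tidyr::pivot_longer(x$sample_scores, -"sample_id",
                               names_to = "axis", values_to = "score")
  } else {
    out <- tidyr::pivot_longer(x$taxon_loadings, -"taxon",
                               names_to = "axis", values_to = "score")
  }
  left_join(out, prop, by = "axis")
}

#' One-row ordination summary
#'
#' @param x A `milkphen_rpca` object.
#' @param ... Unused.
#' @export
glance.milkphen_rpca <- function(x, ...) {
  tibble(rank = length(x$singular_values),
         total_prop_explained = sum(x$proportion_explained),
         converged = x$converged, n_iter = x$n_iter)
}

#' Tidy a perMANOVA result
#'
#' @param x A `milkphen_permanova` object.
#' @param ... Unused.
#' @export
tidy.milkphen_permanova <- function(x, ...) {
  tibble(term = "group", df = unname(x$df["between"]),
         pseudo_F = x$pseudo_F, r_squared = x$r_squared,
         p_value = x$p_value)
}

#' One-row perMANOVA summary
#'
#' @param x A `milkphen_permanova` object.
#' @param ... Unused.
#' @export
glance.milkphen_permanova <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, r_squared = x$r_squared,
         p_value = x$p_value, n_permutations = x$n_permutations,
         seed = x$seed)
}
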