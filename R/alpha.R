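#' Per-sample alpha diversity
#'
#' Shannon index (natural log), Simpson index (`1 - sum p^2`), richness
#' (number of observed taxa), Pielou evenness (`H / ln(richness)`, defined as
#' 0 when richness <= 1 so group means stay computable) and sequencing depth.
#' Zero-depth samples are kept with `NA` metrics and flagged with a warning.
#'
#' @param counts Wide count tibble (`sample_id` + taxa columns).
#' @return A tibble with columns `sample_id`, `shannon`, `simpson`,
#'   `richness`, `evenness`, `depth`.
#' @export
alpha_diversity <- function(counts) {
  m <- as_feature_matrix(counts)
  depth <- rowSums(m)
  zero <- depth == 0
  if (any(zero)) {
    warn(paste0("Zero-depth sample(s), alpha metrics set to NA: ",
                paste(rownames(m)[zero], collapse = ", ")))
  }
  res <- purrr::map(seq_len(nrow(m)), function(i) {
    if (zero[i]) {
      return(tibble(shannon = NA_real_, simpson = NA_real_,
                    richness = NA_integer_, evenness = NA_real_))
    }
    p <- m[i, ] / depth[i]
    p <- p[p > 0]
    h <- -sum(p * log(p))
    rich <- length(p)
    tibble(shannon = h, simpson = 1 - sum(p^2), richness = rich,
           evenness = if (rich > 1) h / log(rich) else 0)
  })
  bind_cols(tibble(sample_id = rownames(m)), bind_rows(res),
            tibble(depth = depth))
}
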