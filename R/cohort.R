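#' Milk-consumption group labels
#'
#' The four feeding groups compared throughout the package: human milk at the
#' breast (`BB`), pumped human milk from a bottle (`BP`), traditional
#' lactose-based formula (`TF`), and lactose-reduced formula with added corn
#' syrup solids (`ASF`).
#'
#' @export
milk_groups <- c("BB", "BP", "TF", "ASF")

#' Reference taxonomy used by the synthetic cohort generator
#'
#' A fixed set of taxa spanning the bacterial families that dominate the
#' infant gut (Bifidobacteriaceae, Enterobacteriaceae, Lachnospiraceae,
#' Bacteroidaceae, ...), each with a 7-rank lineage string. Several families
#' carry more than one member so that rank collapse is a real aggregation.
#'
#' @return A tibble with columns `taxon_id` and `lineage`.
#' @export
default_taxa <- function() {
  spec <- list(
    # family = c(kingdom, phylum, class, order), genera as names of species vectors
    Bifidobacteriaceae = list(
      up = c("Bacteria", "Actinobacteria", "Actinobacteria", "Bifidobacteriales"),
      Bifidobacterium = c("longum", "breve", "bifidum")
    ),
    Coriobacteriaceae = list(
      up = c("Bacteria", "Actinobacteria", "Coriobacteriia", "Coriobacteriales"),
      Collinsella = c("aerofaciens")
    ),
    Atopobiaceae = list(
      up = c("Bacteria", "Actinobacteria", "Coriobacteriia", "Coriobacteriales"),
      Atopobium = c("parvulum")
    ),
    Micrococcaceae = list(
      up = c("Bacteria", "Actinobacteria", "Actinobacteria", "Micrococcales"),
      Rothia = c("mucilaginosa")
    ),
    Bacteroidaceae = list(
      up = c("Bacteria", "Bacteroidetes", "Bacteroidia", "Bacteroidales"),
      Bacteroides = c("fragilis", "vulgatus", "uniformis")
    ),
    Enterobacteriaceae = list(
      up = c("Bacteria", "Proteobacteria", "Gammaproteobacteria", "Enterobacterales"),
      Escherichia = c("coli"),
      Klebsiella = c("pneumoniae", "oxytoca"),
      Enterobacter = c("cloacae")
    ),
    Lachnospiraceae = list(
      up = c("Bacteria", "Firmicutes", "Clostridia", "Lachnospirales"),
      Blautia = c("wexlerae", "luti"),
      Anaerostipes = c("hadrus"),
      Roseburia = c("intestinalis"),
      Fusicatenibacter = c("saccharivorans")
    ),
    Ruminococcaceae = list(
      up = c("Bacteria", "Firmicutes", "Clostridia", "Oscillospirales"),
      Faecalibacterium = c("prausnitzii"),
      Ruminococcus = c("bromii"),
      unclassified = c("unclassified")
    ),
    Peptostreptococcaceae = list(
      up = c("Bacteria", "Firmicutes", "Clostridia", "Peptostreptococcales"),
      Clostridioides = c("difficile"),
      Romboutsia = c("ilealis")
    ),
    Clostridiaceae = list(
      up = c("Bacteria", "Firmicutes", "Clostridia", "Clostridiales"),
      Clostridium = c("perfringens", "butyricum")
    ),
    Lactobacillaceae = list(
      up = c("Bacteria", "Firmicutes", "Bacilli", "Lactobacillales"),
      Lactobacillus = c("gasseri", "rhamnosus")
    ),
    Streptococcaceae = list(
      up = c("Bacteria", "Firmicutes", "Bacilli", "Lactobacillales"),
      Streptococcus = c("salivarius", "thermophilus")
    ),
    Enterococcaceae = list(
      up = c("Bacteria", "Firmicutes", "Bacilli", "Lactobacillales"),
      Enterococcus = c("faecalis")
    ),
    Erysipelotrichaceae = list(
      up = c("Bacteria", "Firmicutes", "Bacilli", "Erysipelotrichales"),
      Erysipelatoclostridium = c("ramosum"),
      Holdemanella = c("biformis")
    ),
    Veillonellaceae = list(
      up = c("Bacteria", "Firmicutes", "Negativicutes", "Veillonellales"),
      Veillonella = c("parvula", "dispar")
    ),
    Acidaminococcaceae = list(
      up = c("Bacteria", "Firmicutes", "Negativicutes", "Acidaminococcales"),
      Phascolarctobacterium = c("faecium"),
      Acidaminococcus = c("intestini")
    )
  )
  rows <- purrr::imap(spec, function(fam, fam_name) {
    up <- fam$up
    genera <- fam[setdiff(names(fam), "up")]
    purrr::imap(genera, function(species, genus) {
      purrr::map(species, function(sp) {
        if (genus == "unclassified") {
          lineage <- paste(c(up, fam_name, "unclassified", "unclassified"),
                           collapse = ";")
          id <- paste0(fam_name, "_unclassified")
        } else {
          lineage <- paste(c(up, fam_name, genus, paste(genus, sp)),
                           collapse = ";")
          id <- paste0(genus, "_", gsub(" ", "_", sp))
        }
        tibble(taxon_id = id, lineage = lineage)
      })
    })
  })
  out <- bind_rows(purrr::flatten(purrr::flatten(rows)))
  stopifnot(!anyDuplicated(out$taxon_id))
  out
}

# Baseline mean log abundances (natural log, arbitrary origin) chosen so the
# softmax composition resembles a 6-month infant gut: Bifidobacteriaceae,
# Enterobacteriaceae and Bacteroidaceae dominant, rarer families 2-4 log
# units down.
default_base_log_abundances <- function(taxa = default_taxa()) {
  fam <- lineage_rank(taxa$lineage, "family")
  base_by_family <- c(
    Bifidobacteriaceae = 3.2, Enterobacteriaceae = 3.0, Bacteroidaceae = 2.8,
    Lachnospiraceae = 1.6, Ruminococcaceae = 0.6, Veillonellaceae = 1.8,
    Streptococcaceae = 1.6, Clostridiaceae = 1.0, Peptostreptococcaceae = 0.6,
    Lactobacillaceae = 0.6, Erysipelotrichaceae = 0.4, Enterococcaceae = 0.4,
    Coriobacteriaceae = 0.2, Micrococcaceae = -0.2, Atopobiaceae = -0.4,
    Acidaminococcaceae = -0.8
  )
  vals <- base_by_family[fam]
  names(vals) <- taxa$taxon_id
  # spread members of a family a little so species are not exchangeable
  offsets <- stats::ave(seq_along(vals), fam, FUN = function(i) {
    seq_along(i) - (length(i) + 1) / 2
  })
  vals + 0.3 * offsets
}

#' Default per-taxon group effects emulating the published family shifts
#'
#' Additive shifts (natural-log scale, applied to all members of a family at
#' 6 months only) whose directions match the reported enrichment of
#' Lachnospiraceae, Ruminococcaceae, Peptostreptococcaceae, Erysipelotrichaceae
#' and Acidaminococcaceae in formula-fed infants and depletion of
#' Bifidobacteriaceae, Enterobacteriaceae and Lactobacillaceae.
#'
#' @param taxa Tibble with `taxon_id`, `lineage` (default [default_taxa()]).
#' @return A taxa-by-group numeric matrix; the `BB` column is zero (reference).
#' @export
default_effect_table <- function(taxa = default_taxa()) {
  fam <- lineage_rank(taxa$lineage, "family")
  eff <- matrix(0, nrow(taxa), length(milk_groups),
                dimnames = list(taxa$taxon_id, milk_groups))
  shifts <- list(
    Lachnospiraceae        = c(BP = 0.5,  TF = 0.9,  ASF = 1.2),
    Ruminococcaceae        = c(BP = 0.8,  TF = 2.0,  ASF = 2.2),
    Peptostreptococcaceae  = c(BP = 0.3,  TF = 0.8,  ASF = 1.0),
    Erysipelotrichaceae    = c(BP = 0.0,  TF = 0.8,  ASF = 1.0),
    Acidaminococcaceae     = c(BP = 0.0,  TF = 0.1,  ASF = 1.0),
    Bifidobacteriaceae     = c(BP = -0.2, TF = -0.8, ASF = -1.2),
    Enterobacteriaceae     = c(BP = -0.5, TF = -0.6, ASF = -0.8),
    Lactobacillaceae       = c(BP = 0.4,  TF = -0.8, ASF = -0.6),
    Micrococcaceae         = c(BP = -0.4, TF = -0.6, ASF = -0.8)
  )
  for (f in names(shifts)) {
    for (g in names(shifts[[f]])) {
      eff[fam == f, g] <- shifts[[f]][[g]]
    }
  }
  eff
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the generator: group sizes, the taxon set with
#' baseline log abundances, 6-month group effects, the per-infant random
#' effect linking the 1- and 6-month samples, Dirichlet-multinomial
#' dispersion, sequencing-depth distribution, covariate distributions and the
#' seed. Defaults reproduce the structure of the motivating cohort: 91
#' infants in groups of 14/19/30/28, ~25,000 reads per sample, and
#' family-level feeding-group shifts at 6 months.
#'
#' @param group_sizes Named integer vector, one entry per feeding group.
#' @param taxa Tibble with `taxon_id` and 7-rank `lineage`.
#' @param base_log_abundances Numeric vector, one baseline log abundance per
#'   taxon (natural log, arbitrary origin; compositions come out of a softmax).
#' @param effect_table Taxa-by-group matrix of additive log shifts applied at
#'   6 months only, or `NULL` for no group effects.
#' @param infant_effect_sd SD of the per-infant Gaussian random effect shared
#'   by the 1- and 6-month samples (induces baseline correlation).
#' @param dispersion Dirichlet concentration scalar; smaller values give more
#'   over-dispersed, sparser counts.
#' @param depth_mean,depth_sd Normal parameters for per-sample sequencing
#'   depth (reads), truncated below at 1000.
#' @param covariate_params Named list of `c(mean, sd)` pairs for
#'   `mother_age` (years), `prepregnancy_bmi`, `bmi_increment` (positive
#'   pregnancy-attributable BMI gain), `age_days`, `weight_kg`.
#' @param p_female,p_vaginal Probabilities of female sex and vaginal delivery.
#' @param n_phenotypes Number of columns in the synthetic phenotype reference.
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(group_sizes = c(BB = 14, BP = 19, TF = 30, ASF = 28),
                          taxa = default_taxa(),
                          base_log_abundances = default_base_log_abundances(taxa),
                          effect_table = default_effect_table(taxa),
                          infant_effect_sd = 0.5,
                          dispersion = 50,
                          depth_mean = 25000,
                          depth_sd = 4000,
                          covariate_params = list(
                            mother_age       = c(mean = 29.5, sd = 6),
                            prepregnancy_bmi = c(mean = 27.5, sd = 5.3),
                            bmi_increment    = c(mean = 2.5,  sd = 1.5),
                            age_days         = c(mean = 184,  sd = 8),
                            weight_kg        = c(mean = 7.95, sd = 0.75)
                          ),
                          p_female = 0.52,
                          p_vaginal = 0.78,
                          n_phenotypes = 25,
                          seed = 1L) {
  unknown <- setdiff(names(group_sizes), milk_groups)
  if (length(unknown) > 0) {
    abort(paste0("Unknown group label(s) in group_sizes: ",
                 paste(unknown, collapse = ", ")),
          class = "milkphen_config_error")
  }
  if (any(group_sizes < 0)) {
    abort("group_sizes must be nonnegative", class = "milkphen_config_error")
  }
  if (is.null(effect_table)) {
    effect_table <- matrix(0, nrow(taxa), length(milk_groups),
                           dimnames = list(taxa$taxon_id, milk_groups))
  }
  if (!all(names(group_sizes) %in% colnames(effect_table))) {
    abort("effect_table must have one column per declared group",
          class = "milkphen_config_error")
  }
  if (length(base_log_abundances) != nrow(taxa)) {
    abort("base_log_abundances must have one entry per taxon",
          class = "milkphen_config_error")
  }
  if (dispersion <= 0 || depth_mean <= 0) {
    abort("dispersion and depth_mean must be positive",
          class = "milkphen_config_error")
  }
  if (infant_effect_sd < 0) {
    abort("infant_effect_sd must be nonnegative",
          class = "milkphen_config_error")
  }
  if (n_phenotypes < 1) {
    abort("n_phenotypes must be at least 1", class = "milkphen_config_error")
  }
  structure(
    list(group_sizes = group_sizes, taxa = taxa,
         base_log_abundances = base_log_abundances,
         effect_table = effect_table, infant_effect_sd = infant_effect_sd,
         dispersion = dispersion, depth_mean = depth_mean, depth_sd = depth_sd,
         covariate_params = covariate_params, p_female = p_female,
         p_vaginal = p_vaginal, n_phenotypes = n_phenotypes,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate per-infant metadata
#'
#' Draws one row per infant: feeding group, sex, age in days, weight,
#' delivery mode, maternal age, pre-pregnancy BMI and current BMI. Current
#' BMI is pre-pregnancy BMI plus a positive Gaussian increment, preserving
#' the ordering seen in real cohorts. Deterministic given the config seed.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per infant.
#' @export
simulate_metadata <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  gs <- config$group_sizes
  n <- sum(gs)
  cp <- config$covariate_params
  with_seed(config$seed, {
    group <- factor(rep(names(gs), gs), levels = milk_groups)
    prepreg <- rnorm(n, cp$prepregnancy_bmi["mean"], cp$prepregnancy_bmi["sd"])
    tibble(
      infant_id = sprintf("infant_%03d", seq_len(n)),
      group = group,
      sex = factor(ifelse(rbinom(n, 1, config$p_female) == 1, "female", "male"),
                   levels = c("female", "male")),
      age_days = round(rnorm(n, cp$age_days["mean"], cp$age_days["sd"])),
      weight_kg = round(rnorm(n, cp$weight_kg["mean"], cp$weight_kg["sd"]), 2),
      mother_age = round(rnorm(n, cp$mother_age["mean"], cp$mother_age["sd"]), 1),
      prepregnancy_bmi = round(prepreg, 1),
      current_bmi = round(prepreg +
        abs(rnorm(n, cp$bmi_increment["mean"], cp$bmi_increment["sd"])), 1),
      delivery_mode = factor(
        ifelse(rbinom(n, 1, config$p_vaginal) == 1, "vaginal", "c-section"),
        levels = c("vaginal", "c-section"))
    )
  })
}

# Dirichlet draw: one row per sample
rdirichlet_rows <- function(alpha_matrix) {
  g <- matrix(rgamma(length(alpha_matrix), shape = alpha_matrix),
              nrow = nrow(alpha_matrix))
  sweep(g, 1, rowSums(g), "/")
}

#' Simulate paired 1- and 6-month taxon count tables
#'
#' For each infant, the expected composition is
#' `softmax(base_log_abundances + infant_effect + group_effect)`, where the
#' per-infant Gaussian effect is shared by both timepoints and the group
#' effect from `effect_table` applies at 6 months only. Counts are drawn from
#' a Dirichlet-multinomial (Dirichlet parameters `dispersion * composition`)
#' at a depth drawn from `Normal(depth_mean, depth_sd)`.
#'
#' @param config A [cohort_config()].
#' @param metadata Metadata generated from the same config by
#'   [simulate_metadata()].
#' @return A list with elements `month1` and `month6` (wide count tibbles,
#'   first column `sample_id`, then one column per taxon) and `taxonomy`
#'   (the `taxa` tibble of the config).
#' @export
simulate_counts <- function(config, metadata) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(metadata)
  taxa_ids <- config$taxa$taxon_id
  k <- length(taxa_ids)
  base <- config$base_log_abundances

  with_seed(config$seed + 1L, {
    infant_eff <- matrix(rnorm(n * k, 0, config$infant_effect_sd), n, k)
    draw_table <- function(with_group_effect) {
      logab <- matrix(base, n, k, byrow = TRUE) + infant_eff
      if (with_group_effect) {
        logab <- logab + t(config$effect_table[, as.character(metadata$group),
                                               drop = FALSE])
      }
      comp <- exp(logab - apply(logab, 1, max))
      comp <- sweep(comp, 1, rowSums(comp), "/")
      p <- rdirichlet_rows(config$dispersion * comp)
      depth <- pmax(1000, round(rnorm(n, config$depth_mean, config$depth_sd)))
      counts <- t(vapply(seq_len(n),
                         function(i) rmultinom(1, depth[i], p[i, ])[, 1],
                         numeric(k)))
      dimnames(counts) <- list(metadata$infant_id, taxa_ids)
      matrix_to_tibble(counts)
    }
    list(month1 = draw_table(FALSE), month6 = draw_table(TRUE),
         taxonomy = config$taxa)
  })
}

# The 25 metabolic phenotypes of the motivating analysis, grouped into the
# five reported categories.
default_phenotype_catalog <- function() {
  tibble(
    phenotype = c(
      "Galactitol", "Glucoronides", "Lactose", "Glucosamine", "Mannitol",
      "N-acetylgalactosamine", "Psicoselysine", "Alpha-xylosides", "Gluconate",
      "Trehalose", "Fructoselysine", "Raffinose", "Melibiose",
      "Beta-arabinosides", "Sorbitol", "Arabinose", "Fructose", "Lacto-N-biose",
      "Rhamnose",
      "Propionate",
      "Cysteine", "Threonine",
      "Lysine", "Methionine",
      "B12 (cobalamin)"
    ),
    category = c(
      rep("carbohydrate utilization", 19),
      "SCFA production",
      rep("amino-acid synthesis", 2),
      rep("amino-acid degradation", 2),
      "vitamin synthesis"
    )
  )
}

#' Simulate a taxa-by-phenotype reference matrix
#'
#' Stand-in for a curated collection of predicted metabolic capabilities:
#' each entry is the prevalence (in `[0, 1]`) of a phenotype among the
#' members of a taxon. The first `min(n_phenotypes, 25)` phenotypes take the
#' names and categories of the package's metabolite catalog; any further
#' columns are generic carbohydrate-utilization phenotypes. Entries are Beta
#' draws (optionally thresholded to binary).
#'
#' @param config A [cohort_config()].
#' @param taxa Character vector of taxon names for the reference rows.
#' @param binary If `TRUE`, entries are 0/1 presence calls instead of
#'   prevalences.
#' @param constant If non-`NULL`, every entry is set to this value (useful for
#'   saturation checks).
#' @return A `phenotype_matrix`: tibble with a `taxon` column and one column
#'   per phenotype, carrying a `categories` attribute (named character
#'   vector, phenotype -> category).
#' @export
simulate_phenotype_reference <- function(config, taxa, binary = FALSE,
                                         constant = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(taxa) == 0) {
    abort("taxa must be non-empty", class = "milkphen_config_error")
  }
  np <- config$n_phenotypes
  catalog <- default_phenotype_catalog()
  if (np <= nrow(catalog)) {
    catalog <- catalog[seq_len(np), ]
  } else {
    extra <- tibble(
      phenotype = sprintf("Phenotype_%02d", seq_len(np - nrow(catalog))),
      category = "carbohydrate utilization"
    )
    catalog <- bind_rows(catalog, extra)
  }
  with_seed(config$seed + 2L, {
    vals <- matrix(rbeta(length(taxa) * np, 0.6, 0.9), length(taxa), np,
                   dimnames = list(taxa, catalog$phenotype))
    if (binary) vals <- round(vals)
    if (!is.null(constant)) vals[] <- constant
    phenotype_matrix(
      bind_cols(tibble(taxon = taxa), as_tibble(vals)),
      categories = setNames(catalog$category, catalog$phenotype)
    )
  })
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running [simulate_metadata()], [simulate_counts()] and
#' [simulate_phenotype_reference()] (with reference rows at family rank so it
#' matches family-collapsed tables) in one call.
#'
#' @param config A [cohort_config()].
#' @return A list with `metadata`, `month1`, `month6`, `taxonomy`,
#'   `phenotype_ref` and the `config` itself.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  metadata <- simulate_metadata(config)
  counts <- simulate_counts(config, metadata)
  families <- unique(lineage_rank(config$taxa$lineage, "family"))
  ref <- simulate_phenotype_reference(config, families)
  list(metadata = metadata, month1 = counts$month1, month6 = counts$month6,
       taxonomy = counts$taxonomy, phenotype_ref = ref, config = config)
}
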