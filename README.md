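# milkphen

Tools for comparing the gut microbiota of infants across four
milk-consumption groups: human milk at the breast (**BB**), pumped human
milk from a bottle (**BP**), traditional lactose-based formula (**TF**),
and lactose-reduced formula with added corn syrup solids (**ASF**). The
package is aimed at microbiome analysts working with paired 1- and 6-month
16S-derived taxon count tables, per-infant covariates, and a reference
matrix of predicted metabolic phenotypes — and at anyone who wants to
stress-test this analysis design on simulated cohorts before trusting it on
real ones.

## What it computes

* **Community Phenotype Index (CPI)** — the abundance-weighted fraction of
  a community predicted to carry a metabolic phenotype (carbohydrate
  utilization, SCFA production, amino-acid synthesis/degradation, vitamin
  synthesis):

  CPI<sub>sp</sub> = Σ<sub>i∈M</sub> a<sub>si</sub> φ<sub>ip</sub> / Σ<sub>i∈M</sub> a<sub>si</sub>,

  with φ<sub>ip</sub> ∈ [0,1] the phenotype prevalence of taxon *i* in the
  reference and *M* the taxa matched by exact name. The denominator
  renormalizes over the mapped abundance; samples mapping less than a
  configurable fraction are flagged.

* **Beta diversity by robust Aitchison ordination** — the robust clr
  transform (zeros treated as missing) followed by rank-3 PCA via iterative
  SVD matrix completion; Euclidean distances between sample scores
  approximate Aitchison distance. Group separation is tested by
  **perMANOVA** (pseudo-F, R², permutation p with the add-one estimator)
  and per-axis one-way ANOVAs.

* **Alpha diversity** — Shannon (nats), Simpson, richness, Pielou evenness,
  sequencing depth.

* **Covariate-adjusted group comparison** — per feature, the 6-month value
  is modeled as

  `feature_6mo ~ group + mother_age + prepregnancy_bmi + delivery_mode +
  current_bmi + sex + age_days + weight_kg + feature_1mo`,

  with the overall p from the F-test against the reduced model without
  `group`, Tukey–Kramer pairwise contrasts on the covariate-adjusted
  response, a permutation FDR confidence interval per feature family, and
  the dual significance rule: overall p < 0.05 **and** FDR CI upper limit
  < 0.25.

* **A synthetic cohort generator** — Dirichlet-multinomial counts over a
  softmax composition with per-infant random effects, 6-month group shifts
  on selected families, and realistic covariates, defaulting to the
  motivating study's structure (91 infants, groups of 14/19/30/28,
  ~25,000 reads/sample).

See `vignettes/milkphen-methods.Rmd` for the model details, parameter
defaults and validation design.

## Worked example

```r
library(milkphen)

cohort <- simulate_cohort(cohort_config(seed = 2024))
fam6 <- collapse_to_rank(cohort$month6, cohort$taxonomy, "family")
fam1 <- collapse_to_rank(cohort$month1, cohort$taxonomy, "family")

ord <- rpca(rclr_transform(fam6))
#> Robust Aitchison ordination (rank 3)
#> Proportion explained: PC1 56.0%, PC2 31.8%, PC3 12.2%

permanova(aitchison_distance(ord), cohort$metadata$group,
          n_permutations = 10000, seed = 1)
#> perMANOVA: pseudo-F = 3.177, R^2 = 0.0987, p = 0.0029 (10000 permutations)
```

The three retained axes explain all of the modeled variation by
construction; the perMANOVA says milk-consumption group accounts for ~10%
of the distance variance among these simulated infants, far beyond chance.

```r
ct <- comparison_table(log_normalize(relative_abundance(fam6)),
                       cohort$metadata,
                       baseline = log_normalize(relative_abundance(fam1)),
                       n_permutations = 1000, seed = 1)
make_report(ct)[c("feature", "BB_mean_sd", "ASF_mean_sd",
                  "p_value", "ASF_BB", "significant")]
#>    feature               BB_mean_sd    ASF_mean_sd    p_value ASF_BB    significant
#>  1 Bifidobacteriaceae    3.45 (0.111)  2.88 (0.195)  7.17e-20 -0.519****  TRUE
#>  7 Lachnospiraceae       2.95 (0.271)  3.46 (0.132)  6.61e-15 0.515****   TRUE
#>  8 Ruminococcaceae       2.12 (0.601)  3.18 (0.129)  1.08e-15 0.986****   TRUE
#> 16 Acidaminococcaceae    0.99 (0.875)  1.26 (0.889)  2.96e- 2 0.384       TRUE
#> ...
```

Each row gives per-group mean (SD) of the log-normalized abundance, the
full-vs-reduced ANOVA p for the group term, the covariate-adjusted ASF−BB
difference with its Tukey star code, and the dual-rule significance flag.
The generator's injected family shifts (Lachnospiraceae up in formula
groups, Bifidobacteriaceae down, and so on) come back with the right signs.

CPI profiling works the same way on relative abundances plus a phenotype
reference:

```r
cpi <- community_phenotype_index(relative_abundance(fam6),
                                 cohort$phenotype_ref)
cpi[1:3, 1:5]
#>   sample_id  mapped_fraction Galactitol Glucoronides Lactose
#> 1 infant_001               1      0.480        0.222   0.675
#> 2 infant_002               1      0.470        0.174   0.642
#> 3 infant_003               1      0.589        0.207   0.577
```

`run_pipeline(run_config(synthetic = cohort_config(seed = 1)), out_dir = "out")`
runs every stage and writes the three report TSVs (alpha diversity, taxon
families, CPI phenotypes), ordination scores/loadings, the distance matrix,
and a JSON manifest of seeds and settings.

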