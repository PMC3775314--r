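#' Simulation configuration for the synthetic study system
#'
#' Builds the single configuration object consumed by every generator in the
#' package. The defaults describe the study system the analysis chain was
#' designed around: eight case-control postmortem expression studies (two
#' DLPFC, four ACC, two amygdala; half performed in female subjects; 9-21
#' matched pairs each) with a larger planted SST deficit in female MDD; a
#' 214-subject two-region control cohort carrying a correlated GABA gene
#' module; an X-chromosome genotype panel (136 hemizygous males, 34 diploid
#' females) with LD blocks and sex-specific trans/cis effects on GABA genes;
#' and a 2x2x2 Four Core Genotypes mouse design with planted main effects on
#' expression and behavioral endpoints.
#'
#' All planted effects are expressed in units of the residual (noise) SD so
#' downstream recovery can be asserted on a standardized scale.
#'
#' @param seed integer; master seed. Every generator derives its own
#'   sub-stream from it, so identical config + seed gives bit-identical
#'   output.
#' @param study_designs tibble with columns `study_id`, `sex`
#'   (`"male"`/`"female"`), `region` (`"DLPFC"`/`"ACC"`/`"AMY"`), `n_pairs`,
#'   and list-column `declared_covariates` (covariate names adjusted for that
#'   study's seed-gene analysis).
#' @param effect_female,effect_male planted standardized mean difference
#'   (MDD minus control, SD units) of the target gene in female/male studies.
#' @param target_gene gene receiving the planted case-control effect.
#' @param covariate_effects named numeric; expression units per covariate
#'   unit, added to every gene.
#' @param module_genes genes sharing the latent co-expression factor.
#' @param module_loading loading of module genes on the shared factor, in
#'   `[0, 1]`; expected pairwise module correlation is `module_loading^2`.
#' @param gaba_panel gene panel used for the GABA co-expression network.
#' @param n_background_genes number of unrelated background genes.
#' @param n_coexpr_subjects subjects in the two-region co-expression cohort.
#' @param n_male,n_female eQTL cohort stratum sizes.
#' @param n_snps,ld_block_size,ld_r2,maf X-chromosome genotype panel: SNP
#'   count, SNPs per LD block, target within-block squared correlation, and
#'   minor-allele frequency.
#' @param n_x_genes number of simulated X-chromosome transcripts.
#' @param trans_effects tibble (`snp`, `gene`, `stratum`, `beta`): planted
#'   trans effects, beta in residual-SD units per alternate allele.
#' @param cis_effects tibble (`snp`, `gene`, `stratum`, `beta`): planted cis
#'   effects on X transcripts.
#' @param control_genes genes guaranteed free of genotype effects, used as
#'   negative controls.
#' @param fcg_cell_sizes named integer vector of animals per design cell;
#'   names are `<geneticsex>_<gonadalsex>_<treatment>`.
#' @param fcg_effects tibble (`endpoint`, `genetic_delta`, `gonadal_delta`,
#'   `treatment_delta`, `interaction_delta`), deltas in endpoint-SD units.
#'   `genetic_delta` is XY minus XX, `gonadal_delta` gonadal male minus
#'   female, `treatment_delta` testosterone minus blank; the interaction
#'   delta is added to the gonadal-male + testosterone cell only.
#' @param fcg_scales tibble (`endpoint`, `mean`, `sd`) giving each endpoint's
#'   baseline location and noise SD in its natural units.
#' @param baseline_mean baseline expression level (arbitrary log-scale
#'   units) for simulated human expression values.
#' @param noise_sd residual SD of simulated expression.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$study_designs
#' @export
sim_config <- function(seed = NULL,
                       study_designs = default_study_designs(),
                       effect_female = -0.8,
                       effect_male = -0.3,
                       target_gene = "SST",
                       covariate_effects = c(age = -0.01, pmi = -0.005,
                                             ph = 0.3, rin = 0.25,
                                             alcohol = -0.2, suicide = -0.15),
                       module_genes = c("SST", "GAD67", "GAD65",
                                        "CALB1", "GABRA5"),
                       module_loading = 0.85,
                       gaba_panel = c("SST", "PV", "NPY", "CR", "CALB1",
                                      "VIP", "CCK", "GABRA1", "GABRA2",
                                      "GABRA5", "GAD67", "GAD65", "GAT1"),
                       n_background_genes = 50L,
                       n_coexpr_subjects = 214L,
                       n_male = 136L,
                       n_female = 34L,
                       n_snps = 500L,
                       ld_block_size = 10L,
                       ld_r2 = 0.8,
                       maf = 0.3,
                       n_x_genes = 20L,
                       trans_effects = default_trans_effects(),
                       cis_effects = default_cis_effects(),
                       control_genes = c("KDM5C", "C2orf49"),
                       fcg_cell_sizes = default_fcg_cell_sizes(),
                       fcg_effects = default_fcg_effects(),
                       fcg_scales = default_fcg_scales(),
                       baseline_mean = 5,
                       noise_sd = 1) {
  cfg <- list(
    seed = seed, study_designs = study_designs,
    effect_female = effect_female, effect_male = effect_male,
    target_gene = target_gene, covariate_effects = covariate_effects,
    module_genes = module_genes, module_loading = module_loading,
    gaba_panel = gaba_panel, n_background_genes = n_background_genes,
    n_coexpr_subjects = n_coexpr_subjects,
    n_male = n_male, n_female = n_female,
    n_snps = n_snps, ld_block_size = ld_block_size,
    ld_r2 = ld_r2, maf = maf, n_x_genes = n_x_genes,
    trans_effects = trans_effects, cis_effects = cis_effects,
    control_genes = control_genes,
    fcg_cell_sizes = fcg_cell_sizes, fcg_effects = fcg_effects,
    fcg_scales = fcg_scales,
    baseline_mean = baseline_mean, noise_sd = noise_sd
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  studies:      ", nrow(x$study_designs), " (",
      sum(x$study_designs$sex == "female"), " female)\n", sep = "")
  cat("  planted g:    female ", x$effect_female, ", male ",
      x$effect_male, " on ", x$target_gene, "\n", sep = "")
  cat("  module:       ", paste(x$module_genes, collapse = ", "),
      " (loading ", x$module_loading, ")\n", sep = "")
  cat("  genotypes:    ", x$n_snps, " X SNPs, blocks of ", x$ld_block_size,
      " (r2 ", x$ld_r2, ", MAF ", x$maf, "); ", x$n_male, " M / ",
      x$n_female, " F\n", sep = "")
  cat("  FCG cells:    ", paste(x$fcg_cell_sizes, collapse = "/"), "\n",
      sep = "")
  invisible(x)
}

validate_sim_config <- function(cfg) {
  sd_ <- cfg$study_designs
  if (!is.data.frame(sd_) ||
      !all(c("study_id", "sex", "region", "n_pairs",
             "declared_covariates") %in% names(sd_))) {
    abort_config("study_designs",
                 "must have columns study_id, sex, region, n_pairs, declared_covariates")
  }
  if (anyDuplicated(sd_$study_id)) {
    abort_config("study_designs", "has duplicated study_id values")
  }
  if (!all(sd_$sex %in% c("male", "female"))) {
    abort_config("study_designs", "sex must be 'male' or 'female'")
  }
  if (!all(sd_$n_pairs >= 2)) {
    abort_config("study_designs", "needs n_pairs >= 2 in every study")
  }
  if (!is.numeric(cfg$module_loading) || cfg$module_loading < 0 ||
      cfg$module_loading > 1) {
    abort_config("module_loading", "must lie in [0, 1]")
  }
  if (!is.numeric(cfg$maf) || cfg$maf <= 0 || cfg$maf > 0.5) {
    abort_config("maf", "must lie in (0, 0.5]")
  }
  if (!is.numeric(cfg$ld_r2) || cfg$ld_r2 < 0 || cfg$ld_r2 > 1) {
    abort_config("ld_r2", "must lie in [0, 1]")
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0) {
    abort_config("noise_sd", "must be positive")
  }
  if (cfg$ld_block_size < 1) abort_config("ld_block_size", "must be >= 1")
  if (cfg$n_snps < 1) abort_config("n_snps", "must be >= 1")
  if (length(cfg$fcg_cell_sizes) != 8L ||
      !setequal(names(cfg$fcg_cell_sizes), fcg_cell_names())) {
    abort_config("fcg_cell_sizes",
                 paste("must name all eight cells:",
                       paste(fcg_cell_names(), collapse = ", ")))
  }
  if (any(cfg$fcg_cell_sizes < 2)) {
    abort_config("fcg_cell_sizes", "needs n >= 2 in every cell")
  }
  snp_universe <- sprintf("snp_%05d", seq_len(cfg$n_snps))
  for (f in c("trans_effects", "cis_effects")) {
    eff <- cfg[[f]]
    if (nrow(eff) > 0 && !all(eff$snp %in% snp_universe)) {
      abort_config(f, paste("references SNP(s) beyond n_snps:",
                            paste(setdiff(eff$snp, snp_universe),
                                  collapse = ", ")))
    }
  }
  x_universe <- sprintf("XG%02d", seq_len(cfg$n_x_genes))
  if (nrow(cfg$cis_effects) > 0 &&
      !all(cfg$cis_effects$gene %in% x_universe)) {
    abort_config("cis_effects", "references genes beyond n_x_genes")
  }
  cfg
}

#' Default eight-study case-control design template
#'
#' Two DLPFC, four ACC, and two amygdala studies, half performed in female
#' subjects, with 9-21 matched case-control pairs and study-specific
#' covariate adjustment sets.
#'
#' @return tibble usable as `study_designs` in [sim_config()].
#' @export
default_study_designs <- function() {
  tibble::tibble(
    study_id = c("MD2_DLPFC_M", "MD1_ACC_M", "MD2_ACC_M", "MD1_AMY_M",
                 "MD2_DLPFC_F", "MD3_ACC_F", "MD2_ACC_F", "MD3_AMY_F"),
    sex = rep(c("male", "female"), each = 4),
    region = c("DLPFC", "ACC", "ACC", "AMY", "DLPFC", "ACC", "ACC", "AMY"),
    n_pairs = c(16L, 15L, 9L, 14L, 14L, 14L, 11L, 21L),
    declared_covariates = list(
      c("age", "pmi"), "age", character(0), "age",
      c("age", "pmi"), c("age", "rin"), c("alcohol", "suicide"),
      c("age", "suicide")
    )
  )
}

#' Default planted trans-eQTL effects
#'
#' A female-biased pattern: several X SNP blocks drive SST/GAD67/GAD65 in
#' the female stratum, with a single weaker male-stratum effect on GAD65,
#' mimicking the sexually dimorphic trans-association pattern the pipeline
#' is meant to recover.
#'
#' @return tibble with columns snp, gene, stratum, beta.
#' @export
default_trans_effects <- function() {
  tibble::tibble(
    snp = c("snp_00005", "snp_00105", "snp_00205", "snp_00305", "snp_00405"),
    gene = c("SST", "SST", "GAD67", "GAD65", "GAD65"),
    stratum = c("female", "female", "female", "female", "male"),
    beta = c(1.4, -1.4, 1.4, 1.4, 0.6)
  )
}

#' Default planted cis-eQTL effects on X transcripts
#' @return tibble with columns snp, gene, stratum, beta.
#' @export
default_cis_effects <- function() {
  tibble::tibble(
    snp = c("snp_00005", "snp_00105"),
    gene = c("XG01", "XG05"),
    stratum = c("female", "female"),
    beta = c(1.4, 1.4)
  )
}

fcg_cell_names <- function() {
  as.vector(outer(
    c("XX_female", "XX_male", "XY_female", "XY_male"),
    c("blank", "testosterone"),
    paste, sep = "_"
  ))
}

#' Default Four Core Genotypes cell sizes
#'
#' Unbalanced 12-20 animals per genotype-by-treatment cell, matching the
#' post-stress group sizes of the design the generator emulates.
#'
#' @return named integer vector over the eight design cells.
#' @export
default_fcg_cell_sizes <- function() {
  c(XX_female_blank = 13L, XX_female_testosterone = 20L,
    XX_male_blank = 17L, XX_male_testosterone = 14L,
    XY_female_blank = 13L, XY_female_testosterone = 13L,
    XY_male_blank = 12L, XY_male_testosterone = 14L)
}

#' Default planted FCG effect pattern
#'
#' XY genetic sex lowers Sst/Gad67/Gad65 expression, open-arm and center
#' measures, and locomotor activity; adult testosterone raises open-arm,
#' center, and activity measures; gonadal males show higher sucrose
#' preference with an additional gonadal-male-by-testosterone interaction.
#' All deltas are 1 endpoint-SD in magnitude.
#'
#' @return tibble with one row per endpoint.
#' @export
default_fcg_effects <- function() {
  tibble::tribble(
    ~endpoint,             ~genetic_delta, ~gonadal_delta, ~treatment_delta, ~interaction_delta,
    "Sst",                 -1,             0,              0,                0,
    "Gad67",               -1,             0,              0,                0,
    "Gad65",               -1,             0,              0,                0,
    "open_time",           -1,             0,              1,                0,
    "pct_open_entries",    -1,             0,              1,                0,
    "center_time",         0,              0,              1,                0,
    "pct_center_distance", -1,             0,              1,                0,
    "total_entries",       -1,             0,              1,                0,
    "total_distance",      -1,             0,              1,                0,
    "sucrose_pref",        0,              1,              0,                1
  )
}

#' Default endpoint scales for the FCG generator
#'
#' Baseline means and noise SDs in each endpoint's natural units (seconds
#' for times out of a 600-s session, percentages, counts, centimeters,
#' arbitrary expression units).
#'
#' @return tibble with columns endpoint, mean, sd.
#' @export
default_fcg_scales <- function() {
  tibble::tribble(
    ~endpoint,             ~mean, ~sd,
    "Sst",                 1.0,   0.2,
    "Gad67",               1.0,   0.2,
    "Gad65",               1.0,   0.2,
    "open_time",           90,    25,
    "pct_open_entries",    30,    8,
    "center_time",         60,    18,
    "pct_center_distance", 15,    5,
    "total_entries",       25,    6,
    "total_distance",      2000,  350,
    "sucrose_pref",        75,    8
  )
}
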