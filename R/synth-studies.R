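#' Simulate a collection of case-control expression studies
#'
#' Generates one expression study per row of `config$study_designs`. Each
#' study is a genes-by-subjects matrix on an arbitrary log scale: a common
#' baseline, additive covariate contributions (`config$covariate_effects`),
#' and independent Gaussian noise with SD `config$noise_sd`. The target
#' gene's mean in MDD subjects is shifted by `effect_female` or
#' `effect_male` (in noise-SD units) according to the study's sex, giving a
#' known ground truth for effect-size recovery.
#'
#' Covariates are drawn from ranges typical of postmortem brain cohorts:
#' age ~ N(50.8, 14.9) truncated to 16-96 years, PMI ~ N(17.2, 5.9) hours,
#' pH ~ N(6.7, 0.3), RIN ~ N(8.0, 0.73), and binary alcohol/suicide
#' indicators.
#'
#' @param config a [sim_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return a tibble with one row per study: `study_id`, `sex`, `region`,
#'   `n_pairs`, and list-columns `declared_covariates` (character),
#'   `expression` (genes x subjects matrix) and `covariates` (tibble with
#'   `subject`, `diagnosis` and the numeric covariates).
#' @examples
#' studies <- simulate_study_collection(sim_config(seed = 1))
#' studies$expression[[1]][1:3, 1:4]
#' @export
simulate_study_collection <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% derive_seed(config$seed, SEED_OFFSETS[["studies"]])
  with_seed(seed, {
    rows <- purrr::pmap(config$study_designs, function(study_id, sex, region,
                                                      n_pairs,
                                                      declared_covariates) {
      simulate_one_study(config, study_id, sex, region, n_pairs,
                         declared_covariates)
    })
    out <- config$study_designs
    out$expression <- purrr::map(rows, "expression")
    out$covariates <- purrr::map(rows, "covariates")
    out
  })
}

simulate_one_study <- function(config, study_id, sex, region, n_pairs,
                               declared) {
  n <- 2L * n_pairs
  subjects <- sprintf("%s_S%02d", study_id, seq_len(n))
  covs <- tibble::tibble(
    subject = subjects,
    diagnosis = rep(c("MDD", "control"), each = n_pairs),
    age = round(rnorm_trunc(n, 50.8, 14.9, 16, 96), 1),
    pmi = round(rnorm_trunc(n, 17.2, 5.9, 1, 40), 1),
    ph = round(rnorm_trunc(n, 6.7, 0.3, 5.5, 7.8), 2),
    rin = round(rnorm_trunc(n, 8.0, 0.73, 5, 10), 1),
    # binary covariates are drawn independently of diagnosis so the
    # planted case-control shift stays the exact ground-truth effect
    alcohol = stats::rbinom(n, 1L, 0.3),
    suicide = stats::rbinom(n, 1L, 0.25)
  )
  # a study only declares a covariate it can adjust for, i.e. one that
  # varies in its cohort; redraw the rare all-constant binary draw
  for (cv in intersect(declared, c("alcohol", "suicide"))) {
    while (stats::var(covs[[cv]]) == 0) {
      idx <- sample.int(n, 1)
      covs[[cv]][idx] <- 1L - covs[[cv]][idx]
    }
  }

  genes <- union(config$module_genes,
                 sprintf("BG%03d", seq_len(config$n_background_genes)))
  # covariate contribution, identical for every gene
  centers <- c(age = 50.8, pmi = 17.2, ph = 6.7, rin = 8.0,
               alcohol = 0, suicide = 0)
  shift <- rep(0, n)
  for (cv in names(config$covariate_effects)) {
    if (cv %in% names(covs)) {
      shift <- shift +
        config$covariate_effects[[cv]] * (covs[[cv]] - centers[[cv]])
    }
  }
  expr <- matrix(stats::rnorm(length(genes) * n, sd = config$noise_sd),
                 nrow = length(genes), dimnames = list(genes, subjects))
  expr <- expr + config$baseline_mean +
    matrix(shift, nrow = length(genes), ncol = n, byrow = TRUE)

  effect <- if (sex == "female") config$effect_female else config$effect_male
  is_case <- covs$diagnosis == "MDD"
  expr[config$target_gene, is_case] <-
    expr[config$target_gene, is_case] + effect * config$noise_sd

  list(expression = expr, covariates = covs)
}
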