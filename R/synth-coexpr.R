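#' Simulate the two-region co-expression cohort
#'
#' Generates expression for two prefrontal cortex regions (BA11, BA47)
#' measured on the same `n_coexpr_subjects` control subjects, under a
#' single-latent-factor model: module genes load on one shared
#' subject-level factor with loading `module_loading`, so their expected
#' pairwise correlation is `module_loading^2`. Non-module panel genes get a
#' small fixed loading (GABA-related but outside the tight module) and
#' background genes a small random loading, which spreads the seed-gene
#' correlation profile over a realistic range without creating any
#' above-threshold network edge outside the module.
#'
#' Because both regions are measured on the same subjects, each gene also
#' carries a subject-level component shared across regions (70% of its
#' non-factor variance); this reproduces the empirically high cross-region
#' agreement of seed-gene correlation profiles that the profile-averaging
#' step assumes.
#'
#' @param config a [sim_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return list with elements `BA11`, `BA47` (genes x subjects matrices),
#'   `covariates` (tibble: subject, age, pmi, ph, rin), and `truth` (tibble
#'   gene, loading - the planted ground truth).
#' @examples
#' cohort <- simulate_coexpression_cohort(sim_config(seed = 1))
#' dim(cohort$BA11)
#' @export
simulate_coexpression_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$module_loading < 0 || config$module_loading > 1) {
    abort_config("module_loading", "must lie in [0, 1]")
  }
  seed <- seed %||% derive_seed(config$seed, SEED_OFFSETS[["coexpr"]])
  with_seed(seed, {
    n <- config$n_coexpr_subjects
    subjects <- sprintf("C%03d", seq_len(n))
    panel_extra <- setdiff(config$gaba_panel, config$module_genes)
    bg <- sprintf("BG%03d", seq_len(config$n_background_genes))
    genes <- c(config$module_genes, panel_extra, bg)

    loading <- c(
      rep(config$module_loading, length(config$module_genes)),
      rep(0.3, length(panel_extra)),
      stats::runif(length(bg), -0.3, 0.35)
    )
    names(loading) <- genes

    f <- stats::rnorm(n)                       # shared latent factor
    resid_var <- 1 - loading^2
    c_sd <- sqrt(0.7 * resid_var)              # subject component, region-shared
    d_sd <- sqrt(0.3 * resid_var)              # region-specific noise
    u <- matrix(stats::rnorm(length(genes) * n), nrow = length(genes))

    region_matrix <- function() {
      e <- matrix(stats::rnorm(length(genes) * n), nrow = length(genes))
      m <- loading %o% f + c_sd * u + d_sd * e
      m <- config$baseline_mean + config$noise_sd * m
      dimnames(m) <- list(genes, subjects)
      m
    }
    ba11 <- region_matrix()
    ba47 <- region_matrix()

    covariates <- tibble::tibble(
      subject = subjects,
      age = round(rnorm_trunc(n, 50.8, 14.9, 16, 96), 1),
      pmi = round(rnorm_trunc(n, 17.2, 5.9, 1, 40), 1),
      ph = round(rnorm_trunc(n, 6.7, 0.3, 5.5, 7.8), 2),
      rin = round(rnorm_trunc(n, 8.0, 0.73, 5, 10), 1)
    )
    list(BA11 = ba11, BA47 = ba47, covariates = covariates,
         truth = tibble::tibble(gene = genes, loading = unname(loading)))
  })
}
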