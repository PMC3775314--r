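#' Run the full analysis chain on simulated data
#'
#' Executes the stages in order - study simulation and meta-analysis,
#' co-expression profiling and network construction, sex-stratified
#' trans/cis-eQTL mapping with negative controls, and the FCG factorial
#' analysis - writing each stage's tidy results as CSV under `out_dir`
#' together with a manifest (file checksums, package version, seed).
#'
#' @param config a [sim_config()]; its `seed` drives every stage.
#' @param out_dir output directory, created if needed.
#' @param stages subset of `c("meta", "coexpr", "eqtl", "fcg")` to run
#'   (synthesis happens implicitly per stage).
#' @param alpha BH FDR level for the trans scan.
#' @return invisible named list with the in-memory stage results:
#'   `effects`, `pooled_female`, `pooled_male`, `pooled_all`, `moderator`,
#'   `stouffer`, `pct_control`, `profile`, `network`, `core`,
#'   `trans_records`, `trans_summary`, `cis_records`, `controls`,
#'   `fcg_results`, `fcg_summary`.
#' @examples
#' \donttest{
#' res <- run_pipeline(sim_config(seed = 1), tempfile("gabasex_run_"))
#' res$moderator
#' }
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("meta", "coexpr", "eqtl", "fcg"),
                         alpha = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # resolved configuration is written beside the outputs for provenance
  writeLines(yaml::as.yaml(lapply(unclass(config), function(x) {
    if (is.data.frame(x)) as.list(x) else x
  })), file.path(out_dir, "config.yaml"))
  res <- list()
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }

  if ("meta" %in% stages) {
    studies <- simulate_study_collection(config)
    eff <- study_effect_sizes(studies, config$target_gene)
    res$effects <- eff
    res$pooled_female <- pool_random_effects(eff[eff$sex == "female", ])
    res$pooled_male <- pool_random_effects(eff[eff$sex == "male", ])
    res$pooled_all <- pool_random_effects(eff)
    res$moderator <- meta_regress_sex(eff)

    per_study_p <- purrr::map_dfr(seq_len(nrow(studies)), function(i) {
      st <- studies[i, ]
      adj <- adjust_covariates(st, config$target_gene)
      diag <- st$covariates[[1]]$diagnosis
      tt <- stats::t.test(adj[diag == "MDD"], adj[diag == "control"],
                          var.equal = TRUE)
      tibble::tibble(
        study_id = st$study_id, sex = st$sex,
        p = max(tt$p.value, .Machine$double.xmin),
        n = length(adj),
        direction = sign(mean(adj[diag == "MDD"]) -
                           mean(adj[diag == "control"])),
        mean_ctrl = mean(adj[diag == "control"]),
        mean_mdd = mean(adj[diag == "MDD"])
      )
    })
    res$stouffer <- stouffer_z_trend(per_study_p)
    res$pct_control <- dplyr::bind_rows(
      female = percent_of_control(per_study_p[per_study_p$sex == "female", ]),
      male = percent_of_control(per_study_p[per_study_p$sex == "male", ]),
      .id = "sex"
    )
    wcsv(eff, "meta_effect_sizes.csv")
    wcsv(dplyr::bind_rows(female = tidy(res$pooled_female),
                          male = tidy(res$pooled_male),
                          all = tidy(res$pooled_all), .id = "subset"),
         "meta_pooled.csv")
    wcsv(tidy(res$moderator), "meta_moderator.csv")
    wcsv(forest_data(res$pooled_all), "meta_forest.csv")
    wcsv(res$pct_control, "meta_percent_of_control.csv")
  }

  if ("coexpr" %in% stages) {
    cohort <- simulate_coexpression_cohort(config)
    prof <- average_profiles(
      seed_correlations(cohort$BA11, config$target_gene, "BA11"),
      seed_correlations(cohort$BA47, config$target_gene, "BA47")
    )
    res$profile <- prof
    res$top_genes <- select_top(prof)
    res$network <- build_network(cohort$BA11, config$gaba_panel)
    res$core <- core_module(res$network, c("SST", "GAD67", "GAD65"))
    wcsv(prof, "coexpr_profile.csv")
    wcsv(res$top_genes, "coexpr_top_genes.csv")
    write_edge_list(res$network, file.path(out_dir, "coexpr_edges.tsv"))
    write_graphml(res$network, file.path(out_dir, "coexpr_network.graphml"))
  }

  if ("eqtl" %in% stages) {
    gt <- simulate_x_genotypes(config)
    ch <- simulate_eqtl_cohort(config, gt)
    expr <- attach_effects(ch$expression, gt, config)
    targets <- c("SST", "GAD67", "GAD65")
    recs <- dplyr::bind_rows(
      trans_scan(expr, gt, ch$covariates, targets, "female"),
      trans_scan(expr, gt, ch$covariates, targets, "male")
    )
    recs <- bh_correct(recs, alpha = alpha)
    res$trans_records <- recs
    res$trans_summary <- summarize_trans(recs, gt)
    sig_snps <- unique(recs$snp[recs$significant])
    res$cis_records <- dplyr::bind_rows(
      cis_scan(sig_snps, expr, ch$x_annotation, gt, ch$covariates, "female"),
      cis_scan(sig_snps, expr, ch$x_annotation, gt, ch$covariates, "male")
    )
    res$controls <- negative_controls(config$control_genes, expr, gt,
                                      ch$covariates, alpha = alpha)
    wcsv(recs, "eqtl_trans.csv")
    wcsv(res$trans_summary, "eqtl_trans_summary.csv")
    wcsv(res$cis_records, "eqtl_cis.csv")
    wcsv(res$controls$records, "eqtl_controls.csv")
  }

  if ("fcg" %in% stages) {
    fcg <- simulate_fcg(config)
    ep <- derive_endpoints(fcg)
    res$fcg_results <- analyze_fcg(ep)
    res$fcg_summary <- main_effect_summary(res$fcg_results, ep)
    wcsv(ep, "fcg_endpoints.csv")
    wcsv(purrr::map_dfr(res$fcg_results,
                        function(r) cbind(endpoint = r$endpoint, r$terms)),
         "fcg_anova.csv")
    wcsv(res$fcg_summary, "fcg_summary.csv")
  }

  out_files <- list.files(out_dir, full.names = TRUE)
  manifest <- data.frame(
    file = basename(out_files),
    md5 = unname(tools::md5sum(out_files)),
    stringsAsFactors = FALSE
  )
  manifest$package_version <- as.character(utils::packageVersion("gabasex"))
  manifest$seed <- if (is.null(config$seed)) NA_integer_ else config$seed
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(res)
}

#' Forest-plot data for a pooled effect
#'
#' @param pooled a `pooled_effect`.
#' @return tibble: study rows (g, CI bounds, relative weight) followed by
#'   the pooled summary row.
#' @export
forest_data <- function(pooled) {
  eff <- pooled$effects
  w <- 1 / (eff$var_g + pooled$tau2)
  studies <- tibble::tibble(
    study = if ("study_id" %in% names(eff)) eff$study_id else
      paste0("study_", seq_len(nrow(eff))),
    g = eff$g,
    ci_low = eff$g - 1.96 * sqrt(eff$var_g),
    ci_high = eff$g + 1.96 * sqrt(eff$var_g),
    weight = w / sum(w),
    pooled = FALSE
  )
  dplyr::bind_rows(studies, tibble::tibble(
    study = "RE model", g = pooled$mu, ci_low = pooled$ci95[1],
    ci_high = pooled$ci95[2], weight = NA_real_, pooled = TRUE
  ))
}
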