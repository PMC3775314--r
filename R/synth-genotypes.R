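#' Simulate X-chromosome genotypes with LD blocks and hemizygous males
#'
#' SNPs are laid out in consecutive LD blocks of `ld_block_size`. Each
#' haplotype draws one ancestral allele per block (frequency `maf`); every
#' SNP copies that ancestral allele with probability `1 - eps` and
#' otherwise redraws independently, with `eps = 1 - ld_r2^(1/4)` so the
#' expected squared correlation between two SNPs of the same block is
#' `ld_r2` while the marginal minor-allele frequency stays `maf`. Males
#' carry a single haplotype (dosage 0/1); females carry two independent
#' haplotypes (dosage 0/1/2).
#'
#' SNPs of block *b* sit at positions `(b-1)*50000 + (k-1)*1000 + 10001`
#' (1-based bp), i.e. 1 kb apart within a block with 40 kb between blocks.
#'
#' @param config a [sim_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return a `genotype_matrix` object: list with `dosages` (SNPs x
#'   subjects integer matrix), `sex` (named character vector), `subject_ids`
#'   and `snp_annotation` (tibble: snp, chrom, position, ref, alt, block -
#'   block is the generator's ground truth).
#' @examples
#' gt <- simulate_x_genotypes(sim_config(seed = 1))
#' max(gt$dosages[, gt$sex == "male"])   # never 2: hemizygous
#' @export
simulate_x_genotypes <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% derive_seed(config$seed, SEED_OFFSETS[["genotypes"]])
  with_seed(seed, {
    n_m <- config$n_male
    n_f <- config$n_female
    subjects <- c(sprintf("M%03d", seq_len(n_m)), sprintf("F%03d", seq_len(n_f)))
    sex <- stats::setNames(rep(c("male", "female"), c(n_m, n_f)), subjects)

    n_hap <- n_m + 2L * n_f
    eps <- 1 - config$ld_r2^(1 / 4)
    bs <- config$ld_block_size
    n_snps <- config$n_snps
    block_of <- ceiling(seq_len(n_snps) / bs)
    n_blocks <- max(block_of)

    hap <- matrix(0L, nrow = n_snps, ncol = n_hap)
    for (b in seq_len(n_blocks)) {
      idx <- which(block_of == b)
      anc <- stats::rbinom(n_hap, 1L, config$maf)
      keep <- matrix(stats::rbinom(length(idx) * n_hap, 1L, 1 - eps),
                     nrow = length(idx))
      redraw <- matrix(stats::rbinom(length(idx) * n_hap, 1L, config$maf),
                       nrow = length(idx))
      hap[idx, ] <- keep * matrix(anc, nrow = length(idx), ncol = n_hap,
                                  byrow = TRUE) + (1L - keep) * redraw
    }
    dos <- cbind(hap[, seq_len(n_m), drop = FALSE],
                 hap[, n_m + seq_len(n_f), drop = FALSE] +
                   hap[, n_m + n_f + seq_len(n_f), drop = FALSE])
    storage.mode(dos) <- "integer"
    snps <- sprintf("snp_%05d", seq_len(n_snps))
    dimnames(dos) <- list(snps, subjects)

    ann <- tibble::tibble(
      snp = snps,
      chrom = "X",
      position = (block_of - 1L) * 50000L +
        ((seq_len(n_snps) - 1L) %% bs) * 1000L + 10001L,
      ref = "A", alt = "G",
      block = block_of
    )
    new_genotype_matrix(dos, sex, ann)
  })
}

new_genotype_matrix <- function(dosages, sex, snp_annotation) {
  stopifnot(nrow(dosages) == nrow(snp_annotation),
            ncol(dosages) == length(sex))
  structure(
    list(dosages = dosages, sex = sex, subject_ids = colnames(dosages),
         snp_annotation = snp_annotation),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosages), " SNPs x ",
      length(x$subject_ids), " subjects (",
      sum(x$sex == "male"), " male hemizygous, ",
      sum(x$sex == "female"), " female diploid)\n", sep = "")
  invisible(x)
}

#' Simulated X-chromosome transcript annotation
#'
#' `n_x_genes` transcripts of 15 kb, spaced 120 kb apart along the
#' simulated X chromosome so that some planted SNPs fall within the +/-50 kb
#' cis window of a transcript and others do not. Coordinates are 1-based
#' inclusive.
#'
#' @param config a [sim_config()].
#' @return tibble: gene, chrom, start, end.
#' @export
simulate_x_annotation <- function(config) {
  j <- seq_len(config$n_x_genes)
  tibble::tibble(
    gene = sprintf("XG%02d", j),
    chrom = "X",
    start = (j - 1L) * 120000L + 30001L,
    end = (j - 1L) * 120000L + 45000L
  )
}

#' Simulate expression for the eQTL cohort
#'
#' Builds a genes-by-subjects expression matrix over the genotyped cohort:
#' the autosomal trans targets (SST, GAD67, GAD65), the negative-control
#' genes, and the simulated X transcripts. Expression is baseline plus
#' age/pH/RIN covariate contributions plus Gaussian noise; no genotype
#' effect is present until [attach_effects()] plants one.
#'
#' @param config a [sim_config()].
#' @param genotypes a `genotype_matrix` for the same cohort.
#' @param seed optional seed overriding `config$seed`.
#' @return list with `expression` (matrix), `covariates` (tibble: subject,
#'   age, ph, rin) and `x_annotation` (tibble from
#'   [simulate_x_annotation()]).
#' @export
simulate_eqtl_cohort <- function(config, genotypes, seed = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genotypes, "genotype_matrix"))
  seed <- seed %||% derive_seed(config$seed, SEED_OFFSETS[["eqtl_expr"]])
  with_seed(seed, {
    subjects <- genotypes$subject_ids
    n <- length(subjects)
    covs <- tibble::tibble(
      subject = subjects,
      age = round(rnorm_trunc(n, 50.8, 14.9, 16, 96), 1),
      ph = round(rnorm_trunc(n, 6.7, 0.3, 5.5, 7.8), 2),
      rin = round(rnorm_trunc(n, 8.0, 0.73, 5, 10), 1)
    )
    x_ann <- simulate_x_annotation(config)
    genes <- c("SST", "GAD67", "GAD65", config$control_genes, x_ann$gene)
    centers <- c(age = 50.8, ph = 6.7, rin = 8.0)
    shift <- rep(0, n)
    for (cv in c("age", "ph", "rin")) {
      slope <- config$covariate_effects[[cv]]
      if (!is.null(slope)) shift <- shift + slope * (covs[[cv]] - centers[[cv]])
    }
    expr <- matrix(stats::rnorm(length(genes) * n, sd = config$noise_sd),
                   nrow = length(genes), dimnames = list(genes, subjects))
    expr <- expr + config$baseline_mean +
      matrix(shift, nrow = length(genes), ncol = n, byrow = TRUE)
    list(expression = expr, covariates = covs, x_annotation = x_ann)
  })
}

#' Plant genotype effects into an expression matrix
#'
#' For every effect row, adds `beta * noise_sd * dosage` to the target
#' gene's expression, only in subjects of the stated sex stratum. This is
#' the ground truth the eQTL scans are later asked to recover.
#'
#' @param expression genes x subjects matrix; column names must match the
#'   genotype subject ids.
#' @param genotypes a `genotype_matrix`.
#' @param effects tibble with columns `snp`, `gene`, `stratum`, `beta`, or
#'   a [sim_config()] (in which case its `trans_effects` and `cis_effects`
#'   are combined).
#' @param noise_sd scale converting beta from SD units to expression units.
#' @return the expression matrix with effects added.
#' @examples
#' cfg <- sim_config(seed = 1)
#' gt <- simulate_x_genotypes(cfg)
#' cohort <- simulate_eqtl_cohort(cfg, gt)
#' expr <- attach_effects(cohort$expression, gt, cfg)
#' @export
attach_effects <- function(expression, genotypes, effects, noise_sd = NULL) {
  if (inherits(effects, "sim_config")) {
    noise_sd <- noise_sd %||% effects$noise_sd
    effects <- dplyr::bind_rows(effects$trans_effects, effects$cis_effects)
  }
  noise_sd <- noise_sd %||% 1
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (nrow(effects) == 0) return(expression)
  if (!all(effects$snp %in% rownames(genotypes$dosages))) {
    stop("attach_effects: unknown SNP(s): ",
         paste(setdiff(effects$snp, rownames(genotypes$dosages)),
               collapse = ", "), call. = FALSE)
  }
  if (!all(effects$gene %in% rownames(expression))) {
    stop("attach_effects: unknown gene(s): ",
         paste(setdiff(effects$gene, rownames(expression)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(effects$stratum %in% c("male", "female"))) {
    stop("attach_effects: stratum must be 'male' or 'female'", call. = FALSE)
  }
  sex <- genotypes$sex[colnames(expression)]
  for (i in seq_len(nrow(effects))) {
    in_str <- which(sex == effects$stratum[i])
    dose <- genotypes$dosages[effects$snp[i], colnames(expression)[in_str]]
    expression[effects$gene[i], in_str] <-
      expression[effects$gene[i], in_str] +
      effects$beta[i] * noise_sd * dose
  }
  expression
}
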