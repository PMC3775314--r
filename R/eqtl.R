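#' Sex-stratified trans-eQTL scan
#'
#' Within one sex stratum, fits the covariate-adjusted additive model
#' `expression ~ dosage + age + ph + rin` for every (SNP, target gene)
#' pair and reports the two-sided t-test on the dosage coefficient. The
#' scan is computed by residualizing expression and dosages on the
#' covariate design once per stratum (Frisch-Waugh-Lovell), which is
#' algebraically identical to the full per-pair least-squares fit.
#'
#' SNPs with minor-allele count below `min_mac` in the stratum (including
#' monomorphic SNPs) are skipped: the dosage t-test is degenerate there.
#'
#' @param expression genes x subjects matrix (columns must match genotype
#'   subject ids).
#' @param genotypes a `genotype_matrix`.
#' @param covariates data frame with columns `subject`, `age`, `ph`, `rin`.
#' @param target_genes genes to scan (must be rows of `expression`).
#' @param stratum `"male"` or `"female"`.
#' @param min_mac minimum stratum minor-allele count to test a SNP.
#' @return tibble of association records: `snp`, `gene`, `stratum`, `n`,
#'   `beta` (expression units per alternate allele), `se`, `p`, `q` (NA
#'   until [bh_correct()]). Attribute `skipped` lists untested SNPs.
#' @examples
#' cfg <- sim_config(seed = 1)
#' gt <- simulate_x_genotypes(cfg)
#' ch <- simulate_eqtl_cohort(cfg, gt)
#' expr <- attach_effects(ch$expression, gt, cfg)
#' head(trans_scan(expr, gt, ch$covariates, "SST", "female"))
#' @export
trans_scan <- function(expression, genotypes, covariates, target_genes,
                       stratum = c("male", "female"), min_mac = 3L) {
  stratum <- match.arg(stratum)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!all(target_genes %in% rownames(expression))) {
    stop("trans_scan: gene(s) missing from expression: ",
         paste(setdiff(target_genes, rownames(expression)), collapse = ", "),
         call. = FALSE)
  }
  subj <- genotypes$subject_ids[genotypes$sex == stratum]
  subj <- intersect(subj, colnames(expression))
  subj <- intersect(subj, covariates$subject)
  n <- length(subj)
  if (n == 0) stop("trans_scan: empty stratum", call. = FALSE)

  cv <- covariates[match(subj, covariates$subject), ]
  X <- cbind(1, cv$age, cv$ph, cv$rin)
  for (j in 2:4) {
    if (stats::var(X[, j]) == 0) {
      stop("trans_scan: singular covariate design (constant covariate)",
           call. = FALSE)
    }
  }
  qr_x <- qr(X)
  p_cov <- qr_x$rank
  df <- n - p_cov - 1L

  D <- genotypes$dosages[, subj, drop = FALSE]
  # stratum minor-allele count; male X is haploid so max dosage is 1
  ploidy_max <- if (stratum == "male") 1L else 2L
  mac <- pmin(rowSums(D), n * ploidy_max - rowSums(D))
  keep <- which(mac >= min_mac)
  skipped <- rownames(D)[setdiff(seq_len(nrow(D)), keep)]
  if (length(keep) == 0) {
    warning("trans_scan: all SNPs monomorphic or below MAC in stratum",
            call. = FALSE)
    out <- empty_eqtl_records()
    attr(out, "skipped") <- skipped
    return(out)
  }

  RD <- qr.resid(qr_x, t(D[keep, , drop = FALSE]))   # subjects x SNPs
  sxx <- colSums(RD^2)

  res <- purrr::map_dfr(target_genes, function(gene) {
    ry <- qr.resid(qr_x, expression[gene, subj])
    syy <- sum(ry^2)
    sxy <- colSums(RD * ry)
    beta <- sxy / sxx
    rss <- syy - beta^2 * sxx
    se <- sqrt(pmax(rss, 0) / df / sxx)
    tstat <- beta / se
    tibble::tibble(
      snp = rownames(D)[keep], gene = gene, stratum = stratum, n = n,
      beta = unname(beta), se = unname(se),
      p = unname(2 * stats::pt(-abs(tstat), df = df)),
      q = NA_real_
    )
  })
  attr(res, "skipped") <- skipped
  res
}

empty_eqtl_records <- function() {
  tibble::tibble(
    snp = character(), gene = character(), stratum = character(),
    n = integer(), beta = double(), se = double(), p = double(),
    q = double()
  )
}

#' Benjamini-Hochberg correction of eQTL records
#'
#' Applies the BH step-up procedure to the scan p-values. The default
#' family is all SNPs tested for one (gene, stratum) pair; setting
#' `family = "pooled"` corrects across everything at once.
#'
#' @param records tibble from [trans_scan()].
#' @param alpha FDR level in (0, 1).
#' @param family `"gene_stratum"` (default) or `"pooled"`.
#' @return the records with `q` filled and a logical `significant`
#'   column (`q <= alpha`).
#' @export
bh_correct <- function(records, alpha = 0.05,
                       family = c("gene_stratum", "pooled")) {
  stopifnot(alpha > 0, alpha < 1)
  family <- match.arg(family)
  if (nrow(records) == 0) {
    records$significant <- logical(0)
    return(records)
  }
  if (family == "pooled") {
    records$q <- stats::p.adjust(records$p, method = "BH")
  } else {
    records <- dplyr::mutate(
      dplyr::group_by(records, .data$gene, .data$stratum),
      q = stats::p.adjust(.data$p, method = "BH")
    )
    records <- dplyr::ungroup(records)
  }
  records$significant <- records$q <= alpha
  records
}

#' Collapse significant SNPs into LD blocks
#'
#' Single-linkage clustering: two SNPs join the same block when their
#' pairwise dosage r-squared is at least `r2_threshold` and they lie
#' within `max_bp` of each other; blocks are the connected components of
#' that relation. Following the usual reporting convention, multi-SNP
#' components are counted as LD blocks and size-one components as
#' individual (singleton) SNPs.
#'
#' @param snps SNP identifiers (e.g. the significant set of a scan).
#' @param genotypes a `genotype_matrix`.
#' @param r2_threshold minimum pairwise r-squared (default 0.8).
#' @param max_bp maximum pairwise distance in bp (default 500 kb).
#' @return object of class `ld_block_summary`: list with `blocks` (list of
#'   character vectors), `n_blocks` (multi-SNP components), `n_singletons`,
#'   `n_snps`, `r2_threshold`, `max_bp`.
#' @export
collapse_blocks <- function(snps, genotypes, r2_threshold = 0.8,
                            max_bp = 500000L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  snps <- unique(snps)
  if (!all(snps %in% rownames(genotypes$dosages))) {
    stop("collapse_blocks: unknown SNP(s): ",
         paste(setdiff(snps, rownames(genotypes$dosages)), collapse = ", "),
         call. = FALSE)
  }
  if (length(snps) == 0) {
    return(structure(list(blocks = list(), n_blocks = 0L, n_singletons = 0L,
                          n_snps = 0L, r2_threshold = r2_threshold,
                          max_bp = max_bp),
                     class = "ld_block_summary"))
  }
  D <- genotypes$dosages[snps, , drop = FALSE]
  pos <- genotypes$snp_annotation$position[
    match(snps, genotypes$snp_annotation$snp)]
  r2 <- suppressWarnings(stats::cor(t(D)))^2
  r2[is.na(r2)] <- 0
  near <- abs(outer(pos, pos, "-")) <= max_bp
  adj <- (r2 >= r2_threshold) & near
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  blocks <- split(snps, comp)
  names(blocks) <- NULL
  sizes <- lengths(blocks)
  structure(
    list(blocks = blocks, n_blocks = sum(sizes > 1),
         n_singletons = sum(sizes == 1), n_snps = length(snps),
         r2_threshold = r2_threshold, max_bp = max_bp),
    class = "ld_block_summary"
  )
}

#' @export
print.ld_block_summary <- function(x, ...) {
  cat("<ld_block_summary> ", x$n_snps, " SNPs -> ", x$n_blocks,
      " LD block(s) (", x$n_singletons, " individual SNPs) at r2 >= ",
      x$r2_threshold, " within ", x$max_bp, " bp\n", sep = "")
  invisible(x)
}

#' Cis-eQTL follow-up within a window around X transcripts
#'
#' Tests each trans-significant SNP against every X transcript whose
#' window `[start - window_bp, end + window_bp]` (1-based, inclusive at
#' both boundaries) contains the SNP, using the same covariate-adjusted
#' model and stratum as the trans scan. Raw p-values are reported without
#' multiple-testing correction (the SNP set is hypothesis-driven);
#' `significant` flags p < 0.05.
#'
#' @param snps SNPs to follow up (the trans-significant set).
#' @param x_expression genes x subjects matrix of X-transcript expression.
#' @param gene_annotation tibble `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive; use [read_bed()] for BED input).
#' @param genotypes a `genotype_matrix`.
#' @param covariates data frame with `subject`, `age`, `ph`, `rin`.
#' @param stratum `"male"` or `"female"`.
#' @param window_bp window half-width in bp (default 50 kb).
#' @param min_mac minimum stratum minor-allele count.
#' @return tibble of records as in [trans_scan()] plus `significant`
#'   (p < 0.05); empty (with a message) if no SNP lands in any window.
#' @export
cis_scan <- function(snps, x_expression, gene_annotation, genotypes,
                     covariates, stratum = c("male", "female"),
                     window_bp = 50000L, min_mac = 3L) {
  stratum <- match.arg(stratum)
  snps <- unique(snps)
  ann <- genotypes$snp_annotation
  pos <- ann$position[match(snps, ann$snp)]
  pairs <- purrr::map_dfr(seq_len(nrow(gene_annotation)), function(i) {
    gene <- gene_annotation$gene[i]
    lo <- gene_annotation$start[i] - window_bp
    hi <- gene_annotation$end[i] + window_bp
    hit <- snps[!is.na(pos) & pos >= lo & pos <= hi]
    if (length(hit) == 0) return(NULL)
    tibble::tibble(snp = hit, gene = gene)
  })
  if (nrow(pairs) == 0) {
    message("cis_scan: no transcript within ", window_bp, " bp of any SNP")
    out <- empty_eqtl_records()
    out$significant <- logical(0)
    return(out)
  }
  pairs <- pairs[pairs$gene %in% rownames(x_expression), ]
  res <- purrr::map_dfr(unique(pairs$gene), function(gene) {
    rec <- trans_scan(x_expression, genotypes, covariates, gene,
                      stratum = stratum, min_mac = min_mac)
    rec[rec$snp %in% pairs$snp[pairs$gene == gene], ]
  })
  res$significant <- res$p < 0.05
  res
}

#' Negative-control eQTL verification
#'
#' Runs the full trans scan + BH correction on genes expected to show no
#' X-chromosome association (and optionally on a Y-chromosome SNP panel
#' against the real target genes). The report passes when zero
#' BH-significant associations are found.
#'
#' @param control_genes genes with no planted genotype effect.
#' @param expression genes x subjects matrix containing them.
#' @param genotypes a `genotype_matrix`.
#' @param covariates data frame with `subject`, `age`, `ph`, `rin`.
#' @param alpha BH FDR level.
#' @param strata strata to scan (default both).
#' @param y_genotypes optional `genotype_matrix` of Y SNPs; if NULL that
#'   section is skipped with a note in the report.
#' @param y_target_genes genes to test against Y SNPs.
#' @return object of class `control_report`: list with `records` (all
#'   control associations), `n_significant`, `pass` (logical),
#'   `y_section` (`"skipped"` or a record tibble).
#' @export
negative_controls <- function(control_genes, expression, genotypes,
                              covariates, alpha = 0.05,
                              strata = c("male", "female"),
                              y_genotypes = NULL,
                              y_target_genes = c("SST", "GAD67", "GAD65")) {
  records <- purrr::map_dfr(strata, function(s) {
    trans_scan(expression, genotypes, covariates, control_genes, stratum = s)
  })
  records <- bh_correct(records, alpha = alpha)
  n_sig <- sum(records$significant)

  y_section <- "skipped"
  if (!is.null(y_genotypes)) {
    y_records <- purrr::map_dfr(strata, function(s) {
      trans_scan(expression, y_genotypes, covariates,
                 intersect(y_target_genes, rownames(expression)),
                 stratum = s)
    })
    y_section <- bh_correct(y_records, alpha = alpha)
    n_sig <- n_sig + sum(y_section$significant)
  }
  structure(
    list(records = records, n_significant = n_sig, pass = n_sig == 0,
         alpha = alpha, y_section = y_section),
    class = "control_report"
  )
}

#' @export
print.control_report <- function(x, ...) {
  cat("<control_report> ", x$n_significant,
      " BH-significant control association(s) at alpha = ", x$alpha,
      " -> ", if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  if (identical(x$y_section, "skipped")) {
    cat("  Y-chromosome section: skipped (no Y genotypes supplied)\n")
  }
  invisible(x)
}

#' Summarize significant trans-eQTL results per gene and stratum
#'
#' Counts significant SNPs, LD blocks and (via the cis records, when
#' given) associated transcripts in the layout used for sexually dimorphic
#' eQTL summaries.
#'
#' @param records BH-corrected trans records (from [bh_correct()]).
#' @param genotypes a `genotype_matrix` (for LD collapsing).
#' @param r2_threshold,max_bp passed to [collapse_blocks()].
#' @return tibble: `stratum`, `gene`, `n_significant`, `n_ld_blocks`,
#'   `n_singletons`.
#' @export
summarize_trans <- function(records, genotypes, r2_threshold = 0.8,
                            max_bp = 500000L) {
  groups <- dplyr::distinct(records, .data$stratum, .data$gene)
  purrr::pmap_dfr(groups, function(stratum, gene) {
    sig <- records$snp[records$stratum == stratum & records$gene == gene &
                         records$significant]
    bl <- collapse_blocks(sig, genotypes, r2_threshold, max_bp)
    tibble::tibble(stratum = stratum, gene = gene,
                   n_significant = length(sig),
                   n_ld_blocks = bl$n_blocks,
                   n_singletons = bl$n_singletons)
  })
}
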