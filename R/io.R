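#' Read an expression matrix from delimited text
#'
#' Expects genes in rows with a header of subject identifiers; the
#' delimiter is inferred from the extension (`.csv` = comma, otherwise
#' tab). Duplicate gene identifiers are rejected; non-numeric cells raise
#' an error naming the offending row and column. Missing values are
#' tolerated and their positions recorded in the `missing_mask` attribute
#' so downstream correlation steps can use the pairwise-complete rule.
#'
#' @param path input file.
#' @return numeric matrix (genes x subjects) with attribute
#'   `missing_mask` (logical matrix, TRUE where the cell was missing).
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character")
  genes <- raw[[1]]
  if (anyDuplicated(genes)) {
    stop("read_expression: duplicate gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals) & !(vals %in% c("NA", "", "NaN")),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "read_expression: non-numeric value '%s' at gene '%s', subject '%s'",
      vals[bad[1, 1], bad[1, 2]], genes[bad[1, 1]],
      colnames(vals)[bad[1, 2]]), call. = FALSE)
  }
  dimnames(num) <- list(genes, colnames(vals))
  attr(num, "missing_mask") <- is.na(num)
  num
}

#' Write an expression matrix as tab-delimited text
#' @param expression genes x subjects matrix.
#' @param path output file (`.csv` switches to comma-delimited).
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # %.17g guarantees a lossless double -> text -> double round trip
  txt <- matrix(sprintf("%.17g", expression), nrow = nrow(expression),
                dimnames = dimnames(expression))
  txt[is.na(expression)] <- "NA"
  df <- data.frame(gene = rownames(expression), txt, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from VCF or a dosage table
#'
#' VCF input (`.vcf`) is parsed with the GT field: haploid calls (`0`,
#' `1`) count the single allele, diploid calls (`0/1`, `1|1`, ...) count
#' alternate alleles. A diploid heterozygous call in a male sample on the
#' X chromosome is biologically impossible; such SNP/sample entries
#' trigger a warning and, with `drop_bad_male_hets = TRUE`, the genotype
#' is set to missing (NA). Any other malformed GT token is an error naming
#' the record. TSV input expects SNPs in rows (first column `snp`) and
#' one column per subject.
#'
#' @param path `.vcf` or tab-delimited dosage file.
#' @param sex named character vector (`"male"`/`"female"`) covering all
#'   subjects.
#' @param annotation for TSV input, a tibble `snp`, `chrom`, `position`,
#'   `ref`, `alt`; ignored for VCF (taken from the fixed columns).
#' @param drop_bad_male_hets replace impossible male heterozygous diploid
#'   X calls by NA (default TRUE).
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, sex, annotation = NULL,
                           drop_bad_male_hets = TRUE) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    snps <- fix$ID
    rownames(gt) <- snps
    dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                  dimnames = dimnames(gt))
    for (j in seq_len(ncol(gt))) {
      dos[, j] <- parse_gt_column(gt[, j], snps)
    }
    subj <- colnames(gt)
    sexv <- sex[subj]
    if (anyNA(sexv)) {
      stop("read_genotypes: sex missing for subject(s): ",
           paste(subj[is.na(sexv)], collapse = ", "), call. = FALSE)
    }
    ann <- tibble::tibble(
      snp = snps, chrom = fix$CHROM, position = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT
    )
    bad_het <- which(
      matrix(sexv == "male", nrow = nrow(dos), ncol = ncol(dos),
             byrow = TRUE) & !is.na(gt) & gt %in% c("0/1", "1/0", "0|1", "1|0"),
      arr.ind = TRUE
    )
    if (nrow(bad_het) > 0) {
      warning("read_genotypes: ", nrow(bad_het),
              " heterozygous diploid X call(s) in male sample(s)",
              if (drop_bad_male_hets) "; set to NA" else "", call. = FALSE)
      if (drop_bad_male_hets) dos[bad_het] <- NA_integer_
    }
    return(new_genotype_matrix(dos, sexv, ann))
  }
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  snps <- as.character(raw[[1]])
  dos <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(dos) <- "integer"
  rownames(dos) <- snps
  sexv <- sex[colnames(dos)]
  if (anyNA(sexv)) {
    stop("read_genotypes: sex missing for subject(s): ",
         paste(colnames(dos)[is.na(sexv)], collapse = ", "), call. = FALSE)
  }
  if (is.null(annotation)) {
    annotation <- tibble::tibble(snp = snps, chrom = NA_character_,
                                 position = NA_integer_,
                                 ref = NA_character_, alt = NA_character_)
  }
  new_genotype_matrix(dos, sexv, annotation[match(snps, annotation$snp), ])
}

parse_gt_column <- function(gt, snps) {
  out <- rep(NA_integer_, length(gt))
  ok_hap <- gt %in% c("0", "1")
  ok_dip <- grepl("^[01][/|][01]$", gt)
  miss <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  bad <- !(ok_hap | ok_dip | miss)
  if (any(bad)) {
    stop("read_genotypes: malformed GT token '", gt[which(bad)[1]],
         "' at SNP ", snps[which(bad)[1]], call. = FALSE)
  }
  out[ok_hap] <- as.integer(gt[ok_hap])
  out[ok_dip] <- as.integer(substr(gt[ok_dip], 1, 1)) +
    as.integer(substr(gt[ok_dip], 3, 3))
  out
}

#' Write genotypes as minimal VCFv4.2
#'
#' Emits GT-only records: haploid calls for males (X hemizygosity),
#' unphased diploid calls for females.
#'
#' @param genotypes a `genotype_matrix`.
#' @param path output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  ann <- genotypes$snp_annotation
  dos <- genotypes$dosages
  is_male <- genotypes$sex[colnames(dos)] == "male"
  gt <- matrix("", nrow = nrow(dos), ncol = ncol(dos))
  gt[, is_male] <- as.character(dos[, is_male, drop = FALSE])
  fem <- dos[, !is_male, drop = FALSE]
  gt[, !is_male] <- c("0/0", "0/1", "1/1")[fem + 1L]
  gt[is.na(dos)] <- "."
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(dos)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(dos)), function(i) {
    paste(c(ann$chrom[i], ann$position[i], ann$snp[i], ann$ref[i],
            ann$alt[i], ".", "PASS", ".", "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write genotypes as a tab-delimited dosage table
#' @param genotypes a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(snp = rownames(genotypes$dosages), genotypes$dosages,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation from BED
#'
#' BED coordinates are 0-based half-open; they are converted to the
#' 1-based inclusive convention used internally (`start = bed_start + 1`,
#' `end = bed_end`).
#'
#' @param path BED file (chrom, start, end, name).
#' @return tibble: `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "gene"))
  tibble::tibble(
    gene = as.character(raw$gene), chrom = as.character(raw$chrom),
    start = as.integer(raw$start) + 1L, end = as.integer(raw$end)
  )
}

#' Write gene annotation as BED (0-based half-open)
#' @param annotation tibble `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(annotation, path) {
  utils::write.table(
    data.frame(chrom = annotation$chrom, start = annotation$start - 1L,
               end = annotation$end, name = annotation$gene),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Materialize a complete demo dataset on disk
#'
#' Writes every simulated input in its standard interchange format:
#' per-study expression and covariate tables (TSV), the two-region
#' co-expression matrices, genotypes as VCFv4.2 and as a dosage table,
#' X-transcript annotation as BED, and the FCG animal table as CSV.
#'
#' @param config a [sim_config()]; give it a seed for reproducible
#'   fixtures.
#' @param dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
write_fixtures <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  w <- function(p) { files <<- c(files, p); p }

  studies <- simulate_study_collection(config)
  for (i in seq_len(nrow(studies))) {
    id <- studies$study_id[i]
    write_expression(studies$expression[[i]],
                     w(file.path(dir, paste0(id, "_expression.tsv"))))
    utils::write.table(studies$covariates[[i]],
                       w(file.path(dir, paste0(id, "_covariates.tsv"))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cohort <- simulate_coexpression_cohort(config)
  write_expression(cohort$BA11, w(file.path(dir, "coexpr_BA11.tsv")))
  write_expression(cohort$BA47, w(file.path(dir, "coexpr_BA47.tsv")))

  gt <- simulate_x_genotypes(config)
  write_genotypes_vcf(gt, w(file.path(dir, "genotypes_X.vcf")))
  write_dosage_tsv(gt, w(file.path(dir, "genotypes_X_dosage.tsv")))
  utils::write.table(
    data.frame(subject = gt$subject_ids, sex = unname(gt$sex)),
    w(file.path(dir, "subject_sex.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)

  eq <- simulate_eqtl_cohort(config, gt)
  expr <- attach_effects(eq$expression, gt, config)
  write_expression(expr, w(file.path(dir, "eqtl_expression.tsv")))
  utils::write.table(eq$covariates,
                     w(file.path(dir, "eqtl_covariates.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(eq$x_annotation, w(file.path(dir, "x_genes.bed")))

  fcg <- simulate_fcg(config)
  utils::write.csv(fcg, w(file.path(dir, "fcg_animals.csv")),
                   row.names = FALSE)
  invisible(files)
}

#' Read a study collection from a YAML manifest
#'
#' The manifest lists one entry per study with fields `study_id`, `sex`,
#' `region`, `expression` (path to a genes-by-subjects table), `covariates`
#' (path to a subject covariate table with a `diagnosis` column) and
#' `declared_covariates` (possibly empty list of covariate names). Relative
#' paths are resolved against the manifest's directory. The result has the
#' same shape as [simulate_study_collection()] output, so the whole
#' meta-analysis chain runs unchanged on real data.
#'
#' @param path manifest file.
#' @return tibble with one row per study and list-columns `expression`,
#'   `covariates`, `declared_covariates`.
#' @export
read_study_collection <- function(path) {
  manifest <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  purrr::map_dfr(manifest, function(entry) {
    for (f in c("study_id", "sex", "region", "expression", "covariates")) {
      if (is.null(entry[[f]])) {
        stop("manifest entry missing field '", f, "'", call. = FALSE)
      }
    }
    covs <- utils::read.table(resolve(entry$covariates), sep = "\t",
                              header = TRUE, check.names = FALSE)
    expr <- read_expression(resolve(entry$expression))
    if (!"diagnosis" %in% names(covs)) {
      stop("covariate table for study '", entry$study_id,
           "' lacks a diagnosis column", call. = FALSE)
    }
    tibble::tibble(
      study_id = entry$study_id, sex = entry$sex, region = entry$region,
      n_pairs = NA_integer_,
      declared_covariates = list(as.character(unlist(
        entry$declared_covariates %||% character(0)))),
      expression = list(expr),
      covariates = list(tibble::as_tibble(covs))
    )
  })
}
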