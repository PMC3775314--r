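test_that("trans_scan equals per-pair least-squares fits", {
  cfg <- small_geno_config(seed = 61)
  gt <- simulate_x_genotypes(cfg)
  ch <- simulate_eqtl_cohort(cfg, gt)
  expr <- attach_effects(ch$expression, gt, cfg)
  recs <- trans_scan(expr, gt, ch$covariates, c("SST", "GAD67"), "male")

  idx <- sample(seq_len(nrow(recs)), 20)
  males <- gt$subject_ids[gt$sex == "male"]
  cv <- ch$covariates[match(males, ch$covariates$subject), ]
  for (i in idx) {
    y <- expr[recs$gene[i], males]
    d <- gt$dosages[recs$snp[i], males]
    fit <- summary(lm(y ~ d + cv$age + cv$ph + cv$rin))$coefficients
    expect_equal(recs$beta[i], fit["d", "Estimate"], tolerance = 1e-10)
    expect_equal(recs$se[i], fit["d", "Std. Error"], tolerance = 1e-10)
    expect_equal(recs$p[i], fit["d", "Pr(>|t|)"], tolerance = 1e-10)
  }
  expect_true(all(recs$n == length(males)))
})

test_that("a perfect dosage signal is recovered with beta intact", {
  cfg <- small_geno_config(seed = 62)
  gt <- simulate_x_genotypes(cfg)
  ch <- simulate_eqtl_cohort(cfg, gt)
  expr <- ch$expression
  males <- gt$subject_ids[gt$sex == "male"]
  expr["SST", ] <- 1 + 0.5 * gt$dosages["snp_00001", ] +
    1e-8 * rnorm(ncol(expr))
  rec <- trans_scan(expr, gt, ch$covariates, "SST", "male")
  hit <- rec[rec$snp == "snp_00001", ]
  expect_equal(hit$beta, 0.5, tolerance = 1e-4)
  expect_lt(hit$p, 1e-100)
})

test_that("monomorphic and low-MAC SNPs are skipped with a record", {
  cfg <- small_geno_config(seed = 63)
  gt <- simulate_x_genotypes(cfg)
  gt$dosages["snp_00002", ] <- 0L
  ch <- simulate_eqtl_cohort(cfg, gt)
  rec <- trans_scan(ch$expression, gt, ch$covariates, "SST", "female")
  expect_false("snp_00002" %in% rec$snp)
  expect_true("snp_00002" %in% attr(rec, "skipped"))

  gt$dosages[, ] <- 0L
  expect_warning(
    empty <- trans_scan(ch$expression, gt, ch$covariates, "SST", "female"),
    "monomorphic"
  )
  expect_equal(nrow(empty), 0)
})

test_that("scan statistics are equivariant and permutation-stable", {
  cfg <- small_geno_config(seed = 64)
  gt <- simulate_x_genotypes(cfg)
  ch <- simulate_eqtl_cohort(cfg, gt)
  r1 <- trans_scan(ch$expression, gt, ch$covariates, "SST", "male")
  r2 <- trans_scan(2 * ch$expression, gt, ch$covariates, "SST", "male")
  expect_equal(r2$beta, 2 * r1$beta, tolerance = 1e-10)
  expect_equal(r2$p, r1$p, tolerance = 1e-10)

  # permuting subject order jointly leaves every statistic unchanged
  perm <- sample(gt$subject_ids)
  gt2 <- gt
  gt2$dosages <- gt$dosages[, perm]
  gt2$sex <- gt$sex[perm]
  gt2$subject_ids <- perm
  r3 <- trans_scan(ch$expression[, perm], gt2,
                   ch$covariates[match(perm, ch$covariates$subject), ],
                   "SST", "male")
  expect_equal(r3[order(r3$snp), c("beta", "se", "p")],
               r1[order(r1$snp), c("beta", "se", "p")], tolerance = 1e-10)
})

test_that("BH step-up matches the hand-applied rule and stays monotone", {
  recs <- tibble::tibble(
    snp = paste0("s", 1:4), gene = "SST", stratum = "female",
    n = 34L, beta = 0, se = 1, p = c(0.01, 0.02, 0.03, 0.5), q = NA_real_
  )
  out <- bh_correct(recs, alpha = 0.05)
  # step-up: largest i with p_(i) <= i*alpha/m is i = 3 (0.03 <= 0.0375)
  expect_equal(sum(out$significant), 3)
  expect_true(all(out$q >= out$p))

  all1 <- recs
  all1$p <- rep(1, 4)
  expect_equal(sum(bh_correct(all1, 0.05)$significant), 0)

  set.seed(65)
  rand <- tibble::tibble(
    snp = paste0("s", 1:50), gene = "SST", stratum = "female",
    n = 34L, beta = 0, se = 1,
    p = pmin(1, rbeta(50, 0.4, 3)), q = NA_real_
  )
  sig01 <- bh_correct(rand, 0.01)$significant
  sig05 <- bh_correct(rand, 0.05)$significant
  expect_true(all(which(sig01) %in% which(sig05)))
})

test_that("BH families are per (gene, stratum) by default", {
  recs <- tibble::tibble(
    snp = rep(paste0("s", 1:3), 2),
    gene = rep(c("SST", "GAD67"), each = 3),
    stratum = "female", n = 34L, beta = 0, se = 1,
    p = c(0.01, 0.5, 0.9, 0.04, 0.04, 0.04), q = NA_real_
  )
  out <- bh_correct(recs, alpha = 0.05)
  expect_equal(out$q[out$gene == "SST"],
               p.adjust(c(0.01, 0.5, 0.9), "BH"))
  expect_equal(out$q[out$gene == "GAD67"],
               p.adjust(c(0.04, 0.04, 0.04), "BH"))
  pooled <- bh_correct(recs, alpha = 0.05, family = "pooled")
  expect_equal(pooled$q, p.adjust(recs$p, "BH"))
})

test_that("LD collapsing is single-linkage within a distance bound", {
  base <- rep(c(0L, 1L), 30)
  flip <- function(x, i) { x[i] <- 1L - x[i]; x }
  dos <- rbind(A = base, B = flip(base, 1:2), C = flip(base, 1:6),
               D = sample(c(0L, 1L), 60, TRUE))
  colnames(dos) <- paste0("s", 1:60)
  ann <- tibble::tibble(snp = c("A", "B", "C", "D"), chrom = "X",
                        position = c(1000L, 2000L, 3000L, 4000L),
                        ref = "A", alt = "G")
  sex <- setNames(rep("male", 60), colnames(dos))
  gt <- gabasex:::new_genotype_matrix(dos, sex, ann)

  r2 <- cor(t(dos))^2
  thr <- (min(r2["A", "B"], r2["B", "C"]) + r2["A", "C"]) / 2
  expect_true(r2["A", "C"] < thr)  # A-C below threshold: chain via B only
  bl <- collapse_blocks(c("A", "B", "C"), gt, r2_threshold = thr)
  expect_equal(bl$n_blocks, 1)
  expect_equal(sort(bl$blocks[[1]]), c("A", "B", "C"))

  # identical SNPs collapse; independent SNPs stay singletons
  same <- gabasex:::new_genotype_matrix(
    rbind(X1 = base, X2 = base, X3 = base), sex,
    tibble::tibble(snp = c("X1", "X2", "X3"), chrom = "X",
                   position = c(1L, 2L, 3L), ref = "A", alt = "G"))
  expect_equal(collapse_blocks(c("X1", "X2", "X3"), same)$n_blocks, 1)
  expect_equal(collapse_blocks(c("A", "D"), gt, r2_threshold = 0.8)$n_blocks, 0)
  expect_equal(collapse_blocks(c("A", "D"), gt, r2_threshold = 0.8)$n_singletons, 2)

  # distance bound vetoes even perfect correlation
  far <- gabasex:::new_genotype_matrix(
    rbind(F1 = base, F2 = base), sex,
    tibble::tibble(snp = c("F1", "F2"), chrom = "X",
                   position = c(1L, 10000000L), ref = "A", alt = "G"))
  expect_equal(collapse_blocks(c("F1", "F2"), far, max_bp = 500000L)$n_blocks, 0)
})

test_that("the cis window boundary is inclusive at exactly 50 kb", {
  cfg <- small_geno_config(seed = 66)
  gt <- simulate_x_genotypes(cfg)
  ch <- simulate_eqtl_cohort(cfg, gt)
  # gene whose start sits exactly window_bp beyond the first SNP
  pos1 <- gt$snp_annotation$position[1]
  ann <- tibble::tibble(gene = c("XG01", "XG02"), chrom = "X",
                        start = c(pos1 + 50000L, pos1 + 50001L),
                        end = c(pos1 + 65000L, pos1 + 65001L))
  xe <- ch$expression[c("XG01", "XG02"), , drop = FALSE]
  res <- cis_scan(gt$snp_annotation$snp[1], xe, ann, gt, ch$covariates,
                  "male", window_bp = 50000L)
  expect_true("XG01" %in% res$gene)
  expect_false("XG02" %in% res$gene)

  # every emitted pair satisfies the interval rule
  full <- cis_scan(gt$snp_annotation$snp[1:20], ch$expression,
                   ch$x_annotation, gt, ch$covariates, "male")
  pos <- gt$snp_annotation$position[match(full$snp, gt$snp_annotation$snp)]
  lo <- ch$x_annotation$start[match(full$gene, ch$x_annotation$gene)] - 50000L
  hi <- ch$x_annotation$end[match(full$gene, ch$x_annotation$gene)] + 50000L
  expect_true(all(pos >= lo & pos <= hi))
})

test_that("cis scan returns empty cleanly when nothing is in range", {
  cfg <- small_geno_config(seed = 67)
  gt <- simulate_x_genotypes(cfg)
  ch <- simulate_eqtl_cohort(cfg, gt)
  ann <- tibble::tibble(gene = "XG01", chrom = "X",
                        start = 900000000L, end = 900010000L)
  expect_message(
    res <- cis_scan(gt$snp_annotation$snp[1], ch$expression, ann, gt,
                    ch$covariates, "male"),
    "no transcript"
  )
  expect_equal(nrow(res), 0)
})

test_that("negative controls flag planted contamination and skip Y cleanly", {
  cfg <- small_geno_config(seed = 68)
  gt <- simulate_x_genotypes(cfg)
  ch <- simulate_eqtl_cohort(cfg, gt)

  contaminated <- attach_effects(
    ch$expression, gt,
    tibble::tibble(snp = "snp_00001", gene = "KDM5C",
                   stratum = "male", beta = 2))
  rep_bad <- negative_controls(cfg$control_genes, contaminated, gt,
                               ch$covariates)
  expect_false(rep_bad$pass)
  expect_identical(rep_bad$y_section, "skipped")
  expect_gt(rep_bad$n_significant, 0)
})

test_that("planted sex-specific effects surface in the right stratum", {
  cfg <- sim_config(seed = 69, n_background_genes = 5L)
  gt <- simulate_x_genotypes(cfg)
  ch <- simulate_eqtl_cohort(cfg, gt)
  expr <- attach_effects(ch$expression, gt, cfg)
  recs <- bh_correct(dplyr::bind_rows(
    trans_scan(expr, gt, ch$covariates, c("SST", "GAD67", "GAD65"), "female"),
    trans_scan(expr, gt, ch$covariates, c("SST", "GAD67", "GAD65"), "male")
  ))
  smry <- summarize_trans(recs, gt)
  # the planted pattern is female-biased overall
  expect_gt(sum(smry$n_significant[smry$stratum == "female"]), 0)
  # male SST carries no planted effect: stays (near) empty
  expect_lte(smry$n_significant[smry$stratum == "male" & smry$gene == "SST"],
             1)
})
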