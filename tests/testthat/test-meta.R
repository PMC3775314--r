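test_that("adjust_covariates: empty declared set is the identity", {
  studies <- simulate_study_collection(small_config(seed = 41))
  no_cov <- which(lengths(studies$declared_covariates) == 0)[1]
  st <- studies[no_cov, ]
  expect_identical(adjust_covariates(st, "SST"),
                   st$expression[[1]]["SST", ])
})

test_that("adjust_covariates removes the declared covariate exactly", {
  covs <- tibble::tibble(subject = sprintf("s%02d", 1:30),
                         age = seq(20, 78, length.out = 30))
  y <- 2 * covs$age + rnorm(30, sd = 0.5)
  st <- toy_study(y, covs, declared = "age")
  adj <- adjust_covariates(st, "G1")
  # least-squares residuals are numerically orthogonal to the regressor
  expect_lt(abs(cor(adj, covs$age)), 1e-10)
  expect_equal(mean(adj), mean(y))
  # a perfectly linear signal leaves (near-)zero residual variance
  st2 <- toy_study(2 * covs$age + 1, covs, declared = "age")
  expect_lt(var(adjust_covariates(st2, "G1") - mean(2 * covs$age + 1)),
            1e-20)
})

test_that("adjust_covariates errors name missing genes and singular covariates", {
  covs <- tibble::tibble(subject = c("a", "b", "c", "d"),
                         age = c(50, 50, 50, 50))
  st <- toy_study(c(1, 2, 3, 4), covs, declared = "age")
  expect_error(adjust_covariates(st, "G1"), "age")
  expect_error(adjust_covariates(st, "missing_gene"), "missing_gene")
})

test_that("hedges_g reproduces the hand-computed example and symmetries", {
  es <- hedges_g(c(1, 2, 3), c(3, 4, 5))
  # d = -2, df = 4, J = 1 - 3/15 = 0.8 => g = -1.6
  expect_equal(es$g, -1.6, tolerance = 1e-12)
  expect_equal(es$var_g, 6 / 9 + (-1.6)^2 / 12, tolerance = 1e-12)
  expect_equal(es$direction, -1)

  sw <- hedges_g(c(3, 4, 5), c(1, 2, 3))
  expect_equal(sw$g, 1.6, tolerance = 1e-12)
  expect_equal(sw$var_g, es$var_g, tolerance = 1e-12)

  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3))$g, 0)
  expect_error(hedges_g(c(1), c(1, 2)), "n >= 2")
  expect_error(hedges_g(c(1, 1), c(1, 1)), "pooled SD")
})

test_that("DerSimonian-Laird pooling matches an independent oracle", {
  # brute-force implementation straight from the estimator's definition
  dl_oracle <- function(g, v) {
    w <- 1 / v
    gw <- sum(w * g) / sum(w)
    Q <- sum(w * (g - gw)^2)
    k <- length(g)
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (v + tau2)
    mu <- sum(ws * g) / sum(ws)
    list(mu = mu, se = sqrt(1 / sum(ws)), tau2 = tau2, Q = Q)
  }
  eff <- tibble::tibble(g = c(-0.8, -0.5, -0.2), var_g = c(0.05, 0.04, 0.06))
  pooled <- pool_random_effects(eff)
  oracle <- dl_oracle(eff$g, eff$var_g)
  expect_equal(pooled$mu, oracle$mu, tolerance = 1e-10)
  expect_equal(pooled$tau2, oracle$tau2, tolerance = 1e-10)
  expect_equal(pooled$se_mu, oracle$se, tolerance = 1e-10)
  expect_equal(pooled$Q, oracle$Q, tolerance = 1e-10)
})

test_that("DerSimonian-Laird pooling agrees with metafor", {
  skip_if_not_installed("metafor")
  set.seed(77)
  for (i in 1:5) {
    k <- sample(3:10, 1)
    g <- rnorm(k, -0.5, 0.6)
    v <- runif(k, 0.02, 0.3)
    pooled <- pool_random_effects(tibble::tibble(g = g, var_g = v))
    ref <- metafor::rma(yi = g, vi = v, method = "DL")
    expect_equal(pooled$mu, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(pooled$tau2, ref$tau2, tolerance = 1e-8)
    expect_equal(pooled$se_mu, ref$se, tolerance = 1e-8)
  }
})

test_that("pooling degenerate cases: single study and exact homogeneity", {
  one <- pool_random_effects(tibble::tibble(g = 0.4, var_g = 0.1))
  expect_equal(one$mu, 0.4)
  expect_equal(one$tau2, 0)
  expect_equal(one$Q, 0)

  two <- pool_random_effects(tibble::tibble(g = c(0.5, 0.5),
                                            var_g = c(0.1, 0.1)))
  expect_equal(two$mu, 0.5)
  expect_equal(two$Q, 0)
  expect_equal(two$tau2, 0)
  expect_equal(two$ci95, c(0.5 - 1.96 * two$se_mu, 0.5 + 1.96 * two$se_mu))

  expect_error(pool_random_effects(tibble::tibble(g = double(),
                                                  var_g = double())),
               "no effects")
})

test_that("sex meta-regression recovers a near-noiseless moderator", {
  eff <- tibble::tibble(
    g = c(rep(-0.8, 4), rep(-0.3, 4)),
    var_g = rep(1e-6, 8),
    sex = rep(c("female", "male"), each = 4)
  )
  fit <- meta_regress_sex(eff)
  expect_equal(fit$beta_mod, 0.5, tolerance = 1e-6)
  expect_lt(fit$p_mod, 1e-10)
  expect_equal(fit$intercept, -0.8, tolerance = 1e-6)

  same <- eff
  same$g <- rep(-0.5, 8)
  expect_lt(abs(meta_regress_sex(same)$beta_mod), 1e-8)

  expect_error(meta_regress_sex(eff[eff$sex == "female", ]), "both sexes")
})

test_that("sex meta-regression matches metafor's mixed-effects fit", {
  skip_if_not_installed("metafor")
  set.seed(88)
  for (i in 1:5) {
    k <- 8
    sex <- rep(c("female", "male"), each = 4)
    g <- rnorm(k, ifelse(sex == "male", -0.2, -0.7), 0.4)
    v <- runif(k, 0.05, 0.2)
    fit <- meta_regress_sex(tibble::tibble(g = g, var_g = v, sex = sex))
    ref <- metafor::rma(yi = g, vi = v, mods = ~ factor(sex, c("female", "male")),
                        method = "DL")
    expect_equal(fit$beta_mod, as.numeric(ref$beta[2]), tolerance = 1e-8)
    expect_equal(fit$tau2, ref$tau2, tolerance = 1e-8)
    expect_equal(fit$p_mod, ref$pval[2], tolerance = 1e-8)
  }
})

test_that("Stouffer Z-trend identities and closed form hold", {
  one <- stouffer_z_trend(data.frame(p = 0.04, n = 30, direction = -1))
  expect_equal(one$p_two_sided, 0.04, tolerance = 1e-12)
  expect_equal(one$direction, -1)

  two <- stouffer_z_trend(data.frame(p = c(0.05, 0.05), n = c(25, 25),
                                     direction = c(1, 1)))
  expect_equal(two$Z, sqrt(2) * qnorm(0.975), tolerance = 1e-12)
  expect_equal(two$p_two_sided, 2 * (1 - pnorm(sqrt(2) * qnorm(0.975))),
               tolerance = 1e-12)

  opp <- stouffer_z_trend(data.frame(p = c(0.05, 0.05), n = c(25, 25),
                                     direction = c(1, -1)))
  expect_equal(opp$Z, 0)
  expect_equal(opp$p_two_sided, 1)
})

test_that("Stouffer combination is order-invariant and scales by sqrt(2)", {
  df <- data.frame(p = c(0.01, 0.2, 0.07), n = c(30, 18, 42),
                   direction = c(-1, -1, 1))
  expect_equal(stouffer_z_trend(df)$Z,
               stouffer_z_trend(df[c(3, 1, 2), ])$Z, tolerance = 1e-12)
  single <- data.frame(p = 0.03, n = 20, direction = -1)
  doubled <- rbind(single, single)
  expect_equal(stouffer_z_trend(doubled)$Z,
               sqrt(2) * stouffer_z_trend(single)$Z, tolerance = 1e-12)
  expect_error(stouffer_z_trend(data.frame(p = 0, n = 5, direction = 1)),
               "floor")
  expect_error(stouffer_z_trend(data.frame(p = 0.5, n = 5, direction = 0)),
               "direction")
})

test_that("percent-of-control weighting and SEM behave as specified", {
  expect_equal(percent_of_control(
    data.frame(mean_ctrl = 10, mean_mdd = 10, n = 12))$pct, 100)
  combo <- percent_of_control(
    data.frame(mean_ctrl = c(10, 10), mean_mdd = c(8, 6), n = c(10, 30)))
  expect_equal(combo$pct, 65)
  flat <- percent_of_control(
    data.frame(mean_ctrl = c(5, 8, 2), mean_mdd = c(4, 6.4, 1.6),
               n = c(10, 20, 30)))
  expect_equal(flat$sem, 0)
  expect_error(percent_of_control(
    data.frame(mean_ctrl = 0, mean_mdd = 1, n = 5)), "positive")
})

test_that("tidy and glance methods return the documented columns", {
  eff <- tibble::tibble(g = c(-0.8, -0.5, -0.2), var_g = c(0.05, 0.04, 0.06),
                        sex = c("female", "female", "male"))
  pooled <- pool_random_effects(eff)
  td <- tidy(pooled)
  expect_named(td, c("term", "estimate", "std.error", "conf.low",
                     "conf.high", "p.value"))
  expect_equal(td$estimate, pooled$mu)
  gl <- glance(pooled)
  expect_equal(gl$k, 3)
  fit <- meta_regress_sex(eff)
  expect_equal(tidy(fit)$estimate[2], fit$beta_mod)
})
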