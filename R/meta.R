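#' Covariate-adjust one gene's expression within a study
#'
#' Regresses the gene's expression on the study's declared covariates and
#' returns the residuals with the study mean added back, so the adjusted
#' values stay on the original expression scale. A study declaring no
#' covariates is returned unchanged.
#'
#' @param study a single expression study: a list or one-row tibble with
#'   elements/columns `expression` (genes x subjects matrix), `covariates`
#'   (data frame) and `declared_covariates` (character vector). Rows of
#'   [simulate_study_collection()] output qualify.
#' @param gene gene identifier to adjust.
#' @return named numeric vector of adjusted expression, one per subject.
#' @examples
#' studies <- simulate_study_collection(sim_config(seed = 1))
#' adj <- adjust_covariates(studies[1, ], "SST")
#' @export
adjust_covariates <- function(study, gene) {
  study <- as_study(study)
  expr <- study$expression
  if (!gene %in% rownames(expr)) {
    stop("gene '", gene, "' not present in study expression", call. = FALSE)
  }
  y <- expr[gene, ]
  declared <- study$declared_covariates
  if (length(declared) == 0) return(y)
  covs <- study$covariates
  missing_cov <- setdiff(declared, names(covs))
  if (length(missing_cov) > 0) {
    stop("declared covariate(s) not in covariate table: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  for (cv in declared) {
    if (stats::var(as.numeric(covs[[cv]])) == 0) {
      stop("covariate '", cv, "' is constant; design is singular",
           call. = FALSE)
    }
  }
  X <- stats::model.matrix(
    stats::reformulate(declared),
    data = as.data.frame(covs[declared])
  )
  fit <- stats::lm.fit(X, y)
  stats::setNames(fit$residuals + mean(y), names(y))
}

as_study <- function(study) {
  if (is.data.frame(study)) {
    stopifnot(nrow(study) == 1)
    study <- as.list(study)
    for (f in c("expression", "covariates", "declared_covariates")) {
      if (is.list(study[[f]]) && !is.data.frame(study[[f]])) {
        study[[f]] <- study[[f]][[1]]
      }
    }
  }
  study
}

#' Hedges' g standardized mean difference
#'
#' Small-sample-corrected standardized mean difference between a case and
#' a control group: `g = J * (mean_case - mean_control) / s_pooled` with
#' `J = 1 - 3 / (4 * df - 1)`, `df = n1 + n2 - 2`, and sampling variance
#' `var_g = (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))`.
#'
#' @param case,control numeric vectors of (adjusted) expression values.
#' @param study_id,sex,region optional labels carried into the result.
#' @return one-row tibble: `study_id`, `g`, `var_g`, `n_case`, `n_control`,
#'   `sex`, `region`, `direction` (sign of the raw mean difference).
#' @examples
#' hedges_g(c(1, 2, 3), c(3, 4, 5))   # g = -1.6
#' @export
hedges_g <- function(case, control, study_id = NA_character_,
                     sex = NA_character_, region = NA_character_) {
  case <- as.numeric(case); control <- as.numeric(control)
  if (length(case) < 2 || length(control) < 2) {
    stop("hedges_g: each group needs n >= 2", call. = FALSE)
  }
  if (anyNA(case) || anyNA(control) ||
      any(!is.finite(c(case, control)))) {
    stop("hedges_g: values must be finite", call. = FALSE)
  }
  n1 <- length(case); n2 <- length(control)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(case) + (n2 - 1) * stats::var(control)) / df
  if (sp2 <= 0) stop("hedges_g: pooled SD is zero", call. = FALSE)
  d <- (mean(case) - mean(control)) / sqrt(sp2)
  J <- 1 - 3 / (4 * df - 1)
  g <- J * d
  var_g <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
  tibble::tibble(
    study_id = study_id, g = g, var_g = var_g,
    n_case = n1, n_control = n2, sex = sex, region = region,
    direction = sign(mean(case) - mean(control))
  )
}

#' Per-study effect sizes for one gene across a study collection
#'
#' Convenience wrapper: covariate-adjusts the gene in every study and
#' computes Hedges' g of MDD versus control.
#'
#' @param studies output of [simulate_study_collection()] (or a tibble of
#'   the same shape).
#' @param gene gene to analyze.
#' @return tibble of effect sizes, one row per study (see [hedges_g()]).
#' @export
study_effect_sizes <- function(studies, gene) {
  purrr::map_dfr(seq_len(nrow(studies)), function(i) {
    st <- studies[i, ]
    adj <- adjust_covariates(st, gene)
    diag <- st$covariates[[1]]$diagnosis
    hedges_g(adj[diag == "MDD"], adj[diag == "control"],
             study_id = st$study_id, sex = st$sex, region = st$region)
  })
}

#' DerSimonian-Laird random-effects pooling
#'
#' Pools per-study standardized effects under the non-iterative
#' DerSimonian-Laird random-effects model: with fixed-effect weights
#' `w_i = 1 / var_g_i`, heterogeneity `Q = sum w_i (g_i - g_bar_w)^2`,
#' `tau2 = max(0, (Q - (k - 1)) / (sum w - sum w^2 / sum w))`, and pooled
#' mean from weights `1 / (var_g_i + tau2)`. The 95% CI uses the normal
#' multiplier 1.96 and the p-value a normal reference.
#'
#' @param effects tibble with columns `g` and `var_g` (e.g. from
#'   [study_effect_sizes()]); other columns are retained for the forest
#'   display.
#' @return object of class `pooled_effect`; see [tidy.pooled_effect()].
#' @examples
#' eff <- tibble::tibble(g = c(-0.8, -0.5, -0.2), var_g = c(0.05, 0.04, 0.06))
#' pool_random_effects(eff)
#' @export
pool_random_effects <- function(effects) {
  if (nrow(effects) == 0) stop("pool_random_effects: no effects", call. = FALSE)
  if (any(effects$var_g <= 0)) {
    stop("pool_random_effects: all var_g must be > 0", call. = FALSE)
  }
  g <- effects$g; v <- effects$var_g; k <- length(g)
  w <- 1 / v
  gbar <- sum(w * g) / sum(w)
  Q <- sum(w * (g - gbar)^2)
  tau2 <- if (k > 1) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  ws <- 1 / (v + tau2)
  mu <- sum(ws * g) / sum(ws)
  se <- sqrt(1 / sum(ws))
  p <- 2 * stats::pnorm(-abs(mu / se))
  structure(
    list(mu = mu, se_mu = se, ci95 = c(mu - 1.96 * se, mu + 1.96 * se),
         tau2 = tau2, Q = Q, df_Q = k - 1, p_rem = p, k = k,
         effects = effects),
    class = "pooled_effect"
  )
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf(
    "Random-effects pooled estimate (DerSimonian-Laird, k = %d)\n", x$k))
  cat(sprintf("  mu = %.4f [%.4f, %.4f], SE = %.4f, p = %.3g\n",
              x$mu, x$ci95[1], x$ci95[2], x$se_mu, x$p_rem))
  cat(sprintf("  tau2 = %.4f, Q = %.3f (df = %d)\n", x$tau2, x$Q, x$df_Q))
  invisible(x)
}

#' Meta-regression with a binary sex moderator
#'
#' Mixed-effects meta-regression of per-study effects on sex: residual
#' between-study variance by the generalized method of moments
#' (DerSimonian-Laird form with moderators), then weighted least squares
#' with weights `1 / (var_g + tau2)`. The moderator coefficient is coded
#' male minus female (female is the reference level) and tested with a
#' Wald chi-square (QM) on 1 degree of freedom.
#'
#' @param effects tibble with columns `g`, `var_g`, `sex`; both sexes must
#'   be present and k >= 3.
#' @return object of class `moderator_fit` with elements `beta_mod`,
#'   `se_beta`, `QM`, `p_mod`, `tau2`, `intercept` (pooled female effect)
#'   and `k`.
#' @export
meta_regress_sex <- function(effects) {
  if (length(unique(effects$sex)) < 2) {
    stop("meta_regress_sex: both sexes must be represented", call. = FALSE)
  }
  k <- nrow(effects)
  if (k < 3) stop("meta_regress_sex: needs k >= 3 studies", call. = FALSE)
  g <- effects$g; v <- effects$var_g
  X <- cbind(1, as.numeric(effects$sex == "male"))
  p <- ncol(X)

  W <- diag(1 / v, k)
  XtWX <- crossprod(X, W %*% X)
  b_fe <- solve(XtWX, crossprod(X, W %*% g))
  r <- g - X %*% b_fe
  QE <- drop(crossprod(r, W %*% r))
  P <- W - W %*% X %*% solve(XtWX, crossprod(X, W))
  tau2 <- max(0, (QE - (k - p)) / sum(diag(P)))

  Ws <- diag(1 / (v + tau2), k)
  XtWsX <- crossprod(X, Ws %*% X)
  b <- solve(XtWsX, crossprod(X, Ws %*% g))
  vb <- solve(XtWsX)
  beta <- b[2]; se <- sqrt(vb[2, 2])
  QM <- (beta / se)^2
  structure(
    list(beta_mod = beta, se_beta = se, QM = QM,
         p_mod = stats::pchisq(QM, df = 1, lower.tail = FALSE),
         tau2 = tau2, intercept = b[1], k = k),
    class = "moderator_fit"
  )
}

#' @export
print.moderator_fit <- function(x, ...) {
  cat(sprintf("Sex-moderator meta-regression (k = %d)\n", x$k))
  cat(sprintf("  beta (male - female) = %.4f (SE %.4f), QM = %.3f, p = %.3g\n",
              x$beta_mod, x$se_beta, x$QM, x$p_mod))
  cat(sprintf("  residual tau2 = %.4f\n", x$tau2))
  invisible(x)
}

#' Weighted Stouffer Z-trend p-value combination
#'
#' Combines two-sided per-study p-values while honoring sample size and
#' direction of effect: each study contributes a signed one-sided normal
#' quantile `z_i = dir_i * qnorm(1 - p_i / 2)`, combined as
#' `Z = sum(sqrt(n_i) * z_i) / sqrt(sum(n_i))`, with two-sided combined
#' p-value `2 * (1 - pnorm(|Z|))`.
#'
#' @param studies data frame with columns `p` (two-sided p-values in
#'   (0, 1]), `n` (sample sizes >= 1) and `direction` (+1 or -1).
#' @return one-row tibble: `Z`, `p_two_sided`, `direction` (sign of Z; 0
#'   on exact cancellation), `k`.
#' @examples
#' stouffer_z_trend(data.frame(p = c(0.05, 0.05), n = c(20, 20),
#'                             direction = c(-1, -1)))
#' @export
stouffer_z_trend <- function(studies) {
  p <- studies$p; n <- studies$n; dir <- studies$direction
  if (any(p <= 0)) {
    stop("stouffer_z_trend: p must be > 0 (floor tiny p at .Machine$double.xmin)",
         call. = FALSE)
  }
  if (any(p > 1)) stop("stouffer_z_trend: p must be <= 1", call. = FALSE)
  if (any(n < 1)) stop("stouffer_z_trend: n must be >= 1", call. = FALSE)
  if (!all(dir %in% c(-1, 1))) {
    stop("stouffer_z_trend: direction must be +1 or -1", call. = FALSE)
  }
  z <- dir * stats::qnorm(1 - p / 2)
  Z <- sum(sqrt(n) * z) / sqrt(sum(n))
  tibble::tibble(
    Z = Z,
    p_two_sided = 2 * stats::pnorm(-abs(Z)),
    direction = sign(Z),
    k = length(p)
  )
}

#' Sample-size-weighted percent-of-control summary
#'
#' Expresses each study's case mean as a percentage of its control mean
#' (control set to 100%), then combines studies by their sample-size
#' weighted average. The SEM is the square root of the unbiased N-weighted
#' variance of the per-study percentages divided by the number of studies.
#'
#' @param studies data frame with columns `mean_ctrl` (> 0), `mean_mdd`,
#'   `n`.
#' @return one-row tibble: `pct` (weighted mean percentage), `sem`, `k`.
#' @examples
#' percent_of_control(data.frame(mean_ctrl = c(10, 10), mean_mdd = c(8, 6),
#'                               n = c(10, 30)))   # 65%
#' @export
percent_of_control <- function(studies) {
  if (any(studies$mean_ctrl <= 0)) {
    stop("percent_of_control: control means must be positive", call. = FALSE)
  }
  pct <- 100 * studies$mean_mdd / studies$mean_ctrl
  n <- studies$n
  k <- length(pct)
  pbar <- sum(n * pct) / sum(n)
  sem <- if (k > 1) {
    vw <- sum(n * (pct - pbar)^2) / (sum(n) - sum(n^2) / sum(n))
    sqrt(vw / k)
  } else 0
  tibble::tibble(pct = pbar, sem = sem, k = k)
}
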