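#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pooled random-effects estimate
#' @param x a `pooled_effect`.
#' @param ... unused.
#' @return one-row tibble: estimate, std.error, conf.low, conf.high,
#'   p.value.
#' @export
tidy.pooled_effect <- function(x, ...) {
  tibble::tibble(
    term = "pooled", estimate = x$mu, std.error = x$se_mu,
    conf.low = x$ci95[1], conf.high = x$ci95[2], p.value = x$p_rem
  )
}

#' Model-level summary of a pooled random-effects estimate
#' @param x a `pooled_effect`.
#' @param ... unused.
#' @return one-row tibble: k, tau2, Q, df.Q, p.value.
#' @export
glance.pooled_effect <- function(x, ...) {
  tibble::tibble(k = x$k, tau2 = x$tau2, Q = x$Q, df.Q = x$df_Q,
                 p.value = x$p_rem)
}

#' Tidy a sex-moderator meta-regression fit
#' @param x a `moderator_fit`.
#' @param ... unused.
#' @return two-row tibble (intercept = pooled female effect, sex_male =
#'   male-minus-female difference).
#' @export
tidy.moderator_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept_female", "sex_male"),
    estimate = c(x$intercept, x$beta_mod),
    std.error = c(NA_real_, x$se_beta),
    statistic = c(NA_real_, x$QM),
    p.value = c(NA_real_, x$p_mod)
  )
}

#' Model-level summary of a moderator fit
#' @param x a `moderator_fit`.
#' @param ... unused.
#' @return one-row tibble: k, tau2, QM, p.value.
#' @export
glance.moderator_fit <- function(x, ...) {
  tibble::tibble(k = x$k, tau2 = x$tau2, QM = x$QM, p.value = x$p_mod)
}

#' Tidy an FCG three-way ANOVA
#' @param x an `fcg_anova`.
#' @param ... unused.
#' @return the term table with the endpoint label prepended.
#' @export
tidy.fcg_anova <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(endpoint = x$endpoint), x$terms)
}

#' Model-level summary of an FCG ANOVA
#' @param x an `fcg_anova`.
#' @param ... unused.
#' @return one-row tibble: endpoint, n, r.squared, n.significant.
#' @export
glance.fcg_anova <- function(x, ...) {
  tibble::tibble(
    endpoint = x$endpoint, n = x$n,
    r.squared = summary(x$model)$r.squared,
    n.significant = sum(x$terms$significant)
  )
}
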