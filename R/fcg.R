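#' Derive behavioral endpoints from raw FCG measurements
#'
#' Applies the standard endpoint formulas: percent open-arm entries =
#' open / (open + closed) * 100; percent center distance = center distance
#' / total distance * 100; sucrose preference = sucrose / (sucrose + water)
#' * 100. Zero denominators yield missing endpoints (the affected animals
#' are recorded in the `degenerate` attribute and excluded listwise from
#' later ANOVA of that endpoint). Times and expression values pass through
#' unchanged.
#'
#' @param raw tibble from [simulate_fcg()] (or same columns).
#' @return tibble: design factors plus `open_time`, `pct_open_entries`,
#'   `center_time`, `pct_center_distance`, `total_entries`,
#'   `total_distance`, `sucrose_pref`, `Sst`, `Gad67`, `Gad65`. Attribute
#'   `degenerate` lists animal/endpoint pairs lost to zero denominators.
#' @examples
#' ep <- derive_endpoints(simulate_fcg(sim_config(seed = 1)))
#' @export
derive_endpoints <- function(raw) {
  counts <- c("open_entries", "closed_entries")
  if (any(raw[counts] < 0)) {
    stop("derive_endpoints: negative entry counts", call. = FALSE)
  }
  total_entries <- raw$open_entries + raw$closed_entries
  pct_open <- ifelse(total_entries > 0,
                     100 * raw$open_entries / total_entries, NA_real_)
  pct_center <- ifelse(raw$total_distance > 0,
                       100 * raw$center_distance / raw$total_distance,
                       NA_real_)
  fluid <- raw$sucrose_ml + raw$water_ml
  pref <- ifelse(fluid > 0, 100 * raw$sucrose_ml / fluid, NA_real_)

  out <- tibble::tibble(
    animal_id = raw$animal_id,
    genetic_sex = raw$genetic_sex,
    gonadal_sex = raw$gonadal_sex,
    treatment = raw$treatment,
    open_time = raw$open_time,
    pct_open_entries = pct_open,
    center_time = raw$center_time,
    pct_center_distance = pct_center,
    total_entries = total_entries,
    total_distance = raw$total_distance,
    sucrose_pref = pref,
    Sst = raw$Sst, Gad67 = raw$Gad67, Gad65 = raw$Gad65
  )
  attr(out, "degenerate") <- tibble::tibble(
    animal_id = c(raw$animal_id[is.na(pct_open)],
                  raw$animal_id[is.na(pct_center)],
                  raw$animal_id[is.na(pref)]),
    endpoint = c(rep("pct_open_entries", sum(is.na(pct_open))),
                 rep("pct_center_distance", sum(is.na(pct_center))),
                 rep("sucrose_pref", sum(is.na(pref))))
  )
  out
}

fcg_endpoints <- function() {
  c("open_time", "pct_open_entries", "center_time", "pct_center_distance",
    "total_entries", "total_distance", "sucrose_pref",
    "Sst", "Gad67", "Gad65")
}

#' Three-way factorial ANOVA of one FCG endpoint
#'
#' Genetic sex x gonadal sex x treatment ANOVA with Type III sums of
#' squares under sum-to-zero contrasts (the design cells are unbalanced,
#' so Type III is the appropriate decomposition; on a balanced design it
#' coincides with the sequential Type I decomposition). All seven terms
#' (three main effects, three two-way interactions, the three-way
#' interaction) are F-tested. When requested, Tukey-adjusted pairwise
#' contrasts are computed on the marginal means of each significant main
#' effect and on the four cell means of each significant two-way
#' interaction. Significance is flagged at p < 0.05 and trend level at
#' p < 0.1.
#'
#' @param endpoints tibble from [derive_endpoints()].
#' @param endpoint endpoint column to analyze.
#' @param posthoc compute Tukey contrasts for significant terms
#'   (default TRUE; turn off in large simulation loops).
#' @param locomotor_covariate optional column name (e.g. `"total_entries"`
#'   or `"total_distance"`) entered as a numeric covariate, turning the
#'   model into an ANCOVA that controls anxiety endpoints for locomotor
#'   activity.
#' @return object of class `fcg_anova`: list with `endpoint`, `terms`
#'   (tibble term, sumsq, df, statistic, p.value, significant, trend),
#'   `posthoc` (tibble of Tukey contrasts or NULL), `n`, `model`.
#' @examples
#' ep <- derive_endpoints(simulate_fcg(sim_config(seed = 1)))
#' fit <- three_way_anova(ep, "Sst")
#' fit$terms
#' @export
three_way_anova <- function(endpoints, endpoint, posthoc = TRUE,
                            locomotor_covariate = NULL) {
  stopifnot(endpoint %in% names(endpoints))
  if (!is.null(locomotor_covariate)) {
    stopifnot(locomotor_covariate %in% names(endpoints))
  }
  dat <- endpoints[!is.na(endpoints[[endpoint]]), ]
  dat$genetic_sex <- factor(dat$genetic_sex, levels = c("XX", "XY"))
  dat$gonadal_sex <- factor(dat$gonadal_sex, levels = c("female", "male"))
  dat$treatment <- factor(dat$treatment,
                          levels = c("blank", "testosterone"))
  cell_n <- table(dat$genetic_sex, dat$gonadal_sex, dat$treatment)
  if (any(cell_n < 2)) {
    empty <- which(cell_n < 2, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "three_way_anova: cell %s/%s/%s has fewer than 2 animals for '%s'",
      dimnames(cell_n)[[1]][empty[1]], dimnames(cell_n)[[2]][empty[2]],
      dimnames(cell_n)[[3]][empty[3]], endpoint), call. = FALSE)
  }
  dat$.y <- dat[[endpoint]]
  if (stats::var(dat$.y) == 0) {
    # degenerate constant response: every effect has zero sum of squares
    terms <- tibble::tibble(
      term = c("genetic_sex", "gonadal_sex", "treatment",
               "genetic_sex:gonadal_sex", "genetic_sex:treatment",
               "gonadal_sex:treatment", "genetic_sex:gonadal_sex:treatment"),
      sumsq = 0, df = 1L, statistic = NaN, p.value = NA_real_,
      significant = FALSE, trend = FALSE
    )
    return(structure(
      list(endpoint = endpoint, terms = terms, posthoc = NULL,
           n = nrow(dat), model = NULL),
      class = "fcg_anova"
    ))
  }
  rhs <- "genetic_sex * gonadal_sex * treatment"
  if (!is.null(locomotor_covariate)) {
    rhs <- paste(locomotor_covariate, "+", rhs)
  }
  fit <- stats::lm(
    stats::as.formula(paste(".y ~", rhs)), data = dat,
    contrasts = list(genetic_sex = "contr.sum", gonadal_sex = "contr.sum",
                     treatment = "contr.sum")
  )
  a3 <- car::Anova(fit, type = 3)
  keep <- !rownames(a3) %in% c("(Intercept)", "Residuals")
  terms <- tibble::tibble(
    term = rownames(a3)[keep],
    sumsq = a3$`Sum Sq`[keep],
    df = a3$Df[keep],
    statistic = a3$`F value`[keep],
    p.value = a3$`Pr(>F)`[keep]
  )
  terms$significant <- terms$p.value < 0.05
  terms$trend <- terms$p.value < 0.1

  ph <- NULL
  if (posthoc && any(terms$significant)) {
    ph <- purrr::map_dfr(terms$term[terms$significant], function(tm) {
      tukey_contrasts(fit, tm)
    })
  }
  structure(
    list(endpoint = endpoint, terms = terms, posthoc = ph,
         n = nrow(dat), model = fit),
    class = "fcg_anova"
  )
}

# Tukey-adjusted pairwise contrasts for one ANOVA term via emmeans;
# three-way cells are compared only when the three-way term itself is
# significant.
tukey_contrasts <- function(fit, term) {
  vars <- strsplit(term, ":", fixed = TRUE)[[1]]
  em <- suppressMessages(emmeans::emmeans(fit, vars))
  pr <- as.data.frame(suppressMessages(
    emmeans::contrast(em, method = "pairwise", adjust = "tukey")))
  tibble::tibble(
    term = term,
    contrast = as.character(pr$contrast),
    estimate = pr$estimate,
    se = pr$SE,
    p.adjusted = pr$p.value
  )
}

#' @export
print.fcg_anova <- function(x, ...) {
  cat("Three-way ANOVA (Type III) of '", x$endpoint, "' (n = ", x$n,
      ")\n", sep = "")
  print(as.data.frame(x$terms), digits = 4)
  if (!is.null(x$posthoc)) {
    cat("Tukey contrasts for significant terms:\n")
    print(as.data.frame(x$posthoc), digits = 4)
  }
  invisible(x)
}

#' Directional summary of FCG main effects across endpoints
#'
#' For every endpoint and main factor, reports the direction of the
#' marginal mean difference (second level minus first: XY - XX,
#' gonadal male - female, testosterone - blank) and its significance tier
#' (`"significant"` p < 0.05, `"trend"` p < 0.1, `"ns"`), in the layout of
#' a factorial statistics appendix table. Interaction terms are included
#' with direction NA.
#'
#' @param results list of `fcg_anova` objects (possibly one).
#' @param endpoints the endpoint table the models were fitted on (used for
#'   marginal means).
#' @return tibble: `endpoint`, `term`, `direction` (+1/-1/NA), `delta`
#'   (marginal mean difference), `p.value`, `tier`.
#' @export
main_effect_summary <- function(results, endpoints) {
  if (inherits(results, "fcg_anova")) results <- list(results)
  if (length(results) == 0) {
    stop("main_effect_summary: no results", call. = FALSE)
  }
  second_level <- c(genetic_sex = "XY", gonadal_sex = "male",
                    treatment = "testosterone")
  purrr::map_dfr(results, function(res) {
    purrr::map_dfr(seq_len(nrow(res$terms)), function(i) {
      term <- res$terms$term[i]
      p <- res$terms$p.value[i]
      delta <- NA_real_
      if (term %in% names(second_level)) {
        y <- endpoints[[res$endpoint]]
        f <- endpoints[[term]]
        delta <- mean(y[f == second_level[[term]]], na.rm = TRUE) -
          mean(y[f != second_level[[term]]], na.rm = TRUE)
      }
      tibble::tibble(
        endpoint = res$endpoint, term = term,
        direction = if (is.na(delta)) NA_real_ else sign(delta),
        delta = delta, p.value = p,
        tier = if (p < 0.05) "significant" else if (p < 0.1) "trend" else "ns"
      )
    })
  })
}

#' Run the factorial analysis over all endpoints
#'
#' @param endpoints tibble from [derive_endpoints()].
#' @param which endpoints to analyze (default all ten).
#' @param posthoc passed to [three_way_anova()].
#' @return named list of `fcg_anova` objects.
#' @export
analyze_fcg <- function(endpoints, which = fcg_endpoints(), posthoc = TRUE) {
  stats::setNames(
    purrr::map(which, function(e) three_way_anova(endpoints, e, posthoc)),
    which
  )
}
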