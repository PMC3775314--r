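#' Simulate a Four Core Genotypes behavioral/expression dataset
#'
#' Animals fill the eight cells of the genetic sex (XX/XY) x gonadal sex
#' (female/male) x treatment (blank/testosterone) design with the sizes in
#' `config$fcg_cell_sizes`. Each endpoint is drawn as
#' `mean + SD * (planted deltas) + SD * noise` on its natural scale
#' (`config$fcg_scales`), with deltas from `config$fcg_effects`: genetic
#' delta applied to XY animals, gonadal delta to gonadal males, treatment
#' delta to testosterone animals, and the interaction delta to
#' gonadal-male + testosterone animals only.
#'
#' Raw behavioral counts are then back-computed so the derived endpoints
#' carry the planted effects: open/closed arm entries from the planted
#' total-entry count and percent-open-entry value, center/total distance
#' from the planted percent-center-distance, and sucrose/water volumes from
#' the planted sucrose preference. Times are truncated to the 600-s
#' session; counts are non-negative integers.
#'
#' @param config a [sim_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return tibble with one row per animal: factors `genetic_sex`
#'   (`"XX"`/`"XY"`), `gonadal_sex`, `treatment`; raw measures
#'   `open_entries`, `closed_entries`, `open_time`, `center_time`,
#'   `center_distance`, `total_distance`, `sucrose_ml`, `water_ml`; and
#'   expression values `Sst`, `Gad67`, `Gad65`.
#' @examples
#' fcg <- simulate_fcg(sim_config(seed = 1))
#' table(fcg$genetic_sex, fcg$gonadal_sex, fcg$treatment)
#' @export
simulate_fcg <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- config$fcg_cell_sizes
  if (any(sizes < 2)) abort_config("fcg_cell_sizes", "needs n >= 2 per cell")
  seed <- seed %||% derive_seed(config$seed, SEED_OFFSETS[["fcg"]])
  with_seed(seed, {
    cells <- do.call(rbind, strsplit(names(sizes), "_"))
    design <- tibble::tibble(
      genetic_sex = rep(cells[, 1], sizes),
      gonadal_sex = rep(cells[, 2], sizes),
      treatment = rep(cells[, 3], sizes)
    )
    n <- nrow(design)
    design$animal_id <- sprintf("A%03d", seq_len(n))

    eff <- config$fcg_effects
    scl <- config$fcg_scales
    latent <- function(endpoint) {
      e <- eff[eff$endpoint == endpoint, ]
      s <- scl[scl$endpoint == endpoint, ]
      if (nrow(s) != 1) stop("no scale for endpoint ", endpoint, call. = FALSE)
      d <- if (nrow(e) == 1) e else
        tibble::tibble(genetic_delta = 0, gonadal_delta = 0,
                       treatment_delta = 0, interaction_delta = 0)
      mu <- s$mean +
        s$sd * d$genetic_delta * (design$genetic_sex == "XY") +
        s$sd * d$gonadal_delta * (design$gonadal_sex == "male") +
        s$sd * d$treatment_delta * (design$treatment == "testosterone") +
        s$sd * d$interaction_delta *
          (design$gonadal_sex == "male" & design$treatment == "testosterone")
      mu + s$sd * stats::rnorm(n)
    }

    total_entries <- pmax(1, round(latent("total_entries")))
    pct_open <- pmin(99, pmax(1, latent("pct_open_entries")))
    open_entries <- pmin(total_entries, pmax(0L, round(total_entries * pct_open / 100)))
    closed_entries <- total_entries - open_entries

    total_distance <- pmax(1, round(latent("total_distance"), 1))
    pct_center <- pmin(99, pmax(0.5, latent("pct_center_distance")))
    center_distance <- round(total_distance * pct_center / 100, 1)

    open_time <- pmin(600, pmax(0, round(latent("open_time"), 1)))
    center_time <- pmin(600, pmax(0, round(latent("center_time"), 1)))

    total_fluid <- rnorm_trunc(n, 10, 1.5, 2, 20)
    pref <- pmin(99.5, pmax(1, latent("sucrose_pref")))
    sucrose_ml <- round(total_fluid * pref / 100, 2)
    water_ml <- round(total_fluid - sucrose_ml, 2)

    dplyr::bind_cols(
      design[, c("animal_id", "genetic_sex", "gonadal_sex", "treatment")],
      tibble::tibble(
        open_entries = as.integer(open_entries),
        closed_entries = as.integer(closed_entries),
        open_time = open_time,
        center_time = center_time,
        center_distance = center_distance,
        total_distance = total_distance,
        sucrose_ml = sucrose_ml,
        water_ml = water_ml,
        Sst = latent("Sst"),
        Gad67 = latent("Gad67"),
        Gad65 = latent("Gad65")
      )
    )
  })
}
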