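# Internal helpers shared across modules.

#' Run code under a temporary RNG seed, restoring global state afterwards
#'
#' @param seed integer seed, or NULL to run unseeded.
#' @param code expression to evaluate.
#' @return value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Per-stage seed derivation: a single pipeline seed fans out to independent
# sub-streams so rerunning one stage never perturbs another.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + offset) %% 2147483647L)
}

SEED_OFFSETS <- c(
  studies   = 101L,
  coexpr    = 202L,
  genotypes = 303L,
  eqtl_expr = 404L,
  fcg       = 505L
)

# Truncated normal draw by rejection; ranges here are wide so this is cheap.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_config <- function(field, msg) {
  stop(sprintf("invalid simulation config: field '%s' %s", field, msg), call. = FALSE)
}
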