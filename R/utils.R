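# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
stage_seed <- function(seed, stage) {
  # named per-stage substream: distinct, reproducible, < 2^31
  offsets <- c(trees = 11L, occurrences = 23L, pa = 37L, regression = 41L,
               jackknife = 53L, endemic = 67L, cluster = 71L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 97 + off) %% 2147483647)
}

#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Exact (Clopper-Pearson) binomial interval, vectorized over x.
#' @keywords internal
#' @noRd
binom_ci_exact <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- ifelse(x == 0, 0, stats::qbeta(a, x, n - x + 1))
  hi <- ifelse(x == n, 1, stats::qbeta(1 - a, x + 1, n - x))
  cbind(lower = lo, upper = hi)
}
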