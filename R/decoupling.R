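#' Richness-decoupling experiment for index selection
#'
#' The case for prioritizing on a mean-type index instead of a total-type
#' index is that the former barely tracks species richness. This experiment
#' makes that testable without any map: draw random species subsets of size
#' m from the pooled species list (all trees together), compute the
#' aggregated AvTD and PD of each subset, and regress the standardized
#' expected index value on standardized m. PD climbs almost linearly with m;
#' AvTD flattens out once a few pairs are present.
#'
#' @param ts a [treeset()].
#' @param m_values subset sizes; default an even ladder from 2 to the pool
#'   size.
#' @param draws random subsets per m.
#' @param seed integer seed.
#' @return list with `slope_avtd`, `slope_pd` (standardized OLS slopes of
#'   E\[index\] on m) and `table` (data.frame `m,mean_avtd,mean_pd`).
#' @export
richness_decoupling <- function(ts, m_values = NULL, draws = 200, seed = 1) {
  stopifnot(inherits(ts, "treeset"))
  pool <- names(ts$species_index)
  if (is.null(m_values))
    m_values <- unique(round(seq(2, length(pool), length.out = 25)))
  m_values <- m_values[m_values >= 2 & m_values <= length(pool)]
  pms <- lapply(ts$groups, patristic)
  profs <- lapply(ts$groups, tree_profile)
  groups <- ts$species_index

  eval_subset <- function(sp) {
    avtd <- 0; pd <- 0
    for (g in unique(groups[sp])) {
      tips <- sp[groups[sp] == g]
      pm <- pms[[g]]
      idx <- match(tips, pm$labels)
      m <- length(idx)
      if (m >= 2) avtd <- avtd + sum(pm$d[idx, idx]) / (m * (m - 1))
      prof <- profs[[g]]
      cnt <- colSums(prof$incidence[idx, , drop = FALSE])
      pd <- pd + sum(prof$lengths[cnt > 0 & cnt < m])
    }
    c(avtd = avtd, pd = pd)
  }

  with_seed(seed, {
    tab <- t(vapply(m_values, function(m) {
      v <- rowMeans(vapply(seq_len(draws), function(i)
        eval_subset(sample(pool, m)), numeric(2)))
      c(m = m, mean_avtd = v[["avtd"]], mean_pd = v[["pd"]])
    }, numeric(3)))
  })
  tab <- as.data.frame(tab)
  z <- function(v) (v - mean(v)) / stats::sd(v)
  list(slope_avtd = unname(stats::coef(stats::lm(z(tab$mean_avtd) ~ z(tab$m)))[2]),
       slope_pd = unname(stats::coef(stats::lm(z(tab$mean_pd) ~ z(tab$m)))[2]),
       table = tab)
}
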