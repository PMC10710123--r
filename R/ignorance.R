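#' Half-ignorance sampling-reliability surface
#'
#' Survey effort is uneven, so per-cell diversity values are only as
#' trustworthy as the record counts behind them. The half-ignorance index
#' maps a cell with N occurrence records to `o_half / (N + o_half)`: 1 with
#' no records (total ignorance), 0.5 when records reach the half-ignorance
#' parameter `o_half`, and decreasing towards 0 as sampling accumulates.
#'
#' @param grid a [assemble_grid()] result.
#' @param o_half record count at which ignorance equals 0.5; the default 10
#'   treats a cell with ten records as half-trustworthy.
#' @return an `ignorance_surface`: data.frame `cell_id,row,col,n_records,
#'   ignorance` covering every lattice cell (empty cells included), with
#'   attribute `o_half`.
#' @export
half_ignorance <- function(grid, o_half = 10) {
  stopifnot(inherits(grid, "grid_assembly"), o_half > 0)
  n_cells <- grid$n_cols * grid$n_rows
  n_rec <- integer(n_cells)
  occ_ids <- as.integer(names(grid$n_records))
  n_rec[occ_ids] <- as.integer(grid$n_records)
  cell_id <- seq_len(n_cells)
  out <- data.frame(cell_id = cell_id,
                    row = (cell_id - 1L) %/% grid$n_cols + 1L,
                    col = (cell_id - 1L) %% grid$n_cols + 1L,
                    n_records = n_rec,
                    ignorance = o_half / (n_rec + o_half))
  structure(out, o_half = o_half,
            class = c("ignorance_surface", "data.frame"))
}

#' Summarize an ignorance surface
#'
#' @param surface a [half_ignorance()] result.
#' @param threshold values above this count as "high ignorance".
#' @return list with `mean`, `sd` (population standard deviation over all
#'   lattice cells), and `frac_above` the fraction of cells above `threshold`.
#' @export
ignorance_summary <- function(surface, threshold = 0.5) {
  v <- surface$ignorance
  if (!length(v)) stop("empty ignorance surface")
  m <- mean(v)
  list(mean = m,
       sd = sqrt(mean((v - m)^2)),
       frac_above = mean(v > threshold))
}
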