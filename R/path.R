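#' Fill the dynamic-programming matrix over an island
#'
#' Row 1 of the DP matrix copies the island landscape (masked cells are
#' impassable, held at `-Inf`). Each later cell adds its landscape value to
#' the best predecessor within two columns on either side in the previous
#' row; the traceback matrix records the chosen predecessor column
#' (smallest column index on ties, for determinism). Rows whose cells are
#' all unreachable terminate the path at the previous row.
#'
#' @param island an `island_tile_matrix` (typically [island_submatrix()]).
#' @param jump maximum center shift between consecutive rows (default 2).
#' @return A `dp_matrix` list: `dpm`, `tm` (predecessor column index per
#'   cell, `NA` in row 1), `row_lengths`, `col_centers`, `last_row` (the
#'   deepest reachable row).
#' @export
fill_dp <- function(island, jump = 2L) {
  v <- island$values
  v[!island$mask] <- -Inf
  v[is.na(v)] <- -Inf
  nr <- nrow(v); nc <- ncol(v)
  if (nr == 0 || nc == 0 || !any(is.finite(v[1, ])))
    stop("island matrix has no reachable starting cell in its first row")
  dpm <- matrix(-Inf, nr, nc)
  tm <- matrix(NA_integer_, nr, nc)
  dpm[1, ] <- v[1, ]
  last_row <- 1L
  for (i in seq_len(nr)[-1]) {
    reached <- FALSE
    for (j in seq_len(nc)) {
      if (!is.finite(v[i, j])) next
      cols <- max(1L, j - jump):min(nc, j + jump)
      prev <- dpm[i - 1L, cols]
      if (!any(is.finite(prev))) next
      best <- cols[which.max(prev)]         # which.max: first (smallest) index
      dpm[i, j] <- v[i, j] + dpm[i - 1L, best]
      tm[i, j] <- best
      reached <- TRUE
    }
    if (!reached) break
    last_row <- i
  }
  structure(list(dpm = dpm, tm = tm, row_lengths = island$row_lengths,
                 col_centers = island$col_centers, last_row = last_row),
            class = "dp_matrix")
}

#' Trace back the optimal tile path
#'
#' Starts at the maximum entry of the deepest reachable row (ties broken
#' toward the smallest column index) and follows the traceback matrix up to
#' row 1, returning the ordered sequence of (tile length, tile center)
#' steps and the cumulative weight.
#'
#' @param dp a `dp_matrix` from [fill_dp()].
#' @return An `optimal_path` list: `steps` data frame (`row_length`,
#'   `center`, `value`, `cumulative`) ordered by ascending tile length, and
#'   `total_weight`.
#' @export
traceback_path <- function(dp) {
  row <- dp$last_row
  while (row > 1L && !any(is.finite(dp$dpm[row, ]))) row <- row - 1L
  if (!any(is.finite(dp$dpm[row, ]))) stop("no finite cell to trace from")
  j <- which.max(dp$dpm[row, ])
  cols <- integer(row)
  cols[row] <- j
  while (row > 1L) {
    j <- dp$tm[row, j]
    row <- row - 1L
    cols[row] <- j
  }
  m <- length(cols)
  values <- dp$dpm[cbind(seq_len(m), cols)]
  step_vals <- c(values[1], diff(values))
  steps <- data.frame(row_length = dp$row_lengths[seq_len(m)],
                      center = dp$col_centers[cols],
                      value = step_vals,
                      cumulative = values)
  structure(list(steps = steps, total_weight = values[m]),
            class = "optimal_path")
}

#' @export
print.optimal_path <- function(x, ...) {
  cat(sprintf("optimal_path: %d steps, lengths %d..%d, total weight %.4f\n",
              nrow(x$steps), min(x$steps$row_length), max(x$steps$row_length),
              x$total_weight))
  invisible(x)
}

#' Optimal path through one island
#'
#' Convenience wrapper: [island_submatrix()] then [fill_dp()] then
#' [traceback_path()].
#'
#' @param matrix a filtered `island_tile_matrix`.
#' @param island one row of [segment_islands()] output.
#' @param jump maximum center shift between consecutive rows.
#' @return An `optimal_path`.
#' @export
island_optimal_path <- function(matrix, island, jump = 2L) {
  traceback_path(fill_dp(island_submatrix(matrix, island), jump = jump))
}
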