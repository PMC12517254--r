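#' Tile-length by tile-center landscape of weighted similarity
#'
#' Arranges the scored pairs into a matrix whose rows are tile lengths and
#' whose columns are target tile-center indices; each cell holds the best
#' (maximum) weighted similarity over all query tiles for target tiles of
#' that length centered there. Cells with no valid tile — near the chain
#' ends, where long windows no longer fit — are masked, producing the
#' characteristic sawtooth envelope.
#'
#' @param scores a `score_table`.
#' @param weights length-3 weight vector (see [weighted_similarity()]).
#' @param target_n residue count of the target.
#' @return An `island_tile_matrix`: list with `values` (lengths x centers),
#'   `mask` (TRUE where a tile exists/survives), `row_lengths`,
#'   `col_centers`.
#' @export
build_tile_matrix <- function(scores, weights, target_n) {
  if (is.null(scores) || nrow(scores) == 0) stop("empty score table")
  s <- weighted_similarity(scores, weights)
  lens <- sort(unique(scores$length))
  centers <- seq_len(target_n)
  values <- matrix(NA_real_, length(lens), length(centers),
                   dimnames = list(lens, centers))
  agg <- stats::aggregate(s, by = list(length = scores$length,
                                       center = scores$target_center), FUN = max)
  values[cbind(match(agg$length, lens), agg$center)] <- agg$x
  mask <- !is.na(values)
  structure(list(values = values, mask = mask, row_lengths = lens,
                 col_centers = centers),
            class = "island_tile_matrix")
}

#' @export
print.island_tile_matrix <- function(x, ...) {
  cat(sprintf("island_tile_matrix: %d lengths x %d centers, %d live cells\n",
              length(x$row_lengths), length(x$col_centers), sum(x$mask)))
  invisible(x)
}

# Internal: per-residue flag, TRUE when the residue is a cysteine whose SG
# lies within [r_min, r_max] of any iron site.
cys_bonded_flags <- function(target, fe_sites, r_min, r_max) {
  ok <- rep(FALSE, nrow(target))
  has_sg <- !is.na(target$sg_x)
  if (!any(has_sg) || is.null(fe_sites) || nrow(fe_sites) == 0) return(ok)
  sg <- as.matrix(target[has_sg, c("sg_x", "sg_y", "sg_z")])
  fe <- as.matrix(fe_sites[, c("fe_x", "fe_y", "fe_z")])
  d2 <- outer(rowSums(sg^2), rowSums(fe^2), "+") - 2 * tcrossprod(sg, fe)
  d <- sqrt(pmax(d2, 0))
  ok[has_sg] <- apply(d >= r_min & d <= r_max, 1, any)
  ok
}

#' Cysteine-iron coordination filter
#'
#' Masks every tile that either contains no cysteine or whose cysteines'
#' SG atoms all lie outside the Fe-S bonding range `[r_min, r_max]` of
#' every iron site — retaining only regions geometrically capable of
#' ligating an iron-sulfur cluster (both bounds inclusive; defaults span
#' typical Fe-S bond lengths, 2.18-2.35 Angstrom). The filter is purely
#' geometric: survival never depends on the similarity values.
#'
#' @param matrix an `island_tile_matrix` from [build_tile_matrix()].
#' @param target the target [ca_structure()].
#' @param fe_sites iron sites ([extract_fe_sites()]); may have zero rows,
#'   in which case every tile is masked.
#' @param r_min,r_max inclusive SG-Fe distance bounds in Angstrom.
#' @return The filtered `island_tile_matrix`.
#' @export
cys_fe_filter <- function(matrix, target, fe_sites, r_min = 2.18, r_max = 2.35) {
  stopifnot(r_min > 0, r_min < r_max)
  ok <- cys_bonded_flags(target, fe_sites, r_min, r_max)
  cum <- cumsum(c(0, ok))
  n <- nrow(target)
  for (r in seq_along(matrix$row_lengths)) {
    L <- matrix$row_lengths[r]
    half <- (L - 1L) %/% 2L
    for (j in which(matrix$mask[r, ])) {
      start <- matrix$col_centers[j] - half
      end <- start + L - 1L
      if (start < 1 || end > n || (cum[end + 1L] - cum[start]) == 0)
        matrix$mask[r, j] <- FALSE
    }
  }
  matrix$values[!matrix$mask] <- NA_real_
  matrix
}

#' Segment the surviving landscape into islands
#'
#' An island is a maximal run of consecutive tile-center columns holding at
#' least one surviving cell — one "blade" of the sawtooth. Islands are
#' labeled A, B, ... in ascending center order; the optimal-path search is
#' later confined within a single island.
#'
#' @param matrix a filtered `island_tile_matrix`.
#' @return data frame with one row per island: `island_id`, `center_min`,
#'   `center_max`; zero rows when nothing survives.
#' @export
segment_islands <- function(matrix) {
  alive <- apply(matrix$mask, 2, any)
  if (!any(alive))
    return(data.frame(island_id = character(0), center_min = integer(0),
                      center_max = integer(0), stringsAsFactors = FALSE))
  r <- rle(alive)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  live <- which(r$values)
  ids <- make.unique(rep(LETTERS, length.out = length(live)), sep = "")
  data.frame(island_id = ids,
             center_min = matrix$col_centers[starts[live]],
             center_max = matrix$col_centers[ends[live]],
             stringsAsFactors = FALSE)
}

#' Island submatrix of the landscape
#'
#' @param matrix an `island_tile_matrix`.
#' @param island one row of [segment_islands()] output.
#' @return The `island_tile_matrix` restricted to the island's center
#'   columns and to rows (lengths) with at least one surviving cell there.
#' @export
island_submatrix <- function(matrix, island) {
  cols <- which(matrix$col_centers >= island$center_min &
                matrix$col_centers <= island$center_max)
  mask <- matrix$mask[, cols, drop = FALSE]
  rows <- which(apply(mask, 1, any))
  structure(list(values = matrix$values[rows, cols, drop = FALSE],
                 mask = mask[rows, , drop = FALSE],
                 row_lengths = matrix$row_lengths[rows],
                 col_centers = matrix$col_centers[cols]),
            class = "island_tile_matrix")
}

#' Converged tile length of a similarity-vs-length curve
#'
#' Fits a polynomial to the per-path average weighted similarity `S(L)`,
#' differentiates it analytically, smooths the derivative with a Gaussian
#' kernel followed by a rolling average, and returns the smallest L at
#' which the smoothed derivative has magnitude below `eps` — the point of
#' diminishing returns where longer tiles stop adding signal. If the
#' derivative never settles, the L maximizing the fitted curve is returned
#' with `converged = FALSE`.
#'
#' @param lengths tile lengths (>= 5 distinct values).
#' @param s mean weighted similarity at each length.
#' @param degree polynomial degree (capped below the number of points).
#' @param smooth_sigma Gaussian smoothing bandwidth in L units.
#' @param window rolling-average window (odd).
#' @param eps derivative magnitude regarded as "approached zero".
#' @return List `l_opt`, `converged`, `derivative` (smoothed, one per L).
#' @export
convergence_length <- function(lengths, s, degree = 5L, smooth_sigma = 2,
                               window = 5L, eps = 0.005) {
  ord <- order(lengths)
  lengths <- as.numeric(lengths[ord]); s <- as.numeric(s[ord])
  if (length(unique(lengths)) < 5) stop("need at least 5 distinct tile lengths")
  deg <- min(degree, length(unique(lengths)) - 1L)
  fit <- stats::lm(s ~ stats::poly(lengths, deg, raw = TRUE))
  beta <- stats::coef(fit)[-1]
  beta[is.na(beta)] <- 0
  dpoly <- beta * seq_along(beta)            # derivative coefficients
  deriv <- vapply(lengths, function(L)
    sum(dpoly * L^(seq_along(dpoly) - 1L)), numeric(1))
  # Gaussian kernel smoothing on the L grid
  k <- outer(lengths, lengths, function(a, b) exp(-(a - b)^2 / (2 * smooth_sigma^2)))
  sm <- as.numeric(k %*% deriv) / rowSums(k)
  # centered rolling average
  half <- window %/% 2L
  roll <- vapply(seq_along(sm), function(i)
    mean(sm[max(1, i - half):min(length(sm), i + half)]), numeric(1))
  hit <- which(abs(roll) < eps)
  if (length(hit) > 0)
    return(list(l_opt = lengths[hit[1]], converged = TRUE, derivative = roll))
  fitted_s <- stats::predict(fit)
  list(l_opt = lengths[which.max(fitted_s)], converged = FALSE,
       derivative = roll)
}
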