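#' Composite rank of tile pairs
#'
#' Within each tile-length class, each of the three similarity metrics is
#' dense-ranked best-first (rank 1 = most similar) and the three ranks are
#' summed into a composite score; a smaller composite means a better tile
#' pair on all three axes at once.
#'
#' @param scores a `score_table`.
#' @return The input with added columns `rank_cosine`, `rank_frobenius`,
#'   `rank_sw`, `composite` and `percentile` (composite percentile within
#'   the length class, 0 = best).
#' @export
composite_rank <- function(scores) {
  if (is.null(scores) || nrow(scores) == 0) stop("empty score table")
  dense_rank_desc <- function(x) match(x, sort(unique(x), decreasing = TRUE))
  out <- scores
  out$rank_cosine <- NA_integer_
  out$rank_frobenius <- NA_integer_
  out$rank_sw <- NA_integer_
  for (L in unique(out$length)) {
    i <- out$length == L
    out$rank_cosine[i] <- dense_rank_desc(out$s_cosine[i])
    out$rank_frobenius[i] <- dense_rank_desc(out$s_frobenius[i])
    out$rank_sw[i] <- dense_rank_desc(out$s_sw[i])
  }
  out$composite <- out$rank_cosine + out$rank_frobenius + out$rank_sw
  out$percentile <- NA_real_
  for (L in unique(out$length)) {
    i <- out$length == L
    r <- rank(out$composite[i], ties.method = "min") - 1L
    out$percentile[i] <- r / max(1L, sum(i) - 1L)
  }
  out
}

#' Similarity and composite-percentile filtering of ranked tiles
#'
#' Keeps only tile lengths between 6 and half the query length, discards
#' pairs whose cosine similarity is below 0.5 or whose sequence similarity
#' is below 50%, and retains the best `keep_fraction` (by ascending
#' composite rank sum) within each length class.
#'
#' @param ranked output of [composite_rank()].
#' @param n_query query length N (sets the `N/2` upper length bound).
#' @param min_cosine,min_sw similarity cutoffs.
#' @param keep_fraction fraction of each length class retained.
#' @return Filtered subset of `ranked` (possibly zero rows, with a
#'   warning). The result carries a `thresholded` attribute so that
#'   re-applying the filter is a no-op (the percentile head is taken only
#'   once; the similarity cutoffs always hold on the output).
#' @export
threshold_filter <- function(ranked, n_query, min_cosine = 0.5, min_sw = 50,
                             keep_fraction = 0.2) {
  keep <- ranked$length >= 6 & ranked$length <= n_query %/% 2 &
    ranked$s_cosine >= min_cosine & ranked$s_sw >= min_sw
  out <- ranked[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no tiles pass the similarity thresholds")
    return(out)
  }
  if (!isTRUE(attr(ranked, "thresholded"))) {
    parts <- lapply(split(out, out$length), function(d) {
      n_keep <- max(1L, floor(keep_fraction * nrow(d)))
      d[order(d$composite)[seq_len(n_keep)], , drop = FALSE]
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
  }
  attr(out, "thresholded") <- TRUE
  out
}

#' Assemble final match records from island paths
#'
#' For each island, takes the converged tile length (per-path
#' [convergence_length()]) and the optimal path's center at that length,
#' converts the tile span back to chain and author residue numbering, and
#' attaches the weighted-similarity value of the chosen cell.
#'
#' @param paths named list of `optimal_path` objects, one per island id.
#' @param islands data frame from [segment_islands()].
#' @param target the target [ca_structure()].
#' @param convergence optional named list of [convergence_length()] results
#'   per island id; when absent the convergence is computed from each
#'   path's own value-vs-length curve.
#' @return data frame of match records: `island_id`, `length`, `center`,
#'   `start`, `end`, `chain`, `auth_start`, `auth_end`, `s_weighted`,
#'   `converged`.
#' @export
assemble_matches <- function(paths, islands, target, convergence = NULL) {
  n <- nrow(target)
  recs <- lapply(seq_len(nrow(islands)), function(k) {
    id <- islands$island_id[k]
    path <- paths[[id]]
    if (is.null(path)) return(NULL)
    st <- path$steps
    conv <- if (!is.null(convergence) && !is.null(convergence[[id]]))
      convergence[[id]]
    else if (nrow(st) >= 5)
      convergence_length(st$row_length, st$value)
    else
      list(l_opt = st$row_length[which.max(st$value)], converged = FALSE)
    row <- which.min(abs(st$row_length - conv$l_opt))
    L <- st$row_length[row]
    center <- st$center[row]
    start <- center - (L - 1L) %/% 2L
    end <- start + L - 1L
    start <- max(1L, start); end <- min(n, end)
    data.frame(island_id = id, length = L, center = center,
               start = start, end = end,
               chain = target$chain[start],
               auth_start = target$auth_resnum[start],
               auth_end = target$auth_resnum[end],
               s_weighted = st$value[row],
               converged = conv$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(island_id = character(0), length = integer(0),
                      center = integer(0), start = integer(0),
                      end = integer(0), chain = character(0),
                      auth_start = integer(0), auth_end = integer(0),
                      s_weighted = numeric(0), converged = logical(0),
                      stringsAsFactors = FALSE)
  out
}

#' Paired structural-vs-dynamical scores at a fixed tile length
#'
#' Exports `(s_frobenius, s_cosine)` pairs for every query-target tile pair
#' of the requested length (default 30 residues), plot-ready for examining
#' how structural similarity degrades relative to dynamical similarity.
#'
#' @param scores a `score_table`.
#' @param L tile length to export.
#' @param target_id label attached to every row.
#' @return data frame with columns `target_id`, `query_center`,
#'   `target_center`, `s_frobenius`, `s_cosine` (zero rows with a warning
#'   if the table has no tiles of length `L`).
#' @export
export_dynamics_vs_structure <- function(scores, L = 30L, target_id = "target") {
  rows <- scores[scores$length == L, , drop = FALSE]
  if (nrow(rows) == 0)
    warning("score table has no tile pairs of length ", L)
  data.frame(target_id = rep(target_id, nrow(rows)),
             query_center = rows$query_center,
             target_center = rows$target_center,
             s_frobenius = rows$s_frobenius,
             s_cosine = rows$s_cosine,
             stringsAsFactors = FALSE)
}
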