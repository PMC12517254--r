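#' Enumerate sliding-window tiles
#'
#' A tile of length L starting at seq_index s covers residues s..s+L-1 and
#' has center `s + floor((L-1)/2)`. For each L there are `N - L + 1` tiles;
#' over `l_min = 6` to `l_max = N` the total matches the closed form
#' `sum_{L=6}^{N} (N - L + 1)`.
#'
#' @param n_residues protein length N.
#' @param l_min minimum tile length (>= 6, the smallest window that still
#'   captures a secondary-structure element on a Calpha trace).
#' @param l_max maximum tile length (<= N).
#' @return data frame with columns `length`, `start`, `center`, `end`.
#' @export
enumerate_tiles <- function(n_residues, l_min = 6L, l_max = n_residues) {
  n <- as.integer(n_residues)
  l_min <- as.integer(l_min); l_max <- as.integer(l_max)
  if (l_min < 6L) stop("tile length below 6 is not supported (l_min >= 6)")
  if (!(l_min <= l_max && l_max <= n))
    stop("need 6 <= l_min <= l_max <= N")
  lens <- rep(l_min:l_max, times = n - (l_min:l_max) + 1L)
  starts <- unlist(lapply(l_min:l_max, function(L) seq_len(n - L + 1L)),
                   use.names = FALSE)
  data.frame(length = lens, start = starts,
             center = starts + (lens - 1L) %/% 2L,
             end = starts + lens - 1L)
}

#' Extract a tile's diagonal correlation block
#'
#' @param corr N x N cross-correlation matrix.
#' @param start first seq_index of the tile.
#' @param length tile length L.
#' @return L x L submatrix over the tile's residues.
#' @export
tile_submatrix <- function(corr, start, length) {
  idx <- start:(start + length - 1L)
  if (start < 1 || max(idx) > nrow(corr))
    stop("tile out of range of the correlation matrix")
  corr[idx, idx, drop = FALSE]
}

#' Cosine similarity between two flattened correlation blocks
#'
#' Both matrices are flattened to vectors and compared by direction:
#' 1 for identical orientation, -1 for opposite, 0 for orthogonal.
#'
#' @param sub_q,sub_t equal-size numeric matrices.
#' @return Scalar in [-1, 1].
#' @export
cosine_similarity <- function(sub_q, sub_t) {
  if (!all(dim(sub_q) == dim(sub_t))) stop("tile submatrices differ in shape")
  u <- as.numeric(sub_q); v <- as.numeric(sub_t)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("undefined cosine similarity: zero vector")
  sum(u * v) / (nu * nv)
}

#' Frobenius distance and Gower-mapped similarity
#'
#' The structural dissimilarity between two tiles is the Frobenius norm of
#' the element-wise difference of their correlation blocks, computed with
#' no superposition (correlation entries are already rigid-body invariant).
#' It is mapped to a bounded similarity by the continuous Gower transform
#' `s = 1 - d / d_max`, where `d_max` is the largest distance observed
#' among the tile pairs of the same length in the run.
#'
#' @param sub_q,sub_t equal-size numeric matrices.
#' @param d_max normalization constant (> 0).
#' @return List with `d_frobenius` and `s_frobenius` (clamped to 0 with a
#'   warning if `d > d_max`, possible only when `d_max` was estimated on a
#'   subset).
#' @export
frobenius_similarity <- function(sub_q, sub_t, d_max) {
  if (!all(dim(sub_q) == dim(sub_t))) stop("tile submatrices differ in shape")
  if (d_max <= 0) stop("d_max must be positive")
  d <- sqrt(sum((sub_q - sub_t)^2))
  s <- 1 - d / d_max
  if (s < 0) {
    warning("Frobenius distance exceeds d_max; similarity clamped to 0")
    s <- 0
  }
  list(d_frobenius = d, s_frobenius = s)
}

# Internal: BLOSUM62 self-alignment score of each position (diagonal entry),
# letters outside the 20-standard alphabet mapped to X with a warning.
blosum62_matrix <- function() {
  if (is.null(.dynatile_env$blosum62)) {
    e <- new.env(parent = emptyenv())
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .dynatile_env$blosum62 <- e$BLOSUM62
  }
  .dynatile_env$blosum62
}

.dynatile_env <- new.env(parent = emptyenv())

sanitize_seq <- function(s) {
  std <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
  ch <- strsplit(toupper(s), "")[[1]]
  bad <- !ch %in% std
  if (any(bad)) {
    warning("non-standard amino-acid letter(s) mapped to X: ",
            paste(unique(ch[bad]), collapse = ""))
    ch[bad] <- "X"
  }
  paste(ch, collapse = "")
}

#' Normalized Smith-Waterman sequence similarity
#'
#' Local alignment (BLOSUM62, zero gap opening and extension penalties, the
#' alignment toolkit default) scored and divided by the average of the two
#' sequences' self-alignment scores, as a percentage. A sequence against
#' itself scores 100.
#'
#' @param seq_q,seq_t peptide strings (one-letter code).
#' @param gap_opening,gap_extension gap penalties (non-negative costs).
#' @return Percent similarity in [0, 100].
#' @export
sequence_similarity <- function(seq_q, seq_t, gap_opening = 0,
                                gap_extension = 0) {
  if (nchar(seq_q) < 1 || nchar(seq_t) < 1) stop("empty sequence")
  seq_q <- sanitize_seq(seq_q); seq_t <- sanitize_seq(seq_t)
  bl <- blosum62_matrix()
  self <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(bl[cbind(ch, ch)])
  }
  raw <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_q), Biostrings::AAString(seq_t),
    type = "local", substitutionMatrix = bl,
    gapOpening = gap_opening, gapExtension = gap_extension, scoreOnly = TRUE)
  raw <- max(raw, 0)
  100 * raw / mean(c(self(seq_q), self(seq_t)))
}

# Internal: flattened diagonal correlation blocks of all tiles of length L,
# as an L^2 x n_tiles matrix (one column per start position).
flatten_tiles <- function(corr, L) {
  n <- nrow(corr)
  starts <- seq_len(n - L + 1L)
  out <- matrix(0, L * L, length(starts))
  for (s in starts) {
    idx <- s:(s + L - 1L)
    out[, s] <- as.numeric(corr[idx, idx])
  }
  out
}

#' Score all query-target tile pairs at one tile length
#'
#' Computes, for every pair of a query tile and a target tile of length L,
#' the cosine similarity and Frobenius distance of their diagonal
#' correlation blocks and the normalized Smith-Waterman sequence
#' similarity. `d_max` for the Gower mapping is the largest Frobenius
#' distance among the pairs at this length.
#'
#' @param corr_q,corr_t cross-correlation matrices of query and target,
#'   computed with identical [anm_params()].
#' @param structure_q,structure_t the corresponding [ca_structure()]s.
#' @param L tile length.
#' @param gap_opening,gap_extension passed to [sequence_similarity()].
#' @return data frame (class `score_table`) with one row per pair:
#'   `length`, `query_start`, `query_center`, `target_start`,
#'   `target_center`, `s_cosine`, `d_frobenius`, `s_frobenius`, `s_sw`;
#'   attribute `d_max` holds the per-length normalization constant.
#' @export
score_tile_pairs <- function(corr_q, corr_t, structure_q, structure_t, L,
                             gap_opening = 0, gap_extension = 0) {
  nq <- nrow(corr_q); nt <- nrow(corr_t)
  if (L > nq || L > nt) stop("tile length exceeds a protein length")
  if (L < 6) stop("tile length below 6 is not supported")
  uq <- flatten_tiles(corr_q, L)       # L^2 x nq_tiles
  ut <- flatten_tiles(corr_t, L)       # L^2 x nt_tiles
  nq_t <- ncol(uq); nt_t <- ncol(ut)
  dots <- crossprod(uq, ut)            # nq_t x nt_t
  nrm_q <- sqrt(colSums(uq^2)); nrm_t <- sqrt(colSums(ut^2))
  if (any(nrm_q == 0) || any(nrm_t == 0))
    stop("undefined cosine similarity: zero tile vector")
  s_cos <- dots / outer(nrm_q, nrm_t)
  d2 <- outer(nrm_q^2, rep(1, nt_t)) + outer(rep(1, nq_t), nrm_t^2) - 2 * dots
  d <- sqrt(pmax(d2, 0))
  d_max <- max(d)
  # all-identical tiles (e.g. a single self-pair): treat as similarity 1
  # rather than dividing numerical noise by itself
  degenerate <- d_max <= 1e-5 * max(nrm_q, nrm_t)
  s_frob <- if (degenerate) matrix(1, nq_t, nt_t) else 1 - d / d_max

  seq_q <- structure_q$aa; seq_t <- structure_t$aa
  bl <- blosum62_matrix()
  self_cum_q <- cumsum(c(0, bl[cbind(seq_q, seq_q)]))
  self_cum_t <- cumsum(c(0, bl[cbind(seq_t, seq_t)]))
  self_q <- self_cum_q[(1:nq_t) + L] - self_cum_q[1:nq_t]
  self_t <- self_cum_t[(1:nt_t) + L] - self_cum_t[1:nt_t]
  tiles_q <- substring(paste(seq_q, collapse = ""), 1:nq_t, (1:nq_t) + L - 1L)
  tiles_t <- substring(paste(seq_t, collapse = ""), 1:nt_t, (1:nt_t) + L - 1L)
  tset <- Biostrings::AAStringSet(vapply(tiles_t, sanitize_seq, ""))
  s_sw <- matrix(0, nq_t, nt_t)
  for (i in seq_len(nq_t)) {
    raw <- Biostrings::pairwiseAlignment(
      tset, Biostrings::AAString(sanitize_seq(tiles_q[i])),
      type = "local", substitutionMatrix = bl,
      gapOpening = gap_opening, gapExtension = gap_extension,
      scoreOnly = TRUE)
    s_sw[i, ] <- 100 * pmax(raw, 0) / ((self_q[i] + self_t) / 2)
  }

  half <- (L - 1L) %/% 2L
  grid <- expand.grid(query_start = seq_len(nq_t), target_start = seq_len(nt_t))
  out <- data.frame(
    length = L,
    query_start = grid$query_start,
    query_center = grid$query_start + half,
    target_start = grid$target_start,
    target_center = grid$target_start + half,
    s_cosine = as.numeric(s_cos[cbind(grid$query_start, grid$target_start)]),
    d_frobenius = as.numeric(d[cbind(grid$query_start, grid$target_start)]),
    s_frobenius = as.numeric(s_frob[cbind(grid$query_start, grid$target_start)]),
    s_sw = as.numeric(s_sw[cbind(grid$query_start, grid$target_start)]))
  attr(out, "d_max") <- stats::setNames(d_max, as.character(L))
  class(out) <- c("score_table", "data.frame")
  out
}

#' Score tile pairs over a range of lengths
#'
#' @inheritParams score_tile_pairs
#' @param l_min,l_max inclusive tile-length range (defaults: 6 up to the
#'   query length).
#' @return A `score_table` data frame concatenating [score_tile_pairs()]
#'   over all lengths; attribute `d_max` maps each length to its
#'   normalization constant.
#' @export
score_all_lengths <- function(corr_q, corr_t, structure_q, structure_t,
                              l_min = 6L, l_max = nrow(corr_q),
                              gap_opening = 0, gap_extension = 0) {
  parts <- lapply(l_min:l_max, function(L)
    score_tile_pairs(corr_q, corr_t, structure_q, structure_t, L,
                     gap_opening, gap_extension))
  out <- do.call(rbind, lapply(parts, as.data.frame))
  attr(out, "d_max") <- do.call(c, lapply(parts, attr, "d_max"))
  class(out) <- c("score_table", "data.frame")
  out
}
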