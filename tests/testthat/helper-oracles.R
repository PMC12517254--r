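# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the DP oracle enumerates paths, the alignment
# oracle is a direct Smith-Waterman recurrence, and the weight-grid oracle
# lives in the package but is an exhaustive search, not the optimizer.

# Exhaustive best path through a value matrix with |delta column| <= jump
# between consecutive rows. Returns list(total, cols). Assumes no ties in
# practice (continuous random values).
brute_force_best_path <- function(v, jump = 2L) {
  nr <- nrow(v); nc <- ncol(v)
  paths <- lapply(seq_len(nc), function(j) list(cols = j, total = v[1, j]))
  if (nr > 1) {
    for (i in 2:nr) {
      nxt <- list()
      for (p in paths) {
        last <- p$cols[length(p$cols)]
        for (j in max(1L, last - jump):min(nc, last + jump)) {
          nxt[[length(nxt) + 1L]] <- list(cols = c(p$cols, j),
                                          total = p$total + v[i, j])
        }
      }
      paths <- nxt
    }
  }
  best <- which.max(vapply(paths, `[[`, numeric(1), "total"))
  paths[[best]]
}

# Direct Smith-Waterman local alignment score, linear gap penalties.
sw_score_oracle <- function(a, b, sub, gap = 0) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  h <- matrix(0, length(a) + 1L, length(b) + 1L)
  for (i in seq_along(a)) for (j in seq_along(b)) {
    h[i + 1L, j + 1L] <- max(0,
                             h[i, j] + sub[a[i], b[j]],
                             h[i, j + 1L] - gap,
                             h[i + 1L, j] - gap)
  }
  max(h)
}

blosum62_test <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Random score table with a shared latent quality so the three metrics are
# correlated but distinct; used by the weight-optimizer tests.
random_score_table <- function(n, seed, sw_noise_only = FALSE) {
  set.seed(seed)
  z <- runif(n)
  tb <- data.frame(
    length = 10L,
    query_start = seq_len(n), query_center = seq_len(n),
    target_start = seq_len(n), target_center = seq_len(n),
    s_cosine = pmin(1, pmax(-1, z + rnorm(n, 0, 0.15))),
    d_frobenius = 1 - z,
    s_frobenius = pmin(1, pmax(0, z + rnorm(n, 0, 0.2))),
    s_sw = if (sw_noise_only) runif(n, 0, 100)
           else pmin(100, pmax(0, 100 * (z + rnorm(n, 0, 0.25)))))
  class(tb) <- c("score_table", "data.frame")
  tb
}

# Minimal synthetic score table covering given target tiles at one length.
manual_score_table <- function(length, target_centers, values,
                               query_center = 1L) {
  tb <- data.frame(length = length,
                   query_start = 1L, query_center = query_center,
                   target_start = target_centers - (length - 1L) %/% 2L,
                   target_center = target_centers,
                   s_cosine = values, d_frobenius = 1 - values,
                   s_frobenius = values, s_sw = 100 * values)
  class(tb) <- c("score_table", "data.frame")
  tb
}

# A small connected, non-symmetric test structure (perturbed helix).
wiggly_helix <- function(n = 20, seed = 11, rmsd = 0.4) {
  perturb_structure(make_toy_domain(n, seed = seed), rmsd, seed = seed + 1L)
}
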