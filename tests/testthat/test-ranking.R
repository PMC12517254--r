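test_that("composite rank sums dense best-first ranks within a length class", {
  tb <- manual_score_table(7, target_centers = 4:7,
                           values = c(0.9, 0.7, 0.7, 0.2))
  r <- composite_rank(tb)
  expect_equal(r$rank_cosine, c(1, 2, 2, 3))       # dense: tie shares rank 2
  expect_equal(r$composite, r$rank_cosine + r$rank_frobenius + r$rank_sw)
  expect_equal(r$composite[1], 3)                  # best on all three metrics
  expect_equal(r$composite[2], r$composite[3])     # identical rows tie
})

test_that("rank-sum ordering matches an independent counting oracle", {
  set.seed(44)
  tb <- random_score_table(100, seed = 44)
  r <- composite_rank(tb)
  # oracle: dense rank = 1 + number of strictly better distinct values
  oracle_rank <- function(x) vapply(x, function(v)
    1L + length(unique(x[x > v])), integer(1))
  expect_equal(r$rank_cosine, oracle_rank(tb$s_cosine))
  expect_equal(r$rank_frobenius, oracle_rank(tb$s_frobenius))
  expect_equal(r$rank_sw, oracle_rank(tb$s_sw))
  oracle_comp <- oracle_rank(tb$s_cosine) + oracle_rank(tb$s_frobenius) +
    oracle_rank(tb$s_sw)
  expect_equal(order(r$composite), order(oracle_comp))
})

test_that("threshold filtering applies the similarity cutoffs and the 20% head", {
  tb <- manual_score_table(7, target_centers = 4:13,
                           values = seq(0.95, 0.5, length.out = 10))
  tb$s_cosine[10] <- 0.49                          # below the cosine cutoff
  r <- composite_rank(tb)
  kept <- threshold_filter(r, n_query = 20)
  # 9 survivors after cutoffs; floor(20%) of 9 -> 1 kept, the best composite
  expect_equal(nrow(kept), 1)
  expect_equal(kept$target_center, 4)
  # 10 survivors -> 2 kept
  tb$s_cosine[10] <- 0.5
  kept2 <- threshold_filter(composite_rank(tb), n_query = 20)
  expect_equal(nrow(kept2), 2)
  # tiles longer than N/2 are excluded from this stage
  expect_equal(nrow(suppressWarnings(
    threshold_filter(composite_rank(tb), n_query = 13))), 0)
  # all below cutoff: empty result with a warning
  tb$s_sw <- 10
  expect_warning(none <- threshold_filter(composite_rank(tb), n_query = 20),
                 "no tiles")
  expect_equal(nrow(none), 0)
})

test_that("threshold filtering is a subset operation and idempotent", {
  tb <- random_score_table(60, seed = 9)
  r <- composite_rank(tb)
  once <- threshold_filter(r, n_query = 30)
  expect_true(all(rownames(once) %in% rownames(r)) || nrow(once) <= nrow(r))
  expect_true(all(once$s_cosine >= 0.5 & once$s_sw >= 50))
  twice <- threshold_filter(once, n_query = 30)
  expect_equal(nrow(twice), nrow(once))
  expect_equal(twice$target_center, once$target_center)
})

test_that("match assembly converts converged tiles to residue and author ranges", {
  target <- make_toy_domain(80, seed = 6, chain = "A")
  islands <- data.frame(island_id = "A", center_min = 40, center_max = 80)
  steps <- data.frame(row_length = seq(6, 30, by = 2),
                      center = rep(60, 13),
                      value = 1 - exp(-seq(6, 30, by = 2) / 5),
                      cumulative = cumsum(1 - exp(-seq(6, 30, by = 2) / 5)))
  paths <- list(A = structure(list(steps = steps,
                                   total_weight = max(steps$cumulative)),
                              class = "optimal_path"))
  conv <- list(A = list(l_opt = 20, converged = TRUE))
  m <- assemble_matches(paths, islands, target, convergence = conv)
  expect_equal(nrow(m), 1)
  expect_equal(m$length, 20)
  expect_equal(m$start, 51)       # center 60, floor((20-1)/2) = 9 back
  expect_equal(m$end, 70)
  expect_equal(m$auth_start, target$auth_resnum[51])
  expect_true(m$converged)
  # ranges stay within the island's center span +/- L/2 and inside 1..N
  expect_gte(m$start, islands$center_min - 10)
  expect_lte(m$end, min(80, islands$center_max + 10))
})

test_that("paired structure-vs-dynamics export covers all length-30 tile pairs", {
  sq <- wiggly_helix(34, seed = 50)
  st <- wiggly_helix(40, seed = 51)
  tb <- score_all_lengths(anm_cross_correlation(sq), anm_cross_correlation(st),
                          sq, st, l_min = 29, l_max = 31)
  out <- export_dynamics_vs_structure(tb, L = 30, target_id = "t")
  expect_equal(nrow(out), (34 - 29) * (40 - 29))
  expect_named(out, c("target_id", "query_center", "target_center",
                      "s_frobenius", "s_cosine"))
  expect_warning(empty <- export_dynamics_vs_structure(tb, L = 50), "no tile")
  expect_equal(nrow(empty), 0)
  # self-comparison contains the perfect pair (1, 1)
  self_tb <- score_tile_pairs(anm_cross_correlation(sq),
                              anm_cross_correlation(sq), sq, sq, L = 30)
  self_out <- export_dynamics_vs_structure(self_tb, L = 30)
  expect_true(any(abs(self_out$s_cosine - 1) < 1e-9 &
                  abs(self_out$s_frobenius - 1) < 1e-9))
})
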