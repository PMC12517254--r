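# small target with a single cysteine whose SG sits at a controllable
# distance from a single iron
target_with_cys <- function(n = 12, cys_at = 6) {
  make_toy_domain(n, cys_positions = cys_at, seed = 2)
}

fe_at_distance <- function(target, cys_at, d) {
  sg <- as.numeric(target[cys_at, c("sg_x", "sg_y", "sg_z")])
  data.frame(fe_x = sg[1] + d, fe_y = sg[2], fe_z = sg[3],
             cluster_name = "FE", cluster_id = "FE_1")
}

test_that("the landscape holds the best weighted sum per (length, center) cell", {
  tb <- manual_score_table(7, target_centers = c(4, 5, 6),
                           values = c(0.2, 0.9, 0.4))
  m <- build_tile_matrix(tb, c(1, 1, 1) / 3, target_n = 10)
  expect_equal(m$row_lengths, 7)
  expect_equal(sum(m$mask), 3)
  expect_equal(m$values["7", "5"], 0.9)
  # duplicate rows for one cell: the max is kept
  tb2 <- rbind(tb, transform(tb[2, ], s_cosine = 0.1, s_frobenius = 0.1,
                             s_sw = 10))
  class(tb2) <- class(tb)
  m2 <- build_tile_matrix(tb2, c(1, 1, 1) / 3, target_n = 10)
  expect_equal(m2$values["7", "5"], 0.9)
  expect_error(build_tile_matrix(tb[0, ], c(1, 1, 1) / 3, 10), "empty")
})

test_that("cell count per landscape row equals N - L + 1", {
  sq <- wiggly_helix(16, seed = 30)
  st <- wiggly_helix(24, seed = 31)
  tb <- score_all_lengths(anm_cross_correlation(sq), anm_cross_correlation(st),
                          sq, st, l_min = 6, l_max = 12)
  m <- build_tile_matrix(tb, c(1, 1, 1) / 3, target_n = 24)
  for (r in seq_along(m$row_lengths))
    expect_equal(sum(m$mask[r, ]), 24 - m$row_lengths[r] + 1)
})

test_that("tiles survive exactly when a cysteine SG lies inside the bonding window", {
  n <- 12; cys_at <- 3
  target <- target_with_cys(n, cys_at)
  tb <- manual_score_table(7, target_centers = 4:9, values = runif(6, 0.5, 1))
  base <- build_tile_matrix(tb, c(1, 1, 1) / 3, target_n = n)
  for (d in c(2.18, 2.25, 2.35)) {     # inclusive bounds survive
    f <- cys_fe_filter(base, target, fe_at_distance(target, cys_at, d))
    expect_true(any(f$mask), info = sprintf("d = %.2f", d))
  }
  for (d in c(2.17, 2.36, 3.00)) {     # outside the window: all masked
    f <- cys_fe_filter(base, target, fe_at_distance(target, cys_at, d))
    expect_false(any(f$mask), info = sprintf("d = %.2f", d))
  }
  # no irons at all: everything masked
  f0 <- cys_fe_filter(base, target, fe_at_distance(target, cys_at, 2.25)[0, ])
  expect_false(any(f0$mask))
  # tiles not containing the cysteine are masked even with a bonded iron
  f <- cys_fe_filter(base, target, fe_at_distance(target, cys_at, 2.25))
  covered <- abs(4:9 - cys_at) <= 3    # length-7 tiles reach +/- 3 residues
  expect_equal(unname(f$mask[1, 4:9]), unname(covered))
  expect_false(all(covered))           # the check is not vacuous
})

test_that("a cysteine-free tile is masked regardless of iron proximity", {
  target <- make_toy_domain(12, seed = 3)        # no cysteines
  tb <- manual_score_table(7, target_centers = 4:8, values = rep(0.9, 5))
  base <- build_tile_matrix(tb, c(1, 1, 1) / 3, target_n = 12)
  fe <- data.frame(fe_x = target$ca_x[6], fe_y = target$ca_y[6],
                   fe_z = target$ca_z[6], cluster_name = "FE",
                   cluster_id = "FE_1")
  expect_false(any(cys_fe_filter(base, target, fe)$mask))
})

test_that("filtering is monotone in the iron set and ignores cell values", {
  n <- 20
  target <- make_toy_domain(n, cys_positions = c(5, 15), seed = 4)
  tb <- manual_score_table(7, target_centers = 4:17,
                           values = runif(14, 0, 1))
  base <- build_tile_matrix(tb, c(1, 1, 1) / 3, target_n = n)
  fe1 <- fe_at_distance(target, 5, 2.25)
  fe2 <- rbind(fe1, fe_at_distance(target, 15, 2.25))
  m1 <- cys_fe_filter(base, target, fe1)
  m2 <- cys_fe_filter(base, target, fe2)
  expect_true(all(m2$mask >= m1$mask))           # adding irons only grows
  # survival is independent of the weighted-sum values
  tb_flip <- tb; tb_flip$s_cosine <- rev(tb$s_cosine)
  base_flip <- build_tile_matrix(tb_flip, c(1, 1, 1) / 3, target_n = n)
  expect_equal(cys_fe_filter(base_flip, target, fe1)$mask, m1$mask)
})

test_that("island segmentation partitions surviving centers into contiguous runs", {
  tb <- manual_score_table(7, target_centers = c(4, 5, 6, 10, 11),
                           values = rep(0.8, 5))
  m <- build_tile_matrix(tb, c(1, 1, 1) / 3, target_n = 14)
  isl <- segment_islands(m)
  expect_equal(isl$island_id, c("A", "B"))
  expect_equal(isl$center_min, c(4, 10))
  expect_equal(isl$center_max, c(6, 11))
  # fully masked matrix: no islands
  m$mask[] <- FALSE
  expect_equal(nrow(segment_islands(m)), 0)
})

test_that("a two-copy fixture segments into one island per copy", {
  fix <- make_embedded_fixture(domain_length = 30, n_copies = 2,
                               linker_length = 30, noise_rmsd = 0, seed = 5)
  q <- make_toy_domain(30, cys_positions = c(9, 13, 18, 22), seed = 5)
  tb <- score_all_lengths(anm_cross_correlation(q),
                          anm_cross_correlation(fix$structure),
                          q, fix$structure, l_min = 6, l_max = 30)
  m <- build_tile_matrix(tb, c(1, 1, 1) / 3,
                         target_n = n_residues(fix$structure))
  f <- cys_fe_filter(m, fix$structure, fix$fe_sites)
  isl <- segment_islands(f)
  expect_equal(nrow(isl), 2)
  for (k in 1:2) {
    gt <- fix$ground_truth[k, ]
    ov <- max(0, min(isl$center_max[k], gt$end) -
                 max(isl$center_min[k], gt$start) + 1)
    expect_gte(ov / (gt$end - gt$start + 1), 0.8)
  }
})

test_that("convergence length finds where the similarity curve flattens", {
  l <- 6:55
  # constant curve: derivative identically zero, smallest L returned
  flat <- convergence_length(l, rep(0.7, length(l)))
  expect_true(flat$converged)
  expect_equal(flat$l_opt, 6)
  # saturating curve: analytic derivative exp(-L/10)/10 crosses eps = 0.005
  # at L = 10 log(20) ~ 30
  sat <- convergence_length(l, 1 - exp(-l / 10))
  oracle <- l[which(exp(-l / 10) / 10 < 0.005)[1]]
  expect_true(sat$converged)
  expect_lte(abs(sat$l_opt - oracle), 2)
  # steep linear growth never converges; falls back to the maximizing L
  lin <- convergence_length(l, 0.05 * l)
  expect_false(lin$converged)
  expect_equal(lin$l_opt, 55)
  expect_error(convergence_length(6:9, rep(1, 4)), "at least 5")
})
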