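test_that("tile enumeration matches the closed-form count", {
  expect_equal(nrow(enumerate_tiles(55)), 1275)   # sum_{L=6..55} (55 - L + 1)
  expect_equal(nrow(enumerate_tiles(10)), 15)     # 5+4+3+2+1
  t6 <- enumerate_tiles(6)
  expect_equal(nrow(t6), 1)
  expect_equal(t6$start, 1)
  expect_equal(t6$end, 6)
  for (n in c(6, 7, 20, 55, 103, 200)) {
    tiles <- enumerate_tiles(n)
    expect_equal(nrow(tiles), sum(n - (6:n) + 1))
    expect_true(all(tiles$center == tiles$start + (tiles$length - 1) %/% 2))
    expect_true(all(tiles$end - tiles$start + 1 == tiles$length))
    counts <- table(tiles$length)
    expect_equal(as.integer(counts), n - as.integer(names(counts)) + 1L)
  }
  expect_error(enumerate_tiles(20, l_min = 5), "below 6")
  expect_error(enumerate_tiles(5), "l_max")
})

test_that("tile submatrix extraction is the diagonal block and composes", {
  cc <- anm_cross_correlation(wiggly_helix(15, seed = 8))
  expect_equal(tile_submatrix(cc, 1, 15), cc, ignore_attr = TRUE)
  expect_equal(tile_submatrix(cc, 1, 6), cc[1:6, 1:6])
  outer_tile <- tile_submatrix(cc, 3, 10)
  expect_equal(tile_submatrix(outer_tile, 2, 6), tile_submatrix(cc, 4, 6))
  expect_error(tile_submatrix(cc, 12, 6), "out of range")
})

test_that("cosine similarity hits its defining endpoints", {
  a <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(a, -a), -1)
  expect_equal(cosine_similarity(matrix(c(1, 0, 0, 0), 2),
                                 matrix(c(0, 0, 0, 1), 2)), 0)
  expect_equal(cosine_similarity(a, 2 * a), 1)     # scale-free
  expect_error(cosine_similarity(a, matrix(0, 2, 2)), "zero vector")
})

test_that("Frobenius distance and its Gower mapping behave as defined", {
  a <- matrix(c(1, 0.2, 0.2, 1), 2)
  same <- frobenius_similarity(a, a, d_max = 3)
  expect_equal(same$d_frobenius, 0)
  expect_equal(same$s_frobenius, 1)
  r <- frobenius_similarity(diag(2), matrix(0, 2, 2), d_max = sqrt(2))
  expect_equal(r$d_frobenius, sqrt(2))
  expect_equal(r$s_frobenius, 0)                   # d == d_max endpoint
  expect_warning(clamped <- frobenius_similarity(diag(2), matrix(0, 2, 2), 1),
                 "clamped")
  expect_equal(clamped$s_frobenius, 0)
  # symmetry in the two arguments
  b <- matrix(c(1, -0.4, -0.4, 1), 2)
  expect_equal(frobenius_similarity(a, b, 3), frobenius_similarity(b, a, 3))
})

test_that("sequence similarity is a normalized local-alignment percentage", {
  expect_equal(sequence_similarity("MKTAYIAK", "MKTAYIAK"), 100)
  expect_equal(sequence_similarity("AAAAAA", "GGGGGG"), 0)  # A-G scores 0
  expect_equal(sequence_similarity("MKTAY", "KTAYW"),
               sequence_similarity("KTAYW", "MKTAY"))
  expect_warning(sim <- sequence_similarity("MKTO", "MKTA"), "mapped to X")
  expect_true(sim >= 0 && sim <= 100)
})

test_that("sequence similarity matches a direct Smith-Waterman recurrence", {
  set.seed(31)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:8) {
    a <- paste(sample(aas, sample(6:12, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(6:12, 1), TRUE), collapse = "")
    raw <- sw_score_oracle(a, b, blosum62_test, gap = 0)
    self <- function(s) {
      ch <- strsplit(s, "")[[1]]
      sum(blosum62_test[cbind(ch, ch)])
    }
    expect_equal(sequence_similarity(a, b),
                 100 * raw / mean(c(self(a), self(b))),
                 tolerance = 1e-9)
  }
})

test_that("pair scoring produces one row per tile pair with per-length d_max", {
  sq <- wiggly_helix(30, seed = 14)
  st <- wiggly_helix(45, seed = 15)
  ccq <- anm_cross_correlation(sq)
  cct <- anm_cross_correlation(st)
  tb <- score_tile_pairs(ccq, cct, sq, st, L = 20)
  expect_equal(nrow(tb), (30 - 20 + 1) * (45 - 20 + 1))
  expect_true(all(tb$s_frobenius >= 0 & tb$s_frobenius <= 1))
  expect_true(all(abs(tb$s_cosine) <= 1 + 1e-12))
  expect_true(all(tb$s_sw >= 0 & tb$s_sw <= 100 + 1e-9))
  # the Gower maximum is attained: at least one pair sits at s_frobenius 0
  expect_equal(min(tb$s_frobenius), 0)
  expect_equal(unname(attr(tb, "d_max")["20"]), max(tb$d_frobenius))
  # spot-check one row against the scalar operations
  row <- tb[tb$query_start == 3 & tb$target_start == 7, ]
  sub_q <- tile_submatrix(ccq, 3, 20)
  sub_t <- tile_submatrix(cct, 7, 20)
  expect_equal(row$s_cosine, cosine_similarity(sub_q, sub_t))
  expect_equal(row$d_frobenius,
               frobenius_similarity(sub_q, sub_t, attr(tb, "d_max"))$d_frobenius)
})

test_that("self-comparison at full length is the perfect-score row", {
  s <- wiggly_helix(18, seed = 16)
  cc <- anm_cross_correlation(s)
  tb <- score_tile_pairs(cc, cc, s, s, L = 18)
  expect_equal(nrow(tb), 1)
  expect_equal(tb$s_cosine, 1)
  expect_equal(tb$s_frobenius, 1)   # degenerate d_max -> similarity 1
  expect_equal(tb$s_sw, 100)
})

test_that("scoring across lengths concatenates per-length tables", {
  sq <- wiggly_helix(14, seed = 17)
  st <- wiggly_helix(20, seed = 18)
  tb <- score_all_lengths(anm_cross_correlation(sq), anm_cross_correlation(st),
                          sq, st, l_min = 6, l_max = 10)
  expect_equal(sort(unique(tb$length)), 6:10)
  expect_equal(nrow(tb), sum((14 - (6:10) + 1) * (20 - (6:10) + 1)))
  expect_equal(sort(as.integer(names(attr(tb, "d_max")))), 6:10)
})
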