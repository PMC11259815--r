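test_that("spearman correlation handles monotone, antitone and tied cases", {
  expect_equal(spearman_corr(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1.0)
  expect_equal(spearman_corr(c(1, 2, 3), c(3, 2, 1)), -1.0)
  # sum of squared rank differences 4 -> 1 - 6*4/(5*24) = 0.8
  expect_equal(spearman_corr(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4)), 0.8)
  expect_equal(spearman_corr(c(1, 2, 3), c(3, 2, 1), absolute = TRUE), 1.0)
  expect_true(is.na(spearman_corr(c(1, 1, 1), c(1, 2, 3))))
})

test_that("raw stoichiometry is 1 for constant ratios and matches the quartile oracle", {
  expect_equal(raw_stoichiometry(c(2, 4, 6), c(1, 2, 3)), 1.0)
  # oracle: type-7 quartiles of log({1,2,4,8}) give Q1 = 0.75*log2,
  # Q3 = 2.25*log2 -> exp(1.5*log2) = 2^1.5
  expect_equal(raw_stoichiometry(c(1, 2, 4, 8), rep(1, 4)), 2^1.5)
  x <- c(1, 2, 4, 8); y <- rep(1, 4)
  expect_equal(raw_stoichiometry(x, y), raw_stoichiometry(y, x))
})

test_that("raw stoichiometry is swap-symmetric and scale-invariant on random data", {
  set.seed(11)
  for (rep in 1:20) {
    x <- rexp(15) + 0.1
    y <- rexp(15) + 0.1
    s <- raw_stoichiometry(x, y)
    expect_equal(s, raw_stoichiometry(y, x))
    expect_equal(s, raw_stoichiometry(3.7 * x, y))
    expect_equal(s, raw_stoichiometry(x, 0.01 * y))
    expect_gte(s, 1)
  }
})

test_that("stoichiometry eligibility requires >= 3 strictly positive sample pairs", {
  expect_true(is.na(raw_stoichiometry(c(1, 2, 0, 0), c(1, 2, 3, 4))))
  # negative samples are excluded like zeros, not fatal
  x <- c(1, 2, 4, -1, 8)
  y <- c(1, 1, 1, 1, 1)
  expect_equal(raw_stoichiometry(x, y),
               raw_stoichiometry(c(1, 2, 4, 8), rep(1, 4)))
})

test_that("weighted stoichiometry punishes one-zero and rewards both-zero samples", {
  x <- c(1, 2, 4, 0, 0, 5)
  y <- c(1, 2, 4, 3, 0, 5)   # one one-zero sample, one both-zero sample
  base <- raw_stoichiometry(x, y)
  w <- raw_stoichiometry(x, y, weighted = TRUE, weight = 1)
  expect_equal(w, base * (1 + 1 / 6) / (1 + 1 / 6))
  # only a one-zero sample: inflated
  x2 <- c(1, 2, 4, 0, 5)
  y2 <- c(1, 2, 4, 3, 5)
  expect_gt(raw_stoichiometry(x2, y2, weighted = TRUE),
            raw_stoichiometry(x2, y2))
  # only a both-zero sample: deflated
  x3 <- c(1, 2, 4, 0, 5)
  y3 <- c(1, 2, 4, 0, 5)
  expect_lt(raw_stoichiometry(x3, y3, weighted = TRUE),
            raw_stoichiometry(x3, y3))
})

test_that("rank adjustment spans 1 to 0 in equal increments and ties share their best position", {
  expect_equal(rank_adjust(c(0.9, 0.5, 0.1)), c(1, 0.5, 0))
  expect_equal(rank_adjust(c(1, 2, 4, 8, 16), higher_better = FALSE),
               c(1, 0.75, 0.5, 0.25, 0))
  expect_equal(rank_adjust(c(0.7, 0.7)), c(1, 1))
  expect_equal(rank_adjust(0.3), 1)             # single candidate is best
  expect_equal(rank_adjust(c(0.2, NA, 0.8)), c(0, NA, 1))
})

test_that("adjusted scores form the expected grid permutation", {
  set.seed(3)
  for (m in c(4, 9, 25)) {
    raw <- rnorm(m)
    adj <- rank_adjust(raw)
    expect_equal(sort(adj), seq(0, 1, length.out = m))
    expect_equal(adj, rank_adjust(-raw, higher_better = FALSE))
  }
})

test_that("score_all_pairs matches the brute-force oracle on a random matrix", {
  mat <- random_matrix(n_features = 10, n_samples = 20, seed = 99)
  st <- score_all_pairs(mat)
  oracle <- oracle_score_table(mat)
  expect_equal(st$raw_corr, oracle$raw_corr)
  expect_equal(st$raw_stoi, oracle$raw_stoi)
  expect_equal(st$adj_corr, oracle$adj_corr)
  expect_equal(st$adj_stoi, oracle$adj_stoi)
  expect_equal(st$combined, oracle$combined)
})

test_that("combined score is the exact product and 1 only when both components are 1", {
  mat <- random_matrix(n_features = 12, n_samples = 15, seed = 5)
  st <- score_all_pairs(mat)
  expect_equal(st$combined, st$adj_corr * st$adj_stoi)
  ones <- which(st$combined == 1)
  expect_true(all(st$adj_corr[ones] == 1 & st$adj_stoi[ones] == 1))
  ok <- !is.na(st$combined)
  expect_true(all(st$combined[ok] >= 0 & st$combined[ok] <= 1))
  # per-source maxima of both adjusted scores are 1
  expect_true(all(apply(st$adj_corr, 1, max, na.rm = TRUE) == 1))
  expect_true(all(apply(st$adj_stoi, 1, max, na.rm = TRUE) == 1))
  # raw stoichiometry symmetric across the table
  expect_equal(st$raw_stoi, t(st$raw_stoi))
})

test_that("proportional features give combined score 1 for every pair", {
  st <- score_all_pairs(proportional_matrix())
  off <- st$combined[upper.tri(st$combined) | lower.tri(st$combined)]
  expect_true(all(off == 1))
})

test_that("monotone transforms preserve the correlation but not the stoichiometry component", {
  mat <- random_matrix(n_features = 6, n_samples = 20, seed = 13)
  v2 <- mat$values
  v2[1, ] <- v2[1, ]^3          # monotone increasing, non-linear
  mat2 <- expression_matrix(v2)
  st1 <- score_all_pairs(mat)
  st2 <- score_all_pairs(mat2)
  expect_equal(st1$raw_corr, st2$raw_corr)
  expect_false(isTRUE(all.equal(st1$raw_stoi[1, ], st2$raw_stoi[1, ])))
})

test_that("constant features are dropped as unscorable, not fatal", {
  v <- rbind(a = c(5, 5, 5, 5, 5), b = c(1, 2, 3, 4, 5),
             c = c(2, 4, 6, 8, 10), d = c(5, 4, 3, 2, 1))
  st <- score_all_pairs(expression_matrix(v))
  expect_true(all(is.na(st$combined["a", ])))
  expect_true(all(is.na(st$combined[, "a"])))
  expect_false(anyNA(st$combined["b", c("c", "d")]))
})

test_that("score tables round-trip through the long-format TSV writer", {
  mat <- random_matrix(n_features = 5, n_samples = 12, seed = 21)
  st <- score_all_pairs(mat)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(st, path)
  df <- read.delim(path)
  expect_named(df, c("source", "target", "raw_corr", "raw_stoi",
                     "adj_corr", "adj_stoi", "combined"))
  expect_equal(nrow(df), sum(!is.na(st$combined)))
  i <- match(df$source, st$feature_ids)
  j <- match(df$target, st$feature_ids)
  expect_equal(df$combined, st$combined[cbind(i, j)], tolerance = 1e-6)
})
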