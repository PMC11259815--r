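# Build a retained pair set directly from an edge list.
pair_set <- function(edges, ids) {
  df <- data.frame(a = edges$a, b = edges$b, score = edges$score)
  attr(df, "feature_ids") <- ids
  df
}

test_that("best_triplet picks the maximally scoring triangle deterministically", {
  ids <- letters[1:4]
  pr <- pair_set(data.frame(a = c("a", "a", "b", "a"),
                            b = c("b", "c", "c", "d"),
                            score = c(1, 1, 1, 0.5)), ids)
  expect_equal(best_triplet("a", pr), c("a", "b", "c"))
  # a feature with a single retained partner has no triangle
  expect_null(best_triplet("d", pr))
})

test_that("best_triplet equals exhaustive triangle search on random graphs", {
  set.seed(12)
  for (rep in 1:8) {
    n <- 15
    ids <- sprintf("f%02d", 1:n)
    pairs <- t(combn(ids, 2))
    keep <- runif(nrow(pairs)) < 0.35
    pr <- pair_set(data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                              score = round(runif(sum(keep)), 3)), ids)
    edge <- function(u, v) {
      hit <- (pr$a == u & pr$b == v) | (pr$a == v & pr$b == u)
      if (any(hit)) pr$score[hit] else NA_real_
    }
    for (f in ids) {
      # oracle: enumerate all candidate triangles containing f
      others <- setdiff(ids, f)
      best <- NULL
      best_sum <- -Inf
      for (uv in combn(others, 2, simplify = FALSE)) {
        s <- c(edge(f, uv[1]), edge(f, uv[2]), edge(uv[1], uv[2]))
        if (anyNA(s)) next
        tot <- sum(s)
        cand <- sort(c(f, uv))
        if (tot > best_sum + 1e-12 ||
            (abs(tot - best_sum) <= 1e-12 && !is.null(best) &&
             paste(cand, collapse = " ") < paste(best, collapse = " "))) {
          best_sum <- tot
          best <- cand
        }
      }
      expect_identical(best_triplet(f, pr), best)
    }
  }
})

test_that("module scores are the mean symmetrized combined score of member pairs", {
  st <- score_all_pairs(proportional_matrix(n_features = 4))
  expect_equal(module_score(st, c("g1", "g2", "g3")), 1)
  mat <- random_matrix(n_features = 8, seed = 31)
  st2 <- score_all_pairs(mat)
  members <- c("f01", "f03", "f05", "f07")
  sym <- (st2$combined + t(st2$combined)) / 2
  expected <- mean(sym[members, members][upper.tri(diag(4))])
  expect_equal(module_score(st2, members), expected)
})

test_that("merge step 1 combines modules sharing two features", {
  st <- score_all_pairs(proportional_matrix(n_features = 6))
  out <- merge_modules(list(c("g1", "g2", "g3"), c("g2", "g3", "g4")),
                       inference_params(), st)
  expect_equal(unname(out$modules), list(c("g1", "g2", "g3", "g4")))
})

test_that("merge step 2 requires small sizes and strong scores of both modules", {
  # proportional features: all pairwise symmetrized combined scores are 1
  st <- score_all_pairs(proportional_matrix(n_features = 6))
  p <- inference_params(single_join_max_size = 3)
  out <- merge_modules(list(c("g1", "g2", "g3"), c("g3", "g4", "g5")), p, st)
  expect_equal(unname(out$modules), list(c("g1", "g2", "g3", "g4", "g5")))
  # a weak module blocks the single-common-feature join
  mixed <- random_matrix(n_features = 8, seed = 61)
  stw <- score_all_pairs(mixed)
  weak <- c("f01", "f02", "f03")
  strong <- c("f03", "f04", "f05")
  sc <- vapply(list(weak, strong), function(m) module_score(stw, m), 0)
  expect_lt(min(sc), 0.66)   # fixture sanity: at least one module is weak
  outw <- merge_modules(list(weak, strong),
                        inference_params(single_join_max_size = 3,
                                         small_join_enabled = FALSE), stw)
  expect_equal(length(outw$modules), 2L)
})

test_that("step order matters: two-common joins run before one-common joins", {
  # chain {g1,g2,g3} - {g3,g4,g5} - {g4,g5,g6}: running step 1 first merges
  # the right-hand pair into a 4-feature module, which under
  # single_join_max_size = 3 can no longer accept the left-hand module;
  # the leftover triplet is then trimmed away at step 4 (g3 sits in the
  # larger module). Running one-common joins first would have chained all
  # six features into a single module instead.
  st <- score_all_pairs(proportional_matrix(n_features = 7))
  tri <- list(c("g1", "g2", "g3"), c("g3", "g4", "g5"), c("g4", "g5", "g6"))
  p <- inference_params(single_join_max_size = 3)
  out <- merge_modules(tri, p, st)
  expect_equal(unname(out$modules), list(c("g3", "g4", "g5", "g6")))
  # with the cap lifted, the one-common join would have chained them all
  p2 <- inference_params(single_join_max_size = 10)
  out2 <- merge_modules(tri, p2, st)
  expect_equal(unname(out2$modules), list(paste0("g", 1:6)))
})

test_that("step 4 trims three-feature modules already covered by larger ones", {
  st <- score_all_pairs(proportional_matrix(n_features = 8))
  p <- inference_params(single_join_max_size = 3, small_join_enabled = FALSE)
  tri <- list(c("g1", "g2", "g3"), c("g2", "g3", "g4"),  # merge to size 4
              c("g4", "g7", "g8"))                       # g4 in larger module
  out <- merge_modules(tri, p, st)
  sizes <- lengths(out$modules)
  expect_false(any(vapply(out$modules,
                          function(m) setequal(m, c("g4", "g7", "g8")), TRUE)))
  expect_true(any(sizes == 4L))
})

test_that("step 5 joins leftover small modules when enabled and within the cap", {
  st <- score_all_pairs(proportional_matrix(n_features = 9))
  p_off <- inference_params(single_join_max_size = 1,
                            small_join_enabled = FALSE)
  tri <- list(c("g1", "g2", "g3"), c("g3", "g7", "g8"))
  expect_equal(length(merge_modules(tri, p_off, st)$modules), 2L)
  p_on <- inference_params(single_join_max_size = 1,
                           small_join_enabled = TRUE,
                           small_join_max_size = 5)
  joined <- merge_modules(tri, p_on, st)
  expect_equal(unname(joined$modules),
               list(c("g1", "g2", "g3", "g7", "g8")))
  # cap below the union size blocks the join
  p_cap <- inference_params(single_join_max_size = 1,
                            small_join_enabled = TRUE,
                            small_join_max_size = 4)
  expect_equal(length(merge_modules(tri, p_cap, st)$modules), 2L)
})

test_that("a perfect triangle dataset yields one module of size 3 with score 1", {
  mods <- infer_modules(proportional_matrix(n_features = 3))
  expect_equal(length(mods), 1L)
  expect_setequal(mods$modules[[1]], c("g1", "g2", "g3"))
  expect_equal(unname(mods$scores), 1)
})

test_that("module inference is deterministic and reproducible from the score table", {
  sim <- simulate_dataset(seed = 17, n_noise_features = 40)
  p <- inference_params(C = 3, S = 10)
  m1 <- infer_modules(sim$matrix, p)
  m2 <- infer_modules(sim$matrix, p)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  # every module's score is reproducible from the score table
  st <- score_all_pairs(sim$matrix, stoichnet:::resolve_params(p, 50))
  for (id in names(m1$modules))
    expect_equal(module_score(st, m1$modules[[id]]),
                 unname(m1$scores[id]))
  expect_true(all(lengths(m1$modules) >= 3L))
})

test_that("planted two-module structure is recovered exactly at suggested parameters", {
  sim <- simulate_dataset(seed = 23)
  mods <- infer_modules(sim$matrix, inference_params(C = 3, S = 10))
  found <- lapply(mods$modules, sort)
  expect_true(list(paste0("x", 1:5)) %in% found ||
                any(vapply(found, setequal, TRUE, paste0("x", 1:5))))
  expect_true(any(vapply(found, setequal, TRUE, paste0("x", 6:10))))
  rm <- recovery_metrics(mods, sim$truth)
  expect_equal(rm$misassigned, 0L)
})
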