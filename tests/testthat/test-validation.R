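test_that("module validation scores count recovered relations", {
  mods <- list(c("A", "B", "C"))
  ann <- annotation_relations(pairs = data.frame(a = "A", b = "B"))
  expect_equal(module_validation_score(mods, ann), 1)
  # group relation: all three within-module pairs share the group
  grp <- annotation_relations(groups = list(K = c("A", "B", "C")))
  expect_equal(module_validation_score(mods, grp), 3)
  # no annotated features
  far <- annotation_relations(pairs = data.frame(a = "X", b = "Y"))
  expect_equal(module_validation_score(mods, far), 0)
  # a pair recovered in two modules counts once per module
  mods2 <- list(c("A", "B", "C"), c("A", "B", "D"))
  expect_equal(module_validation_score(mods2, ann), 2)
})

test_that("group-derived pairs are deduplicated and weights are summable", {
  mods <- list(c("A", "B", "C"))
  two_groups <- annotation_relations(groups = list(K1 = c("A", "B"),
                                                   K2 = c("A", "B", "C")))
  # pair AB shares two groups but counts once
  expect_equal(module_validation_score(mods, two_groups), 3)
  wann <- annotation_relations(pairs = data.frame(a = c("A", "B"),
                                                  b = c("B", "C"),
                                                  weight = c(0.9, 0.4)))
  expect_equal(module_validation_score(mods, wann, weighted = TRUE), 1.3)
})

test_that("validation scores equal brute force on random instances and grow with annotations", {
  set.seed(19)
  universe <- sprintf("u%02d", 1:40)
  for (rep in 1:5) {
    mods <- lapply(sample(3:6, 4, TRUE), function(k) sample(universe, k))
    prs <- t(combn(universe, 2))
    keep <- runif(nrow(prs)) < 0.1
    ann <- annotation_relations(pairs = data.frame(a = prs[keep, 1],
                                                   b = prs[keep, 2]))
    # brute force double loop
    expected <- 0L
    for (m in mods) for (r in which(keep))
      if (prs[r, 1] %in% m && prs[r, 2] %in% m) expected <- expected + 1L
    expect_equal(module_validation_score(mods, ann), expected)
    # monotone in annotation growth
    more <- annotation_relations(pairs = data.frame(
      a = c(prs[keep, 1], mods[[1]][1]),
      b = c(prs[keep, 2], mods[[1]][2])))
    expect_gte(module_validation_score(mods, more), expected)
  }
})

test_that("pathway validation counts cross-module co-annotated pairs only", {
  pw <- list(list(c("A", "B"), c("C")))
  ann <- annotation_relations(groups = list(P = c("A", "C")))
  expect_equal(pathway_validation_score(pw, ann), 1)
  # same-module co-annotation does not count
  ann2 <- annotation_relations(groups = list(P = c("A", "B")))
  expect_equal(pathway_validation_score(pw, ann2), 0)
})

test_that("pathway validation equals brute force on random instances", {
  set.seed(29)
  universe <- sprintf("v%02d", 1:30)
  for (rep in 1:5) {
    pws <- lapply(1:3, function(i) {
      mods <- lapply(sample(2:4, sample(2:3, 1), TRUE),
                     function(k) sample(universe, k))
      mods
    })
    groups <- lapply(1:4, function(i) sample(universe, sample(3:8, 1)))
    names(groups) <- paste0("P", 1:4)
    ann <- annotation_relations(groups = groups)
    # brute force triple loop over pathways and feature pairs
    expected <- 0L
    co_annotated <- function(f, g)
      any(vapply(groups, function(gr) f %in% gr && g %in% gr, TRUE))
    for (pw in pws) {
      feats <- unique(unlist(pw))
      if (length(feats) < 2) next
      cmb <- combn(sort(feats), 2)
      for (k in seq_len(ncol(cmb))) {
        f <- cmb[1, k]; g <- cmb[2, k]
        cross <- FALSE
        for (i in seq_along(pw)) for (j in seq_along(pw))
          if (i != j && f %in% pw[[i]] && g %in% pw[[j]]) cross <- TRUE
        if (cross && co_annotated(f, g)) expected <- expected + 1L
      }
    }
    expect_equal(pathway_validation_score(pws, ann), expected)
  }
})

test_that("randomized nulls are reproducible and match the hypergeometric expectation", {
  set.seed(4)
  universe <- sprintf("w%02d", 1:30)
  prs <- t(combn(universe, 2))
  keep <- runif(nrow(prs)) < 0.25
  ann <- annotation_relations(pairs = data.frame(a = prs[keep, 1],
                                                 b = prs[keep, 2]))
  M <- sum(keep)
  mods <- list(universe[1:6])
  n1 <- randomized_null(mods, ann, universe, rounds = 400, seed = 11)
  n2 <- randomized_null(mods, ann, universe, rounds = 400, seed = 11)
  expect_identical(n1, n2)
  # E[score] = M * C(k,2) / C(N,2) for one random module of size k
  expected_mean <- M * choose(6, 2) / choose(30, 2)
  expect_lt(abs(mean(n1) - expected_mean),
            4 * stats::sd(n1) / sqrt(length(n1)) + 0.05)
  # universe identical to the single module: every round scores the same
  nd <- randomized_null(list(universe), ann, universe, rounds = 20,
                        seed = 2)
  expect_true(all(nd == module_validation_score(list(universe), ann)))
})

test_that("connections-only nulls permute module-to-pathway assignment", {
  pws <- list(list(c("A", "B"), c("C", "D")),
              list(c("E", "F"), c("G", "H")))
  ann <- annotation_relations(groups = list(P1 = c("A", "C"),
                                            P2 = c("E", "G")))
  obs <- pathway_validation_score(pws, ann)
  expect_equal(obs, 2)
  nc <- randomized_null(pws, ann, universe = c("A", "B", "C", "D",
                                               "E", "F", "G", "H"),
                        rounds = 200, seed = 3, mode = "connections_only")
  expect_length(nc, 200)
  # intact modules shuffled between pathways: scores vary but the pooled
  # module contents never change, so scores stay within the observed range
  expect_true(all(nc %in% c(0, 1, 2)))
  expect_gt(stats::sd(nc), 0)
})

test_that("empirical p-values follow the null CDF with relative distance from the median", {
  set.seed(6)
  null <- 1:1000
  r_mid <- empirical_p(500.5, null)
  expect_equal(r_mid$relative_distance, 0)
  expect_equal(r_mid$p_value, 0.5, tolerance = 0.02)
  r_hi <- empirical_p(max(null) + 10 * r_mid$kde_bandwidth, null)
  expect_lt(r_hi$p_value, 1e-6)
  r_lo <- empirical_p(0, null)
  expect_gt(r_lo$p_value, 0.95)
  # the Epanechnikov KDE at the Silverman bandwidth integrates to 1 over
  # its finite support (direct kernel-sum evaluation)
  bw <- stats::bw.nrd0(null)
  h <- bw * sqrt(5)
  grid <- seq(min(null) - h, max(null) + h, length.out = 2^15)
  f <- vapply(grid, function(x) {
    u <- (x - null) / h
    mean(ifelse(abs(u) < 1, 0.75 * (1 - u^2), 0)) / h
  }, 0)
  integral <- sum((f[-1] + f[-length(f)]) / 2 * diff(grid))
  expect_lt(abs(integral - 1), 1e-6)
  # degenerate null falls back to the point mass with a warning
  expect_warning(rd <- empirical_p(5, rep(3, 100)), "degenerate")
  expect_equal(rd$p_value, 0)
  expect_warning(rd2 <- empirical_p(2, rep(3, 100)), "degenerate")
  expect_equal(rd2$p_value, 1)
})

test_that("relative distance matches its definition on observed scores", {
  null <- c(2, 4, 6, 8, 10)
  r <- empirical_p(9, null)
  expect_equal(r$relative_distance, (9 - 6) / 6)
  expect_warning(z <- empirical_p(1, c(0, 0, 0, 0, 1)), "median is zero")
  expect_true(is.na(z$relative_distance))
})

test_that("conservation recovers training structure and degrades under permutation", {
  sim <- simulate_dataset(seed = 33)
  mods <- infer_modules(sim$matrix, inference_params(C = 3, S = 10))
  expect_gte(length(mods), 1L)
  # identical dataset: strongly conserved
  expect_gt(conservation(mods, sim$matrix, "combined"), 0.9)
  # independent dataset with the same planted structure: conserved
  sim2 <- simulate_dataset(seed = 34)
  expect_gt(conservation(mods, sim2$matrix, "combined"), 0.5)
  # feature-permuted dataset: near the random median 0.5
  meds <- vapply(1:10, function(s) {
    set.seed(100 + s)
    v <- sim2$matrix$values
    rownames(v) <- sample(rownames(v))
    conservation(mods, suppressWarnings(expression_matrix(v)),
                 "correlation")
  }, 0)
  expect_lt(abs(mean(meds) - 0.5), 0.15)
})

test_that("validation wrapper ties the pieces together significantly on planted data", {
  sim <- simulate_dataset(seed = 35, n_module_copies = 4,
                          n_noise_features = 20)
  mods <- infer_modules(sim$matrix, inference_params(C = 3, S = 40))
  truth_groups <- split(names(sim$truth), sim$truth)
  truth_groups$none <- NULL
  ann <- annotation_relations(groups = truth_groups)
  res <- validate_against_annotations(mods, ann,
                                      universe = sim$matrix$feature_ids,
                                      rounds = 300, seed = 7)
  expect_s3_class(res, "validation_result")
  expect_lt(res$p_value, 0.05)
  expect_gt(res$relative_distance, 0)
  expect_length(res$null_scores, 300)
})
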