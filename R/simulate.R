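#' Simulate an omics dataset with planted network modules
#'
#' Generates two planted five-feature modules per copy,
#' `X1 = {x1..x5}` and `X2 = {x6..x10}`, through the chain
#'
#' ```
#' x1 = s1 + e1                x6  = mu1 * x10 + e6
#' x2 = l1 * x1 + e2           x7  = a4 * x6  + e7
#' x3 = a1 * x2 + e3           x8  = a5 * x7  + e8
#' x4 = a2 * x3 + e4           x9  = a6 * x8  + mu2 * x10 + e9
#' x5 = a3 * x4 + l2 * x1 + e5 x10 = s2 + e10
#' ```
#'
#' plus a pool of non-associated noise features built as `s3 - e11`.
#' Three distribution families are supported, with the dataset-difficulty
#' level `Y` drawn once per dataset:
#'
#' * `normal`: `s1, s2 ~ N(Y, 1)`, `e1-e10 ~ N(1, Y/10)` with
#'   `Y` an integer in `[2, 30]`; noise `s3` a per-sample integer draw
#'   from `[1, 35]` and `e11 ~ N(0, 1)`.
#' * `negative_binomial`: `s1, s2 ~ NB(Y, 0.05)`, `e1-e10 ~ NB(Y, 0.5)`,
#'   `Y` in `[2, 15]`; noise `s3 ~ NB(Y', 0.05)`, `e11 ~ NB(Y', 0.5)`.
#' * `beta`: `s1, s2 ~ Beta(Y, 2)`, `e1-e10 ~ Beta(Y, 50)`, `Y` in
#'   `[2, 10]`; noise `s3 ~ Beta(Y', 3)`, `e11 ~ Beta(Y', 50)`.
#'
#' All chain coefficients default to 1. Normal parameters are read as
#' `N(mean, sd)`; negative binomial as (successes `r`, success probability
#' `p`); values are never truncated, so noise features can go slightly
#' negative — the scoring eligibility rules handle that downstream. The
#' `dimensionality_variant` switches the normal-family error terms to
#' `e ~ N(Y/5, Y/50)` with `Y` in `[2, 10]` (the low-noise regime used for
#' dimensionality sweeps).
#'
#' @param family Distribution family.
#' @param n_samples Number of samples (default 50).
#' @param n_module_copies Number of planted X1/X2 pairs (each copy
#'   contributes 10 features).
#' @param n_noise_features Number of non-associated features (default 90,
#'   i.e. 100 features total with one copy).
#' @param lambda,alpha,mu Chain coefficients (`lambda` length 2, `alpha`
#'   length 6, `mu` length 2; default all 1).
#' @param Y Optional fixed difficulty level; drawn uniformly from the
#'   family's range when `NULL`.
#' @param dimensionality_variant Use the low-noise normal error form.
#' @param seed Optional integer seed.
#' @return A list of class `simulated_dataset` with `matrix` (an
#'   [expression_matrix()]) and `truth` (named vector mapping each feature
#'   to its planted module label, `"none"` for noise features).
#' @examples
#' sim <- simulate_dataset(n_noise_features = 10, seed = 1)
#' table(sim$truth)
#' @export
simulate_dataset <- function(family = c("normal", "negative_binomial",
                                        "beta"),
                             n_samples = 50L,
                             n_module_copies = 1L,
                             n_noise_features = 90L,
                             lambda = c(1, 1),
                             alpha = rep(1, 6),
                             mu = c(1, 1),
                             Y = NULL,
                             dimensionality_variant = FALSE,
                             seed = NULL) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  n_samples <- as.integer(n_samples)
  if (n_samples < 3L) stop("at least 3 samples are required")
  stopifnot(length(lambda) == 2L, length(alpha) == 6L, length(mu) == 2L)

  y_range <- switch(family,
                    normal = if (dimensionality_variant) 2:10 else 2:30,
                    negative_binomial = 2:15,
                    beta = 2:10)
  if (is.null(Y)) Y <- sample(y_range, 1L)
  if (!(Y %in% y_range))
    stop(sprintf("Y must lie in [%d, %d] for the %s family",
                 min(y_range), max(y_range), family))

  draw_s <- switch(family,
                   normal = function(n) stats::rnorm(n, Y, 1),
                   negative_binomial = function(n)
                     stats::rnbinom(n, size = Y, prob = 0.05),
                   beta = function(n) stats::rbeta(n, Y, 2))
  draw_e <- switch(family,
                   normal = if (dimensionality_variant)
                     function(n) stats::rnorm(n, Y / 5, Y / 50)
                   else function(n) stats::rnorm(n, 1, Y / 10),
                   negative_binomial = function(n)
                     stats::rnbinom(n, size = Y, prob = 0.5),
                   beta = function(n) stats::rbeta(n, Y, 50))

  rows <- list()
  truth <- character()
  for (copy in seq_len(n_module_copies)) {
    s1 <- draw_s(n_samples)
    s2 <- draw_s(n_samples)
    e <- replicate(10L, draw_e(n_samples), simplify = FALSE)
    x <- vector("list", 10L)
    x[[1L]] <- s1 + e[[1L]]
    x[[2L]] <- lambda[1L] * x[[1L]] + e[[2L]]
    x[[3L]] <- alpha[1L] * x[[2L]] + e[[3L]]
    x[[4L]] <- alpha[2L] * x[[3L]] + e[[4L]]
    x[[5L]] <- alpha[3L] * x[[4L]] + lambda[2L] * x[[1L]] + e[[5L]]
    x[[10L]] <- s2 + e[[10L]]
    x[[6L]] <- mu[1L] * x[[10L]] + e[[6L]]
    x[[7L]] <- alpha[4L] * x[[6L]] + e[[7L]]
    x[[8L]] <- alpha[5L] * x[[7L]] + e[[8L]]
    x[[9L]] <- alpha[6L] * x[[8L]] + mu[2L] * x[[10L]] + e[[9L]]
    names(x) <- paste0("x", (copy - 1L) * 10L + 1:10)
    rows <- c(rows, x)
    truth <- c(truth,
               rep(paste0("X1.", copy), 5L),
               rep(paste0("X2.", copy), 5L))
  }

  if (n_noise_features > 0L) {
    noise <- switch(family,
      normal = lapply(seq_len(n_noise_features), function(i)
        sample(1:35, n_samples, replace = TRUE) -
          stats::rnorm(n_samples, 0, 1)),
      negative_binomial = {
        Y4 <- sample(2:15, 1L)
        lapply(seq_len(n_noise_features), function(i)
          stats::rnbinom(n_samples, size = Y4, prob = 0.05) -
            stats::rnbinom(n_samples, size = Y4, prob = 0.5))
      },
      beta = {
        Y4 <- sample(2:10, 1L)
        lapply(seq_len(n_noise_features), function(i)
          stats::rbeta(n_samples, Y4, 3) - stats::rbeta(n_samples, Y4, 50))
      })
    names(noise) <- paste0("n", seq_len(n_noise_features))
    rows <- c(rows, noise)
    truth <- c(truth, rep("none", n_noise_features))
  }

  values <- do.call(rbind, rows)
  colnames(values) <- paste0("s", seq_len(n_samples))
  names(truth) <- rownames(values)
  mat <- suppressWarnings(
    expression_matrix(values, layer_tag = paste0("sim_", family),
                      missing_as_zero = FALSE))
  structure(list(matrix = mat, truth = truth, family = family, Y = Y),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %s family (Y = %d): %d features (%d planted) x %d samples\n",
              x$family, x$Y, nrow(x$matrix$values),
              sum(x$truth != "none"), ncol(x$matrix$values)))
  invisible(x)
}

#' Recovery metrics of inferred modules against the planted truth
#'
#' Quantifies how well an inferred module set recovers the planted modules
#' of a [simulate_dataset()] run:
#'
#' * `recall` — mean over planted modules of the best single-module
#'   overlap fraction;
#' * `misassigned` — planted features placed in a module whose majority
#'   planted label is a *different* planted module (cross-module
#'   confusion);
#' * `false_positive_features` — noise-label features appearing in any
#'   module;
#' * `false_positive_modules` — modules whose members are mostly noise;
#' * `pair_f1` (with `precision`/`recall` on pairs) — F1 of co-module
#'   feature pairs against co-planted pairs, the overall accuracy summary.
#'
#' @param inferred A `module_set` (or list of feature-id vectors).
#' @param truth Named label vector from [simulate_dataset()].
#' @return A list of class `recovery_metrics`.
#' @export
recovery_metrics <- function(inferred, truth) {
  mem <- member_lists(inferred)
  planted_labels <- setdiff(unique(truth), "none")
  planted_sets <- lapply(planted_labels, function(l) names(truth)[truth == l])
  names(planted_sets) <- planted_labels

  recall_per <- vapply(planted_sets, function(ps) {
    if (!length(mem)) return(0)
    max(vapply(mem, function(m) length(intersect(m, ps)) / length(ps), 0))
  }, 0)

  misassigned <- 0L
  fp_features <- character()
  fp_modules <- 0L
  for (m in mem) {
    labs <- truth[m]
    fp_features <- union(fp_features, m[labs == "none"])
    planted_in <- labs[labs != "none"]
    if (length(planted_in) < length(labs) / 2) fp_modules <- fp_modules + 1L
    if (!length(planted_in)) next
    tab <- sort(table(planted_in), decreasing = TRUE)
    majority <- names(tab)[1L]
    misassigned <- misassigned + sum(planted_in != majority)
  }

  pair_key <- function(sets) {
    keys <- character()
    for (s in sets) {
      if (length(s) < 2L) next
      cmb <- utils::combn(sort(s), 2L)
      keys <- c(keys, paste(cmb[1L, ], cmb[2L, ], sep = "\r"))
    }
    unique(keys)
  }
  true_pairs <- pair_key(planted_sets)
  pred_pairs <- pair_key(mem)
  tp <- length(intersect(pred_pairs, true_pairs))
  precision <- if (length(pred_pairs)) tp / length(pred_pairs) else 0
  recall_pairs <- if (length(true_pairs)) tp / length(true_pairs) else 0
  f1 <- if (precision + recall_pairs > 0)
    2 * precision * recall_pairs / (precision + recall_pairs) else 0

  structure(
    list(recall = mean(recall_per),
         recall_per_module = recall_per,
         misassigned = misassigned,
         false_positive_features = length(fp_features),
         false_positive_modules = fp_modules,
         pair_precision = precision,
         pair_recall = recall_pairs,
         pair_f1 = f1),
    class = "recovery_metrics"
  )
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf(paste0("<recovery_metrics> recall %.2f, misassigned %d, ",
                     "noise FPs %d, pair F1 %.3f\n"),
              x$recall, x$misassigned, x$false_positive_features, x$pair_f1))
  invisible(x)
}
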