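#' Spearman correlation between two sample-aligned vectors
#'
#' Rank correlation with average ranks for ties, the raw correlation score
#' of the association metric. Constant vectors make the correlation
#' undefined; the pair is then flagged degenerate by returning `NA` (it is
#' excluded from scoring rather than aborting a run).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param absolute Return `|rho|`; used at the pathway-combination stage so
#'   that up- and downregulated modules combine equally.
#' @return Spearman rho in `[-1, 1]` (`[0, 1]` if `absolute`), or `NA` for a
#'   degenerate pair.
#' @examples
#' spearman_corr(1:4, c(2, 4, 6, 8))
#' spearman_corr(1:3, 3:1)
#' @export
spearman_corr <- function(x, y, absolute = FALSE) {
  if (length(x) != length(y)) stop("x and y must be sample-aligned")
  if (length(x) < 3L) stop("at least 3 samples are required")
  r <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  if (is.na(r)) return(NA_real_)
  if (absolute) abs(r) else r
}

# Type-7 quartile positions evaluated on log-ratios: interpolation between
# order statistics is done geometrically, which makes Q3/Q1 exactly
# invariant under ratio inversion (swapping the two features) and under
# rescaling of either feature.  Returns exp(Q3 - Q1) of the log-ratios.
q3_over_q1 <- function(log_ratios) {
  n <- length(log_ratios)
  s <- sort.int(log_ratios, method = "quick")
  h1 <- (n - 1) * 0.25
  h3 <- (n - 1) * 0.75
  f1 <- floor(h1)
  f3 <- floor(h3)
  q1 <- s[f1 + 1] + (h1 - f1) * (s[min(f1 + 2, n)] - s[f1 + 1])
  q3 <- s[f3 + 1] + (h3 - f3) * (s[min(f3 + 2, n)] - s[f3 + 1])
  exp(q3 - q1)
}

#' Raw stoichiometry score of a feature pair
#'
#' The third-to-first quartile ratio `Q3/Q1` of the per-sample abundance
#' ratios `x_s / y_s`. A value of 1 means the two features keep a perfectly
#' conserved stoichiometry across samples; larger values mean less
#' conserved. Only samples where both values are non-zero enter the ratio
#' set ("eligible" samples), and at least 3 are required.
#'
#' Quartiles interpolate between order statistics at the type-7 positions,
#' with the interpolation performed on the log scale so that the score is
#' exactly symmetric under swapping `x` and `y` and invariant to rescaling
#' either feature.
#'
#' In the zero-inflated (`weighted`) variant the base score is multiplied by
#' `(1 + w f_one) / (1 + w f_both)`: samples where exactly one feature is
#' zero inflate (punish) the score, samples where both are zero deflate
#' (reward) it.
#'
#' Eligibility requires strictly positive values in both features: zeros
#' are excluded by definition, and negative values (which preprocessed
#' abundance data should not contain, but simulated data occasionally
#' does) are excluded sample-wise the same way so that all ratios stay
#' positive.
#'
#' @param x,y Numeric vectors of equal length.
#' @param weighted Use the zero-inflated variant.
#' @param weight Penalty weight `w >= 0` (default 1).
#' @param anti Score an anti-monotone pair: quartile ratio of the products
#'   `x_s * y_s` instead of the ratios `x_s / y_s` (the ratio against the
#'   reciprocal partner), so that perfectly anti-proportional profiles
#'   score 1. Used at the pathway stage in absolute-correlation mode for
#'   pairs with negative signed correlation.
#' @return The score (`>= 1` for strictly positive data), or `NA` if fewer
#'   than 3 eligible samples exist.
#' @examples
#' raw_stoichiometry(c(2, 4, 6), c(1, 2, 3))   # constant ratio -> 1
#' raw_stoichiometry(c(1, 2, 4, 8), rep(1, 4))
#' @export
raw_stoichiometry <- function(x, y, weighted = FALSE, weight = 1,
                              anti = FALSE) {
  if (length(x) != length(y)) stop("x and y must be sample-aligned")
  zx <- x == 0
  zy <- y == 0
  eligible <- x > 0 & y > 0
  if (sum(eligible) < 3L) return(NA_real_)
  r <- if (anti) x[eligible] * y[eligible] else x[eligible] / y[eligible]
  score <- q3_over_q1(log(r))
  if (weighted) {
    f_one <- mean(xor(zx, zy))
    f_both <- mean(zx & zy)
    score <- score * (1 + weight * f_one) / (1 + weight * f_both)
  }
  score
}

#' Feature-wise rank adjustment of raw scores
#'
#' Converts one feature's raw scores against all its candidate partners into
#' the `[0, 1]` adjusted scale: the best partner gets 1, the worst gets 0,
#' and scores in between decrease in equal increments of `1/(m-1)` by rank
#' (`m` = number of scorable partners). Tied raw scores all receive the
#' adjusted value of their best position, so the guarantee that every
#' feature's best partner scores exactly 1 holds even under ties. For
#' correlation "best" is the highest raw score; for stoichiometry it is
#' the lowest (most conserved).
#'
#' @param raw Numeric vector of raw scores for one source feature; `NA`
#'   entries (unscorable partners) are preserved as `NA` and do not count
#'   towards `m`.
#' @param higher_better `TRUE` for correlation, `FALSE` for stoichiometry.
#' @return Adjusted scores in `[0, 1]`, same length and names as `raw`.
#' @examples
#' rank_adjust(c(0.9, 0.5, 0.1))                       # 1.0 0.5 0.0
#' rank_adjust(c(1, 2, 4, 8, 16), higher_better = FALSE)
#' rank_adjust(c(0.7, 0.7))                            # tied best -> 1 1
#' @export
rank_adjust <- function(raw, higher_better = TRUE) {
  ok <- !is.na(raw)
  m <- sum(ok)
  out <- rep(NA_real_, length(raw))
  names(out) <- names(raw)
  if (m == 0L) return(out)
  if (m == 1L) {
    out[ok] <- 1
    return(out)
  }
  key <- if (higher_better) -raw[ok] else raw[ok]
  rk <- rank(key, ties.method = "min")
  out[ok] <- (m - rk) / (m - 1)
  out
}

#' Score every feature pair of an expression matrix
#'
#' Computes, for all ordered feature pairs, the raw Spearman correlation and
#' raw stoichiometry scores, rank-adjusts both feature-wise, and multiplies
#' the two adjusted scores into the combined association score in `[0, 1]`.
#' The adjustment is directional: the pair (i, j) is ranked within feature
#' i's candidates, and (j, i) within feature j's, so the two directions of a
#' pair generally differ (the discrepancy filter later bounds how much).
#'
#' A pair is scorable only when both raw scores exist (non-constant vectors,
#' at least 3 eligible samples with strictly positive ratios); unscorable
#' pairs are absent (`NA`) and reduce the rank denominator `m` for their
#' source feature.
#'
#' @param matrix An [expression_matrix()].
#' @param params An [inference_params()]; only the scoring switches
#'   (`use_absolute_correlation`, `weighted_stoichiometry`,
#'   `stoichiometry_weight`) are used here.
#' @return An object of class `score_table` holding `n x n` matrices
#'   `raw_corr`, `raw_stoi`, `adj_corr`, `adj_stoi` and `combined`
#'   (rows = source feature, columns = target).
#' @export
score_all_pairs <- function(matrix, params = inference_params()) {
  stopifnot(inherits(matrix, "expression_matrix"))
  v <- matrix$values
  n <- nrow(v)
  if (n < 3L) stop("scoring requires at least 3 features")
  frac_zero <- mean(v == 0)
  if (frac_zero > 0.30 && !params$weighted_stoichiometry)
    warning(sprintf(paste0("%.0f%% of entries are zero; consider the ",
                           "zero-inflated stoichiometry variant ",
                           "(weighted_stoichiometry = TRUE)"),
                    100 * frac_zero))

  rc_signed <- suppressWarnings(stats::cor(t(v), method = "spearman"))
  rc <- if (params$use_absolute_correlation) abs(rc_signed) else rc_signed
  diag(rc) <- NA_real_

  rs <- matrix(NA_real_, n, n, dimnames = dimnames(rc))
  strictly_pos <- rowSums(v > 0) == ncol(v)
  # in absolute-correlation mode anti-monotone pairs are scored against the
  # reciprocal partner so down- and upregulation combine equally
  align <- params$use_absolute_correlation
  # strictly positive rows have no zeros, so the zero-inflation factors are
  # 1 for both variants and the lean ratio path applies
  for (i in seq_len(n - 1L)) {
    vi <- v[i, ]
    for (j in (i + 1L):n) {
      anti <- align && !is.na(rc_signed[i, j]) && rc_signed[i, j] < 0
      sij <- if (strictly_pos[i] && strictly_pos[j])
        q3_over_q1(if (anti) log(vi * v[j, ]) else log(vi / v[j, ]))
      else
        raw_stoichiometry(vi, v[j, ],
                          weighted = params$weighted_stoichiometry,
                          weight = params$stoichiometry_weight,
                          anti = anti)
      rs[i, j] <- rs[j, i] <- sij
    }
  }

  scorable <- !is.na(rc) & !is.na(rs)
  rc[!scorable] <- NA_real_
  rs[!scorable] <- NA_real_

  adj_c <- t(apply(rc, 1L, rank_adjust, higher_better = TRUE))
  adj_s <- t(apply(rs, 1L, rank_adjust, higher_better = FALSE))
  dimnames(adj_c) <- dimnames(adj_s) <- dimnames(rc)

  structure(
    list(feature_ids = matrix$feature_ids,
         n_features = n,
         raw_corr = rc,
         raw_stoi = rs,
         adj_corr = adj_c,
         adj_stoi = adj_s,
         combined = adj_c * adj_s,
         layer_tag = matrix$layer_tag,
         params = params),
    class = "score_table"
  )
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> layer '%s': %d features, %d scorable pairs\n",
              x$layer_tag, x$n_features,
              sum(!is.na(x$combined)) %/% 2L))
  invisible(x)
}

# Undirected edge score: mean of the two directional combined scores.
symmetrized_combined <- function(table) {
  (table$combined + t(table$combined)) / 2
}

#' Write a score table as long-format TSV
#'
#' One row per ordered scorable pair with columns `source`, `target`,
#' `raw_corr`, `raw_stoi`, `adj_corr`, `adj_stoi`, `combined`.
#'
#' @param table A `score_table` from [score_all_pairs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  idx <- which(!is.na(table$combined), arr.ind = TRUE)
  df <- data.frame(
    source = table$feature_ids[idx[, 1L]],
    target = table$feature_ids[idx[, 2L]],
    raw_corr = table$raw_corr[idx],
    raw_stoi = table$raw_stoi[idx],
    adj_corr = table$adj_corr[idx],
    adj_stoi = table$adj_stoi[idx],
    combined = table$combined[idx]
  )
  df <- df[order(df$source, df$target), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
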