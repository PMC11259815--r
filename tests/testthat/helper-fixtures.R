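# Shared fixtures, all generated in code.

# Small strictly positive random matrix with reproducible values.
random_matrix <- function(n_features = 10, n_samples = 20, seed = 42,
                          layer_tag = "test") {
  set.seed(seed)
  v <- matrix(rexp(n_features * n_samples, rate = 0.2),
              n_features, n_samples,
              dimnames = list(sprintf("f%02d", seq_len(n_features)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(v, layer_tag = layer_tag)
}

# Three features that are exact scalar multiples of one template: every
# pair has Spearman rho 1 and a perfectly constant ratio.
proportional_matrix <- function(n_features = 3, n_samples = 10, seed = 7) {
  set.seed(seed)
  base <- sort(rexp(n_samples, 0.1)) + 1
  v <- t(vapply(seq_len(n_features), function(i) i * base,
                numeric(n_samples)))
  rownames(v) <- paste0("g", seq_len(n_features))
  colnames(v) <- paste0("s", seq_len(n_samples))
  expression_matrix(v)
}

# Brute-force oracle: score one ordered pair directly from first
# principles (average-rank Spearman via cor.test-free formula, quartile
# ratio via stats::quantile on the log scale).
oracle_pair <- function(x, y, absolute = FALSE) {
  rc <- stats::cor(rank(x), rank(y))
  if (absolute) rc <- abs(rc)
  eligible <- x > 0 & y > 0
  rs <- if (sum(eligible) < 3) NA_real_ else {
    lr <- log(x[eligible] / y[eligible])
    exp(diff(stats::quantile(lr, c(0.25, 0.75), type = 7, names = FALSE)))
  }
  c(corr = rc, stoi = rs)
}

# Brute-force oracle for the full table: naive double loop plus direct
# rank adjustment.
oracle_score_table <- function(mat, absolute = FALSE) {
  v <- mat$values
  n <- nrow(v)
  rc <- matrix(NA_real_, n, n, dimnames = list(rownames(v), rownames(v)))
  rs <- rc
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (stats::sd(v[i, ]) == 0 || stats::sd(v[j, ]) == 0) next
      o <- oracle_pair(v[i, ], v[j, ], absolute)
      rc[i, j] <- o["corr"]
      rs[i, j] <- o["stoi"]
    }
  }
  scorable <- !is.na(rc) & !is.na(rs)
  rc[!scorable] <- NA
  rs[!scorable] <- NA
  adj <- function(row, higher) {
    ok <- !is.na(row)
    m <- sum(ok)
    out <- rep(NA_real_, length(row))
    if (m == 1) out[ok] <- 1
    else if (m > 1) {
      r <- rank(if (higher) -row[ok] else row[ok], ties.method = "min")
      out[ok] <- (m - r) / (m - 1)
    }
    out
  }
  ac <- t(apply(rc, 1, adj, higher = TRUE))
  as <- t(apply(rs, 1, adj, higher = FALSE))
  dimnames(ac) <- dimnames(as) <- dimnames(rc)
  list(raw_corr = rc, raw_stoi = rs, adj_corr = ac, adj_stoi = as,
       combined = ac * as)
}
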