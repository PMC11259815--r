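#' Score of a feature group
#'
#' The module score: mean of the symmetrized combined scores over all
#' member pairs (pairs without a score are ignored).
#'
#' @param table A `score_table`.
#' @param members Character vector of member feature ids.
#' @return A value in `[0, 1]` (or `NaN` if no member pair is scorable).
#' @export
module_score <- function(table, members) {
  w <- symmetrized_combined(table)
  idx <- match(members, table$feature_ids)
  if (anyNA(idx)) stop("members absent from score table: ",
                       paste(members[is.na(idx)], collapse = ", "))
  sub <- w[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)], na.rm = TRUE)
}

# Internal graph form of a retained pair set: logical adjacency and
# symmetric edge-weight matrix over the full feature order.
pairs_to_graph <- function(pairs) {
  ids <- attr(pairs, "feature_ids")
  if (is.null(ids)) ids <- sort(unique(c(pairs$a, pairs$b)))
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  w <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  ia <- match(pairs$a, ids)
  ib <- match(pairs$b, ids)
  adj[cbind(ia, ib)] <- adj[cbind(ib, ia)] <- TRUE
  w[cbind(ia, ib)] <- w[cbind(ib, ia)] <- pairs$score
  list(ids = ids, adj = adj, w = w)
}

#' Maximally scoring three-feature clique for one feature
#'
#' Among all triangles of retained pairs that contain `feature`, returns the
#' one maximizing the sum of the three symmetrized combined edge scores.
#' Ties are broken towards the lexicographically smallest member set, so
#' the result is deterministic.
#'
#' @param feature Feature id.
#' @param pairs Retained pair set from [discrepancy_filter()].
#' @return Character vector of the 3 member ids (sorted), or `NULL` when no
#'   triangle contains the feature.
#' @export
best_triplet <- function(feature, pairs) {
  g <- pairs_to_graph(pairs)
  f <- match(feature, g$ids)
  if (is.na(f)) return(NULL)
  best_triplet_idx(f, g$adj, g$w, g$ids)
}

best_triplet_idx <- function(f, adj, w, ids) {
  nb <- which(adj[f, ])
  if (length(nb) < 2L) return(NULL)
  best_sum <- -Inf
  best <- NULL
  for (k in seq_len(length(nb) - 1L)) {
    u <- nb[k]
    vs <- nb[(k + 1L):length(nb)]
    vs <- vs[adj[u, vs]]
    if (!length(vs)) next
    sums <- w[f, u] + w[f, vs] + w[u, vs]
    for (m in seq_along(vs)) {
      cand_sum <- sums[m]
      if (cand_sum < best_sum - 1e-12) next
      cand <- sort(ids[c(f, u, vs[m])])
      if (cand_sum > best_sum + 1e-12 ||
          (abs(cand_sum - best_sum) <= 1e-12 &&
           paste(cand, collapse = "\r") < paste(best, collapse = "\r"))) {
        best_sum <- cand_sum
        best <- cand
      }
    }
  }
  best
}

# Deterministic processing order: descending score, then lexicographic
# member key.
module_order <- function(members, scores) {
  keys <- vapply(members, paste, "", collapse = "\r")
  order(-scores, keys)
}

dedupe_modules <- function(members, scores) {
  keys <- vapply(members, paste, "", collapse = "\r")
  keep <- !duplicated(keys)
  list(members = members[keep], scores = scores[keep])
}

# Fixed-point merge of modules sharing >= min_common features (steps 1/3)
# or exactly one feature under the size and score conditions (step 2).
merge_fixed_point <- function(members, scores, table, step,
                              params = NULL, log = character()) {
  repeat {
    if (length(members) < 2L) break
    o <- module_order(members, scores)
    members <- members[o]
    scores <- scores[o]
    merged <- FALSE
    for (i in seq_len(length(members) - 1L)) {
      for (j in (i + 1L):length(members)) {
        common <- length(intersect(members[[i]], members[[j]]))
        ok <- if (step == "two_common") common >= 2L
        else common == 1L &&
          length(members[[i]]) <= params$single_join_max_size &&
          length(members[[j]]) <= params$single_join_max_size &&
          (if (isTRUE(params$single_join_require_both))
            scores[i] >= params$strong_module_score &&
            scores[j] >= params$strong_module_score
           else scores[i] >= params$strong_module_score ||
            scores[j] >= params$strong_module_score)
        if (ok) {
          u <- sort(union(members[[i]], members[[j]]))
          log <- c(log, sprintf("%s: {%s} + {%s} -> {%s}", step,
                                paste(members[[i]], collapse = ","),
                                paste(members[[j]], collapse = ","),
                                paste(u, collapse = ",")))
          members[[i]] <- u
          scores[i] <- module_score(table, u)
          members <- members[-j]
          scores <- scores[-j]
          d <- dedupe_modules(members, scores)
          members <- d$members
          scores <- d$scores
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  list(members = members, scores = scores, log = log)
}

#' Combine and trim three-feature cliques into network modules
#'
#' Applies the five join/trim steps, in order, each run to fixed point
#' before the next begins:
#' 1. modules sharing two features are combined;
#' 2. modules sharing exactly one feature are combined if both are at most
#'    `single_join_max_size` features and both module scores are at least
#'    `strong_module_score` (default 0.66, a strong association);
#' 3. modules sharing two features are combined again;
#' 4. features of the remaining three-feature modules are removed if already
#'    present in a strictly larger module (the trimmed module is discarded
#'    once it falls under 3 members);
#' 5. if enabled, the remaining small modules sharing a feature are joined
#'    while their combined size stays within `small_join_max_size`.
#'
#' Module scores are recomputed after every merge. Merging scans modules in
#' a fixed order (descending score, then lexicographic members), so the
#' result is deterministic.
#'
#' @param triplets List of character vectors (3-feature cliques), e.g. from
#'   [best_triplet()].
#' @param params An [inference_params()].
#' @param table The `score_table` the cliques were built from.
#' @return An object of class `module_set`.
#' @export
merge_modules <- function(triplets, params, table) {
  d <- dedupe_modules(lapply(triplets, sort), rep(NA_real_, length(triplets)))
  members <- d$members
  scores <- vapply(members, function(m) module_score(table, m), 0)
  if (is.null(params$single_join_require_both))
    params$single_join_require_both <- TRUE
  log <- character()

  st1 <- merge_fixed_point(members, scores, table, "two_common", params, log)
  st2 <- merge_fixed_point(st1$members, st1$scores, table, "one_common",
                           params, st1$log)
  st3 <- merge_fixed_point(st2$members, st2$scores, table, "two_common",
                           params, st2$log)
  members <- st3$members
  scores <- st3$scores
  log <- st3$log

  # step 4: trim leftover three-feature modules
  sizes <- lengths(members)
  small_idx <- which(sizes == 3L)
  if (length(small_idx)) {
    drop_feature <- vector("list", length(members))
    for (i in small_idx) {
      for (f in members[[i]]) {
        in_larger <- any(sizes > 3L &
                           vapply(members, function(m) f %in% m, TRUE))
        if (in_larger)
          drop_feature[[i]] <- c(drop_feature[[i]], f)
      }
    }
    for (i in small_idx) {
      if (length(drop_feature[[i]])) {
        log <- c(log, sprintf("trim: removed {%s} from {%s}",
                              paste(drop_feature[[i]], collapse = ","),
                              paste(members[[i]], collapse = ",")))
        members[[i]] <- setdiff(members[[i]], drop_feature[[i]])
      }
    }
    keep <- lengths(members) >= 3L
    members <- members[keep]
    scores <- scores[keep]
    d <- dedupe_modules(members, scores)
    members <- d$members
    scores <- d$scores
    scores <- vapply(members, function(m) module_score(table, m), 0)
  }

  # step 5: join remaining small modules sharing a feature
  if (params$small_join_enabled && length(members) > 1L) {
    is_small <- lengths(members) == 3L
    pool_m <- members[is_small]
    pool_s <- scores[is_small]
    repeat {
      if (length(pool_m) < 2L) break
      o <- module_order(pool_m, pool_s)
      pool_m <- pool_m[o]
      pool_s <- pool_s[o]
      merged <- FALSE
      for (i in seq_len(length(pool_m) - 1L)) {
        for (j in (i + 1L):length(pool_m)) {
          u <- sort(union(pool_m[[i]], pool_m[[j]]))
          if (length(intersect(pool_m[[i]], pool_m[[j]])) >= 1L &&
              length(u) <= params$small_join_max_size) {
            log <- c(log, sprintf("small_join: {%s} + {%s}",
                                  paste(pool_m[[i]], collapse = ","),
                                  paste(pool_m[[j]], collapse = ",")))
            pool_m[[i]] <- u
            pool_s[i] <- module_score(table, u)
            pool_m <- pool_m[-j]
            pool_s <- pool_s[-j]
            d <- dedupe_modules(pool_m, pool_s)
            pool_m <- d$members
            pool_s <- d$scores
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
    members <- c(members[!is_small], pool_m)
    scores <- c(scores[!is_small], pool_s)
    d <- dedupe_modules(members, scores)
    members <- d$members
    scores <- d$scores
  }

  o <- module_order(members, scores)
  module_set(members[o], scores[o], layer_tag = table$layer_tag,
             params = params, provenance = log)
}

#' Construct a module set
#'
#' @param members List of character vectors of member feature ids.
#' @param scores Numeric module scores (mean pairwise symmetrized combined
#'   score).
#' @param layer_tag Omics-layer label.
#' @param params The [inference_params()] used, if any.
#' @param provenance Character log of merge events.
#' @return An object of class `module_set`.
#' @export
module_set <- function(members, scores, layer_tag = "layer", params = NULL,
                       provenance = character()) {
  members <- lapply(members, function(m) sort(as.character(m)))
  keys <- vapply(members, paste, "", collapse = "\r")
  if (anyDuplicated(keys)) stop("duplicate modules with identical members")
  ids <- if (length(members)) paste0("M", seq_along(members)) else character()
  names(members) <- ids
  structure(
    list(modules = members,
         scores = stats::setNames(as.numeric(scores), ids),
         layer_tag = layer_tag,
         params = params,
         provenance = provenance),
    class = "module_set"
  )
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> layer '%s': %d modules (sizes %s)\n",
              x$layer_tag, length(x$modules),
              if (length(x$modules))
                paste(range(lengths(x$modules)), collapse = "-") else "-"))
  invisible(x)
}

#' @export
length.module_set <- function(x) length(x$modules)

#' @export
as.data.frame.module_set <- function(x, ...) {
  if (!length(x$modules))
    return(data.frame(module_id = character(), feature = character(),
                      module_score = numeric()))
  data.frame(
    module_id = rep(names(x$modules), lengths(x$modules)),
    feature = unlist(x$modules, use.names = FALSE),
    module_score = rep(unname(x$scores), lengths(x$modules))
  )
}

#' Infer network modules from an expression matrix
#'
#' End-to-end module inference: score all pairs, derive the combined-score
#' cut-off from `C` and `S`, apply the discrepancy filter, find each
#' feature's maximally scoring three-feature clique, and combine/trim the
#' cliques with the five merge steps. Deterministic given the matrix and
#' parameters. A feature may end up in more than one module.
#'
#' @param matrix An [expression_matrix()].
#' @param params An [inference_params()].
#' @param table Optional precomputed `score_table` for `matrix` (e.g. when
#'   sweeping `C`/`S` without re-scoring); must come from the same matrix
#'   and scoring switches.
#' @return A `module_set`; the retained pair set and threshold are attached
#'   as attributes `pairs` and `threshold`.
#' @examples
#' sim <- simulate_dataset(n_noise_features = 20, seed = 1)
#' mods <- infer_modules(sim$matrix, inference_params(S = 10))
#' mods
#' @export
infer_modules <- function(matrix, params = inference_params(),
                          table = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  params <- resolve_params(params, nrow(matrix$values))
  if (is.null(table)) table <- score_all_pairs(matrix, params)
  stopifnot(inherits(table, "score_table"))
  threshold <- find_cutoff(table, params$C, params$S)
  pairs <- discrepancy_filter(table, threshold, params$discrepancy_count)
  g <- pairs_to_graph(pairs)
  triplets <- list()
  for (f in seq_along(g$ids)) {
    tri <- best_triplet_idx(f, g$adj, g$w, g$ids)
    if (!is.null(tri)) triplets[[length(triplets) + 1L]] <- tri
  }
  out <- merge_modules(triplets, params, table)
  attr(out, "pairs") <- pairs
  attr(out, "threshold") <- threshold
  out
}
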