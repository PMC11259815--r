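#' Annotation relations for module and pathway validation
#'
#' Holds either pairwise relations (e.g. protein-protein interactions, with
#' an optional weight per relation) or group memberships (e.g. kinase ->
#' substrate sites, transcription factor -> target genes, reaction ->
#' metabolites, pathway -> members). Duplicate relations are collapsed.
#'
#' @param pairs Data frame with columns `a`, `b` (feature ids) and
#'   optionally `weight`, or `NULL`.
#' @param groups Named list of character vectors (group id -> feature set),
#'   or `NULL`. Exactly one of `pairs`/`groups` must be given.
#' @return An object of class `annotation_relations`.
#' @export
annotation_relations <- function(pairs = NULL, groups = NULL) {
  if (is.null(pairs) == is.null(groups))
    stop("supply exactly one of `pairs` or `groups`")
  if (!is.null(pairs)) {
    stopifnot(is.data.frame(pairs), all(c("a", "b") %in% names(pairs)))
    a <- as.character(pairs$a)
    b <- as.character(pairs$b)
    w <- if ("weight" %in% names(pairs)) as.numeric(pairs$weight)
    else rep(1, nrow(pairs))
    keep <- a != b
    a <- a[keep]; b <- b[keep]; w <- w[keep]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "\r")
    first <- !duplicated(key)
    if (!length(lo)) stop("empty annotation set")
    structure(list(type = "pairs",
                   pairs = data.frame(a = lo[first], b = hi[first],
                                      weight = w[first]),
                   groups = NULL),
              class = "annotation_relations")
  } else {
    stopifnot(is.list(groups), !is.null(names(groups)))
    groups <- lapply(groups, function(g) sort(unique(as.character(g))))
    groups <- groups[lengths(groups) > 0L]
    if (!length(groups)) stop("empty annotation set")
    structure(list(type = "groups", pairs = NULL, groups = groups),
              class = "annotation_relations")
  }
}

#' @export
print.annotation_relations <- function(x, ...) {
  if (x$type == "pairs")
    cat(sprintf("<annotation_relations> %d pairwise relations\n",
                nrow(x$pairs)))
  else
    cat(sprintf("<annotation_relations> %d groups (median size %d)\n",
                length(x$groups),
                as.integer(stats::median(lengths(x$groups)))))
  invisible(x)
}

# Unordered pair form of an annotation set: for group relations, all
# within-group pairs, each unique pair counted once (shares >= 1 group).
annotation_pairs <- function(ann) {
  stopifnot(inherits(ann, "annotation_relations"))
  if (ann$type == "pairs") return(ann$pairs)
  as_ <- character(); bs <- character()
  for (g in ann$groups) {
    k <- length(g)
    if (k < 2L) next
    cmb <- utils::combn(g, 2L)
    as_ <- c(as_, cmb[1L, ])
    bs <- c(bs, cmb[2L, ])
  }
  if (!length(as_)) return(data.frame(a = character(), b = character(),
                                      weight = numeric()))
  lo <- pmin(as_, bs)
  hi <- pmax(as_, bs)
  key <- paste(lo, hi, sep = "\r")
  first <- !duplicated(key)
  data.frame(a = lo[first], b = hi[first], weight = 1)
}

# Member lists from module_set / pathway_set / plain list input.
member_lists <- function(x) {
  if (inherits(x, "module_set")) x$modules
  else if (is.list(x)) lapply(x, as.character)
  else stop("expected a module_set or a list of feature-id vectors")
}

#' Validation score of a module set against annotation relations
#'
#' The sum, over modules, of annotated relations recovered inside a module:
#' for pairwise relations, the number of annotated pairs with both
#' endpoints in the same module; for group relations, the number of
#' within-module feature pairs sharing at least one annotation group. A
#' pair recovered in several modules counts once per module. With
#' `weighted = TRUE` the relation weights are summed instead of counts
#' (e.g. interaction confidence scores).
#'
#' @param modules A `module_set` or list of feature-id vectors.
#' @param ann An [annotation_relations()].
#' @param weighted Sum relation weights instead of counting.
#' @return Non-negative score (an integer count unless `weighted`).
#' @export
module_validation_score <- function(modules, ann, weighted = FALSE) {
  mem <- member_lists(modules)
  ap <- annotation_pairs(ann)
  score_membership(mem, ap, weighted)
}

# Core counting kernel: modules x features membership matrix, vectorized
# over annotation pairs.
score_membership <- function(mem, ap, weighted = FALSE) {
  if (!length(mem) || !nrow(ap)) return(0)
  feats <- unique(unlist(mem, use.names = FALSE))
  keep <- ap$a %in% feats & ap$b %in% feats
  if (!any(keep)) return(0)
  ap <- ap[keep, , drop = FALSE]
  A <- matrix(FALSE, length(mem), length(feats),
              dimnames = list(NULL, feats))
  for (i in seq_along(mem)) A[i, mem[[i]]] <- TRUE
  hits <- colSums(A[, ap$a, drop = FALSE] & A[, ap$b, drop = FALSE])
  if (weighted) sum(hits * ap$weight) else sum(hits)
}

#' Validation score of a pathway set against pathway annotations
#'
#' Counts, over inferred pathways, the feature pairs that sit in two
#' *different* member modules of the same pathway and are co-annotated to
#' the same reference pathway group. Pairs co-occurring only within a single
#' module do not count; each qualifying feature pair counts once per
#' inferred pathway.
#'
#' @param pathways A `pathway_set`, or a list of pathways where each
#'   pathway is a list of member-module feature-id vectors.
#' @param pathway_ann Group-type [annotation_relations()] (pathway id ->
#'   member features).
#' @return Non-negative integer score.
#' @export
pathway_validation_score <- function(pathways, pathway_ann) {
  stopifnot(inherits(pathway_ann, "annotation_relations"),
            pathway_ann$type == "groups")
  ap <- annotation_pairs(pathway_ann)
  pws <- pathway_member_lists(pathways)
  total <- 0L
  for (pw in pws) {
    if (length(pw) < 2L) next
    feats <- unique(unlist(pw, use.names = FALSE))
    keep <- ap$a %in% feats & ap$b %in% feats
    if (!any(keep)) next
    sub <- ap[keep, , drop = FALSE]
    B <- matrix(FALSE, length(pw), length(feats),
                dimnames = list(NULL, feats))
    for (i in seq_along(pw)) B[i, intersect(pw[[i]], feats)] <- TRUE
    nf <- colSums(B)
    shared <- colSums(B[, sub$a, drop = FALSE] & B[, sub$b, drop = FALSE])
    # ordered module pairs (M1, M2), M1 != M2, with a in M1 and b in M2
    cross <- nf[sub$a] * nf[sub$b] - shared
    total <- total + sum(cross > 0L)
  }
  total
}

# Pathways as lists of member-module feature sets.
pathway_member_lists <- function(x) {
  if (inherits(x, "pathway_set"))
    lapply(names(x$pathways), function(p) pathway_unit_features(x, p))
  else if (is.list(x)) x
  else stop("expected a pathway_set or a list of module lists")
}

#' Size-preserving randomized null scores
#'
#' Generates the empirical null of the validation score. In `full` mode,
#' each round redraws random modules of the observed sizes from the feature
#' universe and rescores them: features are drawn without replacement
#' across the whole round when the observed modules are disjoint, and
#' module-by-module (without replacement within a module) when the observed
#' modules overlap, mirroring the observed overlap structure. For pathway
#' sets the module-to-pathway grouping is kept while member features are
#' redrawn. In `connections_only` mode (pathway sets only) the observed
#' modules are kept intact and only their assignment to pathways is
#' permuted.
#'
#' @param x A `module_set`, list of feature-id vectors, or `pathway_set`.
#' @param ann An [annotation_relations()] (pathway annotations for
#'   pathway sets).
#' @param universe Character vector of all candidate feature ids; must
#'   cover the observed module features.
#' @param rounds Number of null rounds (default 1000).
#' @param seed Optional integer seed.
#' @param mode `"full"` or `"connections_only"`.
#' @param weighted Passed on to [module_validation_score()].
#' @return Numeric vector of `rounds` null scores.
#' @export
randomized_null <- function(x, ann, universe, rounds = 1000L, seed = NULL,
                            mode = c("full", "connections_only"),
                            weighted = FALSE) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  universe <- unique(as.character(universe))

  if (inherits(x, "pathway_set") || (is.list(x) && length(x) &&
                                     is.list(x[[1L]]) && !is.data.frame(x[[1L]]) &&
                                     !inherits(x, "module_set"))) {
    pws <- pathway_member_lists(x)
    all_mods <- unlist(pws, recursive = FALSE, use.names = FALSE)
    sizes <- lengths(all_mods)
    n_per_pw <- lengths(pws)
    if (mode == "connections_only") {
      return(vapply(seq_len(rounds), function(r) {
        perm <- sample(all_mods)
        rand <- split_by_counts(perm, n_per_pw)
        as.numeric(pathway_validation_score(rand, ann))
      }, 0))
    }
    check_universe(all_mods, universe)
    disjoint <- sum(sizes) == length(unique(unlist(all_mods)))
    return(vapply(seq_len(rounds), function(r) {
      mods <- draw_modules(sizes, universe, disjoint)
      rand <- split_by_counts(mods, n_per_pw)
      as.numeric(pathway_validation_score(rand, ann))
    }, 0))
  }

  mem <- member_lists(x)
  if (mode == "connections_only")
    stop("connections_only mode applies to pathway sets")
  check_universe(mem, universe)
  sizes <- lengths(mem)
  disjoint <- sum(sizes) == length(unique(unlist(mem)))
  vapply(seq_len(rounds), function(r) {
    rand <- draw_modules(sizes, universe, disjoint)
    as.numeric(score_membership(rand, annotation_pairs(ann), weighted))
  }, 0)
}

check_universe <- function(mem, universe) {
  missing <- setdiff(unique(unlist(mem)), universe)
  if (length(missing))
    stop("universe does not cover module features: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  if (max(lengths(mem)) > length(universe))
    stop("module size exceeds the universe")
}

draw_modules <- function(sizes, universe, disjoint) {
  if (disjoint) {
    if (sum(sizes) > length(universe))
      stop("total module size exceeds the universe")
    drawn <- sample(universe, sum(sizes))
    split_by_counts(drawn, sizes)
  } else {
    lapply(sizes, function(k) sample(universe, k))
  }
}

split_by_counts <- function(x, counts) {
  ends <- cumsum(counts)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(counts), function(i)
    x[seq.int(starts[i], ends[i])])
}

#' Empirical p-value from an Epanechnikov-kernel null density
#'
#' Fits an Epanechnikov kernel density (bandwidth by Silverman's rule of
#' thumb) to the randomized null scores and reads the upper-tail p-value
#' `1 - CDF(observed)` off the empirical cumulative distribution — the
#' probability of recovering at least as many annotated relations by
#' chance. Also reports the relative distance of the observed score from
#' the null median, `(observed - median) / median`.
#'
#' If all null scores are identical the kernel fit is skipped and the
#' p-value is computed from the degenerate point mass (with a warning).
#'
#' @param observed Observed validation score.
#' @param null_scores Numeric vector of null scores (length >= 2).
#' @return An object of class `validation_result` with fields `observed`,
#'   `null_scores`, `p_value`, `relative_distance`, `kde_bandwidth`.
#' @export
empirical_p <- function(observed, null_scores) {
  stopifnot(length(null_scores) >= 2L)
  med <- stats::median(null_scores)
  rel <- if (med == 0) {
    warning("null median is zero; relative distance undefined")
    NA_real_
  } else (observed - med) / med

  if (stats::sd(null_scores) == 0) {
    warning("degenerate null (all scores identical); ",
            "p-value from point mass")
    p <- if (observed > null_scores[1L]) 0 else 1
    bw <- NA_real_
  } else {
    d <- stats::density(null_scores, kernel = "epanechnikov", bw = "nrd0",
                        n = 4096L)
    bw <- d$bw
    cdf <- c(0, cumsum((d$y[-1L] + d$y[-length(d$y)]) / 2 * diff(d$x)))
    cdf <- cdf / cdf[length(cdf)]
    p <- 1 - stats::approx(d$x, cdf, xout = observed, rule = 2L)$y
    p <- min(max(p, 0), 1)
  }
  structure(
    list(observed = observed,
         null_scores = null_scores,
         p_value = p,
         relative_distance = rel,
         kde_bandwidth = bw),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf(paste0("<validation_result> observed %.6g, null median %.6g ",
                     "(%d rounds)\n  p = %.4g, relative distance = %.3f\n"),
              x$observed, stats::median(x$null_scores),
              length(x$null_scores), x$p_value, x$relative_distance))
  invisible(x)
}

#' Validate modules or pathways against annotation relations
#'
#' Convenience wrapper: computes the observed validation score
#' ([module_validation_score()] or [pathway_validation_score()]), draws the
#' size-preserving randomized null ([randomized_null()]) and derives the
#' Epanechnikov-kernel empirical p-value and relative distance
#' ([empirical_p()]).
#'
#' @inheritParams randomized_null
#' @return A `validation_result`.
#' @export
validate_against_annotations <- function(x, ann, universe, rounds = 1000L,
                                         seed = NULL,
                                         mode = c("full", "connections_only"),
                                         weighted = FALSE) {
  mode <- match.arg(mode)
  observed <- if (inherits(x, "pathway_set"))
    pathway_validation_score(x, ann)
  else module_validation_score(x, ann, weighted)
  nulls <- randomized_null(x, ann, universe, rounds = rounds, seed = seed,
                           mode = mode, weighted = weighted)
  empirical_p(observed, nulls)
}

#' Conservation of modules or pathways in an independent dataset
#'
#' Recomputes the rank-adjusted association scores in a dataset different
#' from the one used for inference and returns the median score over all
#' intra-module pairs (for pathway sets: over intra-pathway module-profile
#' pairs). A median above 0.5 — the median expected if scores were randomly
#' assigned — indicates conserved structure. Modules with features absent
#' from the independent dataset are skipped (reported via message).
#'
#' @param x A `module_set` (or list of feature-id vectors) or `pathway_set`.
#' @param data The independent data: an [expression_matrix()] or an
#'   already-computed `score_table`. For a `pathway_set`, a list of
#'   expression matrices named by layer tag.
#' @param score_kind Which adjusted score to take the median of:
#'   `"correlation"`, `"stoichiometry"` or `"combined"`.
#' @param params Scoring switches used when `data` is an expression matrix.
#' @return Median score over the evaluated pairs.
#' @export
conservation <- function(x, data,
                         score_kind = c("combined", "correlation",
                                        "stoichiometry"),
                         params = inference_params()) {
  score_kind <- match.arg(score_kind)

  if (inherits(x, "pathway_set")) {
    if (inherits(data, "expression_matrix")) data <- list(data)
    stopifnot(is.list(data))
    tags <- vapply(data, function(m) m$layer_tag, "")
    units <- names(x$unit_features)
    profs <- matrix(NA_real_, 0L, 0L)
    rows <- list()
    for (u in units) {
      tag <- sub(":.*$", "", u)
      m <- if (!is.null(names(data)) && tag %in% names(data))
        data[[tag]] else data[[match(tag, tags)]]
      if (is.null(m) || anyNA(match(x$unit_features[[u]], m$feature_ids))) {
        message("skipping unit with absent features: ", u)
        next
      }
      rows[[u]] <- module_expression(x$unit_features[[u]], m)
    }
    if (length(rows) < 3L)
      stop("fewer than 3 module units evaluable in the independent data")
    profs <- do.call(rbind, rows)
    params$use_absolute_correlation <- TRUE
    st <- score_all_pairs(expression_matrix(profs, layer_tag = "modules"),
                          params)
    groups <- lapply(x$pathways, intersect, rownames(profs))
    groups <- groups[lengths(groups) >= 2L]
    if (!length(groups)) stop("no evaluable pathway in the independent data")
    return(median_group_score(st, groups, score_kind))
  }

  st <- if (inherits(data, "score_table")) data
  else score_all_pairs(data, params)
  mem <- member_lists(x)
  present <- vapply(mem, function(m) !anyNA(match(m, st$feature_ids)), TRUE)
  if (any(!present))
    message(sum(!present), " module(s) skipped: features absent from the ",
            "independent dataset")
  mem <- mem[present]
  if (!length(mem)) stop("no overlapping features with independent dataset")
  median_group_score(st, mem, score_kind)
}

# Pooled median of symmetrized adjusted scores over all within-group pairs.
median_group_score <- function(st, groups, score_kind) {
  m <- switch(score_kind,
              combined = st$combined,
              correlation = st$adj_corr,
              stoichiometry = st$adj_stoi)
  sym <- (m + t(m)) / 2
  vals <- numeric()
  for (g in groups) {
    idx <- match(g, st$feature_ids)
    sub <- sym[idx, idx, drop = FALSE]
    vals <- c(vals, sub[upper.tri(sub)])
  }
  stats::median(vals, na.rm = TRUE)
}
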