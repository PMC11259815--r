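#' Per-sample expression profile of a module
#'
#' The sample-wise median of all member-feature values; these medians serve
#' as the module's expression values at the pathway-combination stage.
#'
#' @param module Character vector of member feature ids (or one element of a
#'   `module_set`).
#' @param matrix The [expression_matrix()] of the module's layer.
#' @return Named numeric vector, one value per sample.
#' @examples
#' m <- expression_matrix(rbind(a = c(1, 1, 1), b = c(2, 2, 2),
#'                              c = c(9, 9, 9)))
#' module_expression(c("a", "b", "c"), m)
#' @export
module_expression <- function(module, matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  idx <- match(module, matrix$feature_ids)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("no module feature is present in the matrix")
  apply(matrix$values[idx, , drop = FALSE], 2L, stats::median)
}

# Normalize one pathway-inference input to a common "unit layer" form:
# named member-feature sets + a unit-by-sample profile matrix.
as_unit_layer <- function(x, matrix = NULL) {
  if (inherits(x, "module_set")) {
    if (is.null(matrix))
      stop("an expression matrix is required for a module_set input")
    stopifnot(inherits(matrix, "expression_matrix"))
    if (!length(x$modules)) stop("empty module set")
    profiles <- t(vapply(x$modules, module_expression, matrix = matrix,
                         numeric(ncol(matrix$values))))
    rownames(profiles) <- paste0(x$layer_tag, ":", names(x$modules))
    groups <- x$modules
    names(groups) <- rownames(profiles)
    list(groups = groups, profiles = profiles,
         layer_tag = x$layer_tag, sample_ids = matrix$sample_ids,
         zero_fraction = mean(matrix$values == 0),
         weighted = if (!is.null(x$params))
           x$params$weighted_stoichiometry else FALSE)
  } else if (inherits(x, "pathway_set")) {
    # closure: each pathway becomes a unit whose profile is the sample-wise
    # median of its member-unit profiles
    if (!length(x$pathways)) stop("empty pathway set")
    profiles <- t(vapply(x$pathways, function(u)
      apply(x$unit_profiles[u, , drop = FALSE], 2L, stats::median),
      numeric(ncol(x$unit_profiles))))
    rownames(profiles) <- paste0(x$layer_tag, ":", names(x$pathways))
    groups <- lapply(x$pathways, function(u)
      sort(unique(unlist(x$unit_features[u], use.names = FALSE))))
    names(groups) <- rownames(profiles)
    list(groups = groups, profiles = profiles,
         layer_tag = x$layer_tag, sample_ids = colnames(x$unit_profiles),
         zero_fraction = mean(x$unit_profiles == 0),
         weighted = FALSE)
  } else {
    stop("inputs must be module_set (with matrix) or pathway_set objects")
  }
}

#' Combine network modules into pathways
#'
#' Reruns the module-inference machinery with modules as the features:
#' every module is represented by its sample-wise median expression profile
#' ([module_expression()]), profiles from all layers are stacked into one
#' unit-by-sample matrix, and scoring, cut-off, discrepancy filtering,
#' clique search and merging proceed exactly as for features. The absolute
#' value of the Spearman correlation is used so that upregulated and
#' downregulated modules combine equally (override with
#' `absolute_correlation = FALSE`).
#'
#' All layers must share an identical ordered sample set; multi-omics data
#' acquired from different samples cannot be combined.
#'
#' The function also accepts `pathway_set` inputs, enabling recursive
#' combination of pathways into super-pathways.
#'
#' @param module_sets A `module_set` or `pathway_set`, or a list of them
#'   (one per omics layer).
#' @param matrices The matching [expression_matrix()] per `module_set`
#'   input (a single matrix or a list; ignored for `pathway_set` inputs).
#' @param params An [inference_params()]; defaults to `C = 1` with `S` equal
#'   to the number of modules (all modules assumed associable). The
#'   zero-inflated stoichiometry switch defaults to that of the layer with
#'   the most zero entries.
#' @param absolute_correlation Use `|rho|` (default `TRUE`).
#' @return An object of class `pathway_set`.
#' @export
infer_pathways <- function(module_sets, matrices = NULL,
                           params = NULL, absolute_correlation = TRUE) {
  if (inherits(module_sets, "module_set") ||
      inherits(module_sets, "pathway_set"))
    module_sets <- list(module_sets)
  if (inherits(matrices, "expression_matrix")) matrices <- list(matrices)
  layers <- lapply(seq_along(module_sets), function(i)
    as_unit_layer(module_sets[[i]],
                  if (!is.null(matrices) && i <= length(matrices))
                    matrices[[i]] else NULL))

  samples <- layers[[1L]]$sample_ids
  for (ly in layers)
    if (!identical(ly$sample_ids, samples))
      stop("omics layers acquired from different samples cannot be ",
           "combined into pathways (sample sets must be identical)")

  profiles <- do.call(rbind, lapply(layers, `[[`, "profiles"))
  groups <- do.call(c, lapply(layers, `[[`, "groups"))
  if (anyDuplicated(rownames(profiles)))
    stop("duplicate layer:module unit identifiers across inputs")
  if (nrow(profiles) < 3L)
    stop("pathway inference requires at least 3 modules in total")

  if (is.null(params)) {
    zf <- vapply(layers, `[[`, 0, "zero_fraction")
    params <- inference_params(
      C = 1L, S = NULL,
      weighted_stoichiometry = layers[[which.max(zf)]]$weighted)
  }
  params$use_absolute_correlation <- isTRUE(absolute_correlation)

  unit_matrix <- expression_matrix(profiles, layer_tag = "modules",
                                   missing_as_zero = FALSE)
  mods <- infer_modules(unit_matrix, params)

  pathways <- mods$modules
  names(pathways) <- if (length(pathways))
    paste0("P", seq_along(pathways)) else character()
  structure(
    list(pathways = pathways,
         scores = stats::setNames(unname(mods$scores), names(pathways)),
         unit_features = groups,
         unit_profiles = profiles,
         layer_tag = "pathways",
         params = params),
    class = "pathway_set"
  )
}

#' @export
print.pathway_set <- function(x, ...) {
  cat(sprintf("<pathway_set> %d pathways over %d module units\n",
              length(x$pathways), nrow(x$unit_profiles)))
  invisible(x)
}

#' @export
length.pathway_set <- function(x) length(x$pathways)

#' @export
as.data.frame.pathway_set <- function(x, ...) {
  if (!length(x$pathways))
    return(data.frame(pathway_id = character(), layer_tag = character(),
                      module_id = character(), pathway_score = numeric()))
  units <- unlist(x$pathways, use.names = FALSE)
  parts <- strsplit(units, ":", fixed = TRUE)
  data.frame(
    pathway_id = rep(names(x$pathways), lengths(x$pathways)),
    layer_tag = vapply(parts, `[`, "", 1L),
    module_id = vapply(parts, function(p) paste(p[-1L], collapse = ":"), ""),
    pathway_score = rep(unname(x$scores), lengths(x$pathways))
  )
}

# Member-feature sets of each pathway's units, named by unit id.
pathway_unit_features <- function(pset, pathway_id) {
  pset$unit_features[pset$pathways[[pathway_id]]]
}
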