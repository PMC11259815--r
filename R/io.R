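#' Read pairwise annotation relations from TSV
#'
#' Two columns (feature id, feature id) with an optional third weight
#' column; a header line is detected automatically when the third column
#' of the first line is non-numeric. Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return A pairwise [annotation_relations()] object.
#' @export
read_pairwise_relations <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected at least two tab-separated columns")
  # drop a header row if the weight column fails to parse there
  if (ncol(df) >= 3L &&
      is.na(suppressWarnings(as.numeric(df[1L, 3L]))))
    df <- df[-1L, , drop = FALSE]
  pairs <- data.frame(a = as.character(df[[1L]]), b = as.character(df[[2L]]))
  if (ncol(df) >= 3L) pairs$weight <- as.numeric(df[[3L]])
  annotation_relations(pairs = pairs)
}

#' Write pairwise annotation relations as TSV
#'
#' @param ann A pairwise [annotation_relations()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pairwise_relations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_relations"), ann$type == "pairs")
  utils::write.table(ann$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read set-valued relations from a GMT file
#'
#' Standard GMT: one group per line, tab-separated — group name,
#' description, then member ids.
#'
#' @param path File path.
#' @return A group-type [annotation_relations()] object.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  groups <- lapply(parts, function(p) p[-(1:2)])
  names(groups) <- vapply(parts, `[`, "", 1L)
  annotation_relations(groups = groups)
}

#' Write groups as a GMT file
#'
#' @param groups Named list of member-id vectors, or a group-type
#'   [annotation_relations()], or a `module_set`.
#' @param path Output file path.
#' @param description Description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(groups, path, description = "") {
  if (inherits(groups, "annotation_relations")) {
    stopifnot(groups$type == "groups")
    groups <- groups$groups
  } else if (inherits(groups, "module_set")) {
    groups <- groups$modules
  }
  lines <- vapply(seq_along(groups), function(i)
    paste(c(names(groups)[i], description, groups[[i]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a module set as TSV
#'
#' Long format: `module_id`, `feature`, `module_score`.
#'
#' @param modules A `module_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path) {
  stopifnot(inherits(modules, "module_set"))
  utils::write.table(as.data.frame(modules), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write final intra-module edges as SIF
#'
#' One line per retained intra-module edge in simple interaction format
#' (`source  assoc  target`), for loading into network viewers.
#'
#' @param modules A `module_set` from [infer_modules()] (its retained pair
#'   set is read from the `pairs` attribute unless given explicitly).
#' @param path Output file path.
#' @param pairs Optional retained pair set from [discrepancy_filter()].
#' @return `path`, invisibly.
#' @export
write_sif <- function(modules, path, pairs = attr(modules, "pairs")) {
  stopifnot(inherits(modules, "module_set"))
  if (is.null(pairs)) stop("no retained pair set available")
  lines <- character()
  for (m in modules$modules) {
    keep <- pairs$a %in% m & pairs$b %in% m
    if (any(keep))
      lines <- c(lines, paste(pairs$a[keep], "assoc", pairs$b[keep],
                              sep = "\t"))
  }
  writeLines(unique(lines), path)
  invisible(path)
}

#' Write a pathway set as TSV (plus optional flattened GMT)
#'
#' Long format: `pathway_id`, `layer_tag`, `module_id`, `pathway_score`.
#'
#' @param pathways A `pathway_set`.
#' @param path Output TSV path.
#' @param gmt_path Optional path for a GMT of each pathway's flattened
#'   feature set.
#' @return `path`, invisibly.
#' @export
write_pathways <- function(pathways, path, gmt_path = NULL) {
  stopifnot(inherits(pathways, "pathway_set"))
  utils::write.table(as.data.frame(pathways), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(gmt_path)) {
    flat <- lapply(names(pathways$pathways), function(p)
      sort(unique(unlist(pathway_unit_features(pathways, p)))))
    names(flat) <- names(pathways$pathways)
    write_gmt(flat, gmt_path)
  }
  invisible(path)
}

#' Write a validation result as TSV
#'
#' @param result A `validation_result` from [empirical_p()] or
#'   [validate_against_annotations()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_validation_result <- function(result, path) {
  stopifnot(inherits(result, "validation_result"))
  df <- data.frame(
    observed = result$observed,
    null_median = stats::median(result$null_scores),
    null_rounds = length(result$null_scores),
    p_value = result$p_value,
    relative_distance = result$relative_distance,
    kde_bandwidth = result$kde_bandwidth
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records the subcommand, parameters, seed, package version and MD5
#' checksums of the input files alongside the outputs of a run, so any
#' result can be traced back to its exact inputs.
#'
#' @param path Output JSON path.
#' @param subcommand Name of the executed step.
#' @param params A list of parameters (e.g. an [inference_params()]).
#' @param inputs Character vector of input file paths.
#' @param seed Seed used, if any.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, subcommand, params = list(),
                               inputs = character(), seed = NULL) {
  manifest <- list(
    subcommand = subcommand,
    package_version = as.character(utils::packageVersion("stoichnet")),
    r_version = as.character(getRversion()),
    seed = seed,
    params = unclass(params),
    inputs = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
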