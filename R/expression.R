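#' Construct an expression matrix for one omics layer
#'
#' The basic data container of the package: a feature-by-sample matrix of
#' abundance or expression values for a single omics layer (transcriptome,
#' proteome, phosphoproteome, ...). Rows are features, columns are samples.
#'
#' Values are expected to be preprocessed (normalized, batch-corrected)
#' abundances. Zeros may encode genuine absence or missingness; the
#' `missing_as_zero` flag records which interpretation applies, and the
#' zero-inflated (weighted) stoichiometry variant should be used when many
#' zeros encode missingness (see [score_all_pairs()]).
#'
#' @param values Numeric matrix, features in rows, samples in columns. All
#'   values must be finite. Negative values trigger a warning (abundance data
#'   is non-negative; simulated data may stray below zero and is handled by
#'   the scoring eligibility rules).
#' @param feature_ids,sample_ids Unique identifiers; default to the
#'   dimnames of `values`.
#' @param layer_tag Free-text label for the omics layer.
#' @param missing_as_zero Logical; `TRUE` if zeros encode missing values.
#' @return An object of class `expression_matrix`.
#' @examples
#' m <- matrix(rexp(20), 4, 5,
#'             dimnames = list(paste0("f", 1:4), paste0("s", 1:5)))
#' em <- expression_matrix(m, layer_tag = "proteome")
#' dim(em)
#' @export
expression_matrix <- function(values,
                              feature_ids = rownames(values),
                              sample_ids = colnames(values),
                              layer_tag = "layer",
                              missing_as_zero = FALSE) {
  values <- as.matrix(values)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(feature_ids))
    stop("duplicate feature identifiers: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers")
  if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (nrow(values) < 3L || ncol(values) < 3L)
    stop("at least 3 features and 3 samples are required")
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("all expression values must be finite (map NA to zero on read ",
         "or filter incomplete features first)")
  if (any(values < 0))
    warning("negative expression values present; such samples are excluded ",
            "from stoichiometry ratios like zeros")
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(
    list(values = values,
         feature_ids = feature_ids,
         sample_ids = sample_ids,
         layer_tag = layer_tag,
         missing_as_zero = isTRUE(missing_as_zero)),
    class = "expression_matrix"
  )
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> layer '%s': %d features x %d samples\n",
              x$layer_tag, nrow(x$values), ncol(x$values)))
  frac0 <- mean(x$values == 0)
  if (frac0 > 0)
    cat(sprintf("  zero entries: %.1f%% (missing_as_zero = %s)\n",
                100 * frac0, x$missing_as_zero))
  invisible(x)
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row of sample identifiers and a first column of feature
#' identifiers. `NA` tokens are mapped to zero when `na_to_zero = TRUE`
#' (which also sets `missing_as_zero` on the result).
#'
#' @param path File path (TSV by default).
#' @param sep Field separator.
#' @param layer_tag Layer label stored on the result.
#' @param na_to_zero Replace missing values with zero and flag the layer as
#'   zero-inflated.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, sep = "\t", layer_tag = basename(path),
                                   na_to_zero = TRUE) {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (anyNA(m)) {
    if (!na_to_zero)
      stop("matrix contains missing values; use na_to_zero = TRUE")
    m[is.na(m)] <- 0
  }
  expression_matrix(m, layer_tag = layer_tag,
                    missing_as_zero = na_to_zero && any(m == 0))
}

#' Write an expression matrix as TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(feature = x$feature_ids, x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
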