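#' Inference parameters
#'
#' Collects every tunable of module and pathway inference in one object.
#'
#' @param C Minimum number of associations retained per feature when setting
#'   the combined-score cut-off (positive integer, default 1).
#' @param S Number of features assumed to have at least one true association.
#'   The cut-off threshold is the `S`-th largest of the per-feature `C`-th
#'   best combined scores, so exactly `S` features are guaranteed to retain
#'   at least `C` partners. `NULL` (default) means all features
#'   (most permissive); [suggest_parameters()] helps pick a value.
#' @param use_absolute_correlation Score with `|rho|` instead of signed
#'   Spearman rho, so anti-correlated features associate as strongly as
#'   correlated ones. Forced on at the pathway-combination stage.
#' @param weighted_stoichiometry Use the zero-inflated stoichiometry variant
#'   that penalizes one-zero samples and rewards both-zero samples.
#'   Recommended when more than ~30% of entries are zero-encoded missing.
#' @param stoichiometry_weight Weight `w` of the zero-inflation penalty
#'   (default 1): the base quartile-ratio score is multiplied by
#'   `(1 + w * f_one) / (1 + w * f_both)` where `f_one`/`f_both` are the
#'   fractions of samples with exactly one/both values zero.
#' @param single_join_max_size Modules sharing a single feature are merged
#'   only when both are at most this size (merge step 2; default 5).
#' @param strong_module_score Minimum module score required of both modules
#'   for the single-common-feature merge (step 2; default 0.66).
#' @param single_join_require_both If `TRUE` (default) the step-2 score
#'   condition must hold for both modules being joined; set `FALSE` to
#'   require it of only one.
#' @param small_join_enabled Whether leftover small modules sharing a feature
#'   are joined in the final merge step (step 5; default TRUE).
#' @param small_join_max_size Maximum combined size of modules joined at
#'   step 5 (default 10).
#' @param discrepancy_count Maximum allowed difference between the two
#'   directional combined scores of a pair, in units of the adjusted-score
#'   grid step `1/(n_features - 2)`. `NULL` (default) means 10% of the grid,
#'   `ceiling(0.1 * (n_features - 1))`.
#' @param seed Optional integer seed recorded with the run.
#' @return An object of class `inference_params`.
#' @export
inference_params <- function(C = 1L,
                             S = NULL,
                             use_absolute_correlation = FALSE,
                             weighted_stoichiometry = FALSE,
                             stoichiometry_weight = 1,
                             single_join_max_size = 5L,
                             strong_module_score = 0.66,
                             single_join_require_both = TRUE,
                             small_join_enabled = TRUE,
                             small_join_max_size = 10L,
                             discrepancy_count = NULL,
                             seed = NULL) {
  C <- as.integer(C)
  if (C < 1L) stop("C must be a positive integer")
  if (!is.null(S)) {
    S <- as.integer(S)
    if (S < 1L) stop("S must be a positive integer")
  }
  if (strong_module_score < 0 || strong_module_score > 1)
    stop("strong_module_score must lie in [0, 1]")
  if (stoichiometry_weight < 0) stop("stoichiometry_weight must be >= 0")
  if (!is.null(discrepancy_count)) {
    discrepancy_count <- as.integer(discrepancy_count)
    if (discrepancy_count < 0L) stop("discrepancy_count must be >= 0")
  }
  structure(
    list(C = C, S = S,
         use_absolute_correlation = isTRUE(use_absolute_correlation),
         weighted_stoichiometry = isTRUE(weighted_stoichiometry),
         stoichiometry_weight = stoichiometry_weight,
         single_join_max_size = as.integer(single_join_max_size),
         strong_module_score = strong_module_score,
         single_join_require_both = isTRUE(single_join_require_both),
         small_join_enabled = isTRUE(small_join_enabled),
         small_join_max_size = as.integer(small_join_max_size),
         discrepancy_count = discrepancy_count,
         seed = seed),
    class = "inference_params"
  )
}

# Resolve data-dependent defaults against a concrete feature count.
resolve_params <- function(params, n_features) {
  if (is.null(params$S)) params$S <- n_features
  if (is.null(params$discrepancy_count))
    params$discrepancy_count <- as.integer(ceiling(0.1 * (n_features - 1L)))
  params
}
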