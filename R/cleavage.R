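# Canonical residue order used by all cleavage-model matrices.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Positional frequency model for ADAM-type cleavage motifs
#'
#' A 0th-order Markov model of a 10-residue cleavage window: a positional
#' relative-frequency matrix (10 positions x 20 amino acids, rows summing
#' to 1) for the cleavage motif, against a background of overall amino-acid
#' frequencies for the no-motif hypothesis. Zero frequencies are lifted by
#' an additive pseudocount of `1/(n_screen_peptides + 20)` (standard
#' position-weight-matrix practice, so no window can score a hard zero),
#' followed by renormalization.
#'
#' @param pfm Numeric 10 x 20 matrix of positional relative frequencies;
#'   columns named by one-letter residue codes.
#' @param background Numeric vector of 20 background residue frequencies
#'   (named), summing to 1.
#' @param ratio_threshold Minimum motif/background probability ratio for a
#'   window to count as a probable cleavage site (default 2, i.e. "at
#'   least two times higher").
#' @param tm_window Maximum distance from the transmembrane domain within
#'   which a motif may reside (default 35 residues, the ectodomain size
#'   constraint of gamma-secretase substrates).
#' @param n_screen_peptides Number of peptides behind the frequency
#'   estimates; sets the pseudocount (default 100).
#' @return An object of class `cleavage_model`.
#' @export
cleavage_model <- function(pfm, background, ratio_threshold = 2,
                           tm_window = 35L, n_screen_peptides = 100L) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 10L || ncol(pfm) != 20L)
    stop("pfm must be 10 positions x 20 amino acids")
  if (is.null(colnames(pfm))) colnames(pfm) <- AA_ALPHABET
  if (!setequal(colnames(pfm), AA_ALPHABET))
    stop("pfm columns must be the 20 standard one-letter residue codes")
  pfm <- pfm[, AA_ALPHABET]
  background <- background[AA_ALPHABET]
  if (anyNA(background)) stop("background must name all 20 residues")
  if (any(pfm < 0) || any(background < 0))
    stop("frequencies must be non-negative")

  pc <- 1 / (n_screen_peptides + 20)
  if (any(pfm == 0)) pfm <- pfm + pc
  if (any(background == 0)) background <- background + pc
  pfm <- pfm / rowSums(pfm)
  background <- background / sum(background)

  if (any(abs(rowSums(pfm) - 1) > 1e-9))
    stop("pfm rows must sum to 1")
  structure(
    list(pfm = pfm, background = background,
         ratio_threshold = ratio_threshold,
         tm_window = as.integer(tm_window)),
    class = "cleavage_model"
  )
}

#' @export
print.cleavage_model <- function(x, ...) {
  cat(sprintf(paste0("<cleavage_model> 10 x 20 positional frequencies; ",
                     "ratio threshold %.2g, TM window %d aa\n"),
              x$ratio_threshold, x$tm_window))
  invisible(x)
}

#' Motif-to-background probability ratio of one 10-residue window
#'
#' The probability of the window under the positional motif model divided
#' by its probability under the background model, both as 0th-order Markov
#' chains (products of independent per-position frequencies).
#'
#' @param window Character string of exactly 10 residues.
#' @param model A [cleavage_model()].
#' @return The ratio (>= 0), or `NA` with a warning if the window contains
#'   residues outside the 20-letter alphabet.
#' @export
window_ratio <- function(window, model) {
  stopifnot(inherits(model, "cleavage_model"))
  aa <- strsplit(toupper(window), "")[[1L]]
  if (length(aa) != 10L) stop("window must be exactly 10 residues")
  idx <- match(aa, AA_ALPHABET)
  if (anyNA(idx)) {
    warning("window skipped: non-standard residue(s) ",
            paste(unique(aa[is.na(idx)]), collapse = ", "))
    return(NA_real_)
  }
  # direct products: 10 positions cannot under- or overflow a double
  prod(model$pfm[cbind(seq_len(10L), idx)]) / prod(model$background[idx])
}

#' Predict probable cleavage sites in a protein sequence
#'
#' Slides a 10-residue window over the stretch immediately upstream
#' (extracellular side) of the transmembrane domain and reports every
#' window whose motif/background probability ratio reaches the model's
#' threshold. A window qualifies only when it lies fully within
#' `tm_window` residues of the transmembrane start, i.e. its last residue
#' is before `tm_start` and its first residue is at least
#' `tm_start - tm_window`. Results are sorted by descending ratio. All
#' coordinates are 1-based; the scissile bond of a window is taken between
#' its positions 5 and 6.
#'
#' @param sequence Protein sequence (character string, length >= 10).
#' @param model A [cleavage_model()].
#' @param tm_start 1-based index of the first transmembrane residue.
#' @return Data frame with columns `start`, `end`, `window`, `ratio`.
#' @export
predict_sites <- function(sequence, model, tm_start) {
  stopifnot(inherits(model, "cleavage_model"))
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  if (len < 10L) stop("sequence must be at least 10 residues")
  tm_start <- as.integer(tm_start)
  if (tm_start < 1L || tm_start > len) stop("tm_start outside the sequence")

  first <- max(1L, tm_start - model$tm_window)
  last <- tm_start - 10L
  if (last < first)
    return(data.frame(start = integer(), end = integer(),
                      window = character(), ratio = numeric()))

  starts <- first:last
  windows <- substring(sequence, starts, starts + 9L)
  ratios <- vapply(windows, window_ratio, 0, model = model,
                   USE.NAMES = FALSE)
  keep <- !is.na(ratios) & ratios >= model$ratio_threshold
  out <- data.frame(start = starts[keep], end = starts[keep] + 9L,
                    window = windows[keep], ratio = ratios[keep])
  out <- out[order(-out$ratio, out$start), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(out$end < tm_start),
            all(out$start >= tm_start - model$tm_window))
  out
}

#' Synthetic positional frequency matrix
#'
#' Builds a synthetic motif matrix for testing and demonstration: each
#' position is a mixture of the background and a point mass on the
#' consensus residue, `(1 - strength) * background + strength * consensus`.
#' The published screen-derived ADAM10/ADAM17 matrices are not
#' redistributable, so user-supplied matrices (see [read_pfm()]) are
#' required for real predictions.
#'
#' @param consensus Character string of 10 consensus residues.
#' @param strength Mixture weight of the consensus in `[0, 1]`.
#' @param background Background frequencies (default uniform).
#' @return A 10 x 20 row-stochastic matrix.
#' @export
synthetic_pfm <- function(consensus, strength = 0.8,
                          background = uniform_background()) {
  aa <- strsplit(toupper(consensus), "")[[1L]]
  if (length(aa) != 10L) stop("consensus must be 10 residues")
  idx <- match(aa, AA_ALPHABET)
  if (anyNA(idx)) stop("non-standard residue in consensus")
  stopifnot(strength >= 0, strength <= 1)
  background <- background[AA_ALPHABET] / sum(background[AA_ALPHABET])
  pfm <- matrix(rep((1 - strength) * background, each = 10L), 10L, 20L,
                dimnames = list(NULL, AA_ALPHABET))
  pfm[cbind(seq_len(10L), idx)] <- pfm[cbind(seq_len(10L), idx)] + strength
  pfm
}

#' Uniform amino-acid background
#'
#' @return Named vector of 20 equal frequencies.
#' @export
uniform_background <- function() {
  stats::setNames(rep(1 / 20, 20L), AA_ALPHABET)
}

#' Read a positional frequency matrix from TSV
#'
#' Expects 10 data rows (window positions) and 20 columns headed by the
#' one-letter residue codes.
#'
#' @param path File path.
#' @return Numeric 10 x 20 matrix.
#' @export
read_pfm <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#")
  as.matrix(df)
}

#' Read background residue frequencies from TSV
#'
#' Two columns: residue code and frequency.
#'
#' @param path File path.
#' @return Named numeric vector of 20 frequencies.
#' @export
read_background <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  seqs <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}
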