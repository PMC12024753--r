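# Sample-level filtering and scaling applied before immune inference.

#' Flag hypermutated outlier samples by mutation-count z-score
#'
#' Computes the z-score of each sample's total mutation count against the
#' full input vector (single pass, population standard deviation) and returns
#' the samples exceeding the threshold. With zero variance no sample is
#' flagged.
#'
#' @param mutation_counts named non-negative integer vector (names = sample
#'   identifiers).
#' @param z_threshold flag samples with z above this value (default 3).
#' @return Character vector of flagged sample identifiers (possibly empty).
#' @export
remove_mutation_outliers <- function(mutation_counts, z_threshold = 3) {
  if (length(mutation_counts) < 2L)
    stop_input("need at least 2 samples to compute z-scores")
  if (any(mutation_counts < 0)) stop_input("mutation counts must be >= 0")
  if (z_threshold <= 0) stop_input("z_threshold must be positive")
  s <- sd_pop(mutation_counts)
  if (s == 0) return(character(0))
  z <- (mutation_counts - mean(mutation_counts)) / s
  names(mutation_counts)[z > z_threshold]
}

#' Z-score a matrix along rows or columns
#'
#' Non-constant vectors are centered to mean 0 and scaled to population
#' standard deviation 1; constant vectors map to all zeros.
#'
#' @param m numeric matrix with finite entries.
#' @param margin 1 to standardize each row, 2 for each column.
#' @return Matrix of the same shape and dimnames.
#' @export
zscore_matrix <- function(m, margin = 1L) {
  if (!all(is.finite(m))) stop_input("matrix must be finite")
  if (margin == 2L) return(t(zscore_matrix(t(m), 1L)))
  mu <- rowMeans(m)
  s <- sqrt(rowMeans((m - mu)^2))
  z <- (m - mu) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  z
}

#' Log2 transform with pseudocount
#'
#' @param m non-negative numeric matrix.
#' @param pseudocount positive offset added before the log (default 1).
#' @return `log2(m + pseudocount)` elementwise.
#' @export
log_transform <- function(m, pseudocount = 1) {
  if (pseudocount <= 0) stop_input("pseudocount must be positive")
  if (any(m < 0)) stop_input("expression values must be non-negative")
  log2(m + pseudocount)
}
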