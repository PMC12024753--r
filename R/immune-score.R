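# Rank-statistic cell-type scoring: a self-contained, analytically
# characterized projection of bulk expression onto signature gene sets.
#
# For each sample, genes are ranked ascending (average ranks on ties). For a
# signature of G genes among N measured, the score is the standardized mean
# rank
#
#   score = (meanRank - (N + 1) / 2) / sqrt((N + 1) (N - G) / (12 G)),
#
# i.e. a Wilcoxon-type rank-sum z. Under random placement of the set its
# expectation is 0 and variance 1, and it is invariant under any strictly
# monotone transform of the sample's expression values, so the choice of
# normalization upstream (TPM, RSEM, log) does not affect it.

#' Score cell-type signature gene sets per sample
#'
#' @param expr numeric genes x samples matrix (any monotone scale; ranks are
#'   taken within each sample).
#' @param sets named list of character gene vectors (e.g. from [read_gmt()]
#'   or [signature_gene_sets()]).
#' @param min_overlap sets sharing fewer than this many genes with the matrix
#'   are dropped with a warning (default 3).
#' @return `immune_profile` matrix: cell types x samples standardized scores.
#' @export
score_cell_types <- function(expr, sets, min_overlap = 3L) {
  if (!all(is.finite(expr))) stop_input("expression must be finite")
  if (!length(sets)) stop_input("empty gene-set collection")
  n_genes <- nrow(expr)
  idx <- lapply(sets, function(g) which(rownames(expr) %in% g))
  keep <- lengths(idx) >= min_overlap
  if (!any(keep))
    stop_input("no gene set shares >= ", min_overlap,
               " genes with the expression matrix")
  if (any(!keep))
    warning("dropping ", sum(!keep), " gene set(s) with < ", min_overlap,
            " matched genes: ",
            paste(names(sets)[!keep], collapse = ", "), call. = FALSE)
  idx <- idx[keep]
  ranks <- apply(expr, 2L, rank)  # ascending, average ties
  scores <- do.call(rbind, lapply(idx, function(i) {
    g <- length(i)
    mean_rank <- colMeans(ranks[i, , drop = FALSE])
    (mean_rank - (n_genes + 1) / 2) /
      sqrt((n_genes + 1) * (n_genes - g) / (12 * g))
  }))
  dimnames(scores) <- list(names(idx), colnames(expr))
  class(scores) <- c("immune_profile", class(scores))
  scores
}

#' Write an immune-profile matrix as TSV
#' @param profiles cell-type x sample matrix.
#' @param path file path.
#' @export
write_profiles_tsv <- function(profiles, path) {
  m <- unclass(profiles)
  df <- data.frame(cell_type = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
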