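# Count-based differential expression: median-of-ratios normalization and a
# simplified negative-binomial Wald test, plus the immune-checkpoint panel
# comparison on log-scale expression.
#
# The NB test is a deliberately transparent stand-in for a full DE framework:
# per-gene method-of-moments dispersion (no shrinkage across genes, no LFC
# priors, no independent filtering), so absolute significant-gene counts will
# differ from shrinkage-based tools even on identical data.

#' Median-of-ratios size factors
#'
#' `factor_j = median over reference genes of count[g, j] / geomean_g`, where
#' the reference genes are those with positive counts in every sample and
#' `geomean_g` is the per-gene geometric mean across samples.
#'
#' @param counts genes x samples non-negative count matrix; at least one gene
#'   must be positive in all samples.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_input("counts must be non-negative")
  log_counts <- log(counts)
  log_geo <- rowMeans(log_counts)
  ref <- is.finite(log_geo)
  if (!any(ref))
    stop_input("no gene has positive counts in every sample")
  sf <- apply(log_counts[ref, , drop = FALSE] - log_geo[ref], 2L,
              function(v) exp(stats::median(v)))
  stats::setNames(sf, colnames(counts))
}

#' Simplified negative-binomial Wald test for two groups
#'
#' Counts are normalized by median-of-ratios size factors. Per gene, group
#' means `mu1`, `mu2` and a pooled method-of-moments dispersion
#' `alpha = (variance - mean) / mean^2` (pooled across the two groups,
#' floored at 1e-8) are estimated from the normalized counts. The effect is
#' `log2FC = log2((mu2 + 0.5) / (mu1 + 0.5))` with a delta-method standard
#' error under `Var = mu + alpha mu^2`, a two-sided normal (Wald) p-value,
#' and Benjamini-Hochberg q-values.
#'
#' @param counts genes x samples integer matrix.
#' @param groups two-level factor (or coercible) over the columns; the
#'   fold change is group 2 relative to group 1 (level order).
#' @param sf optional size factors; computed when omitted.
#' @return data.frame with `gene`, `base_mean`, `log2fc`, `se`, `stat`,
#'   `p_value`, `q_value`.
#' @export
nb_wald_test <- function(counts, groups, sf = NULL) {
  counts <- as.matrix(counts)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop_input("groups must have exactly 2 levels")
  if (length(groups) != ncol(counts))
    stop_input("groups length must match the number of samples")
  n1 <- sum(groups == levels(groups)[1L])
  n2 <- sum(groups == levels(groups)[2L])
  if (n1 < 2L || n2 < 2L) stop_input("both groups need >= 2 samples")
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, `/`)
  i1 <- groups == levels(groups)[1L]
  x1 <- norm[, i1, drop = FALSE]; x2 <- norm[, !i1, drop = FALSE]
  mu1 <- rowMeans(x1); mu2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, stats::var); v2 <- apply(x2, 1L, stats::var)
  disp_of <- function(v, mu) ifelse(mu > 0, (v - mu) / mu^2, 0)
  alpha <- pmax(((n1 - 1) * disp_of(v1, mu1) + (n2 - 1) * disp_of(v2, mu2)) /
                  (n1 + n2 - 2), 1e-8)
  eps <- 0.5
  log2fc <- log2((mu2 + eps) / (mu1 + eps))
  var_mu1 <- (mu1 + alpha * mu1^2) / n1
  var_mu2 <- (mu2 + alpha * mu2^2) / n2
  se <- sqrt(var_mu1 / (mu1 + eps)^2 + var_mu2 / (mu2 + eps)^2) / log(2)
  stat <- ifelse(se > 0, log2fc / se, 0)
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(stat)), 1)
  data.frame(gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             base_mean = rowMeans(norm), log2fc = log2fc, se = se,
             stat = stat, p_value = p, q_value = bh_fdr(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up procedure: `q_(i) = min over j >= i of min(1, m p_(j) / j)`,
#' mapped back to input order.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return Numeric q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop_input("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Default immune-checkpoint gene panel
#'
#' TIGIT, PD-L1 (CD274), CTLA4 and PD-1 (PDCD1); `extended = TRUE` appends
#' further commonly screened inhibitory checkpoints.
#'
#' @param extended include the extended list (default FALSE).
#' @return Character vector of gene symbols.
#' @export
checkpoint_panel <- function(extended = FALSE) {
  core <- c("TIGIT", "CD274", "CTLA4", "PDCD1")
  if (!extended) return(core)
  c(core, "LAG3", "HAVCR2", "BTLA", "VSIR", "CD276", "IDO1", "PDCD1LG2")
}

#' Checkpoint-panel comparison between clusters
#'
#' For each panel gene and each pair of retained clusters: the difference of
#' group means on the log2 scale and a two-sided Welch t-test, with
#' significance stars at the conventional thresholds
#' (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05).
#'
#' @param logexpr log2-scale genes x samples matrix.
#' @param labels named cluster factor (discarded samples excluded).
#' @param panel gene symbols to test (default [checkpoint_panel()]); missing
#'   genes are skipped with a warning.
#' @return data.frame with `gene`, `group1`, `group2`, `log2_fc`
#'   (group2 - group1 mean), `p_value`, `stars`.
#' @export
checkpoint_panel_test <- function(logexpr, labels, panel = checkpoint_panel()) {
  labels <- labels[names(labels) %in% colnames(logexpr)]
  labels <- droplevels(labels[labels != "discarded"])
  present <- panel %in% rownames(logexpr)
  if (!any(present)) stop_input("no panel gene present in the matrix")
  if (any(!present))
    warning("panel gene(s) absent from matrix, skipped: ",
            paste(panel[!present], collapse = ", "), call. = FALSE)
  panel <- panel[present]
  cl <- levels(labels)
  usable <- cl[vapply(cl, function(g) sum(labels == g) >= 2L, NA)]
  if (length(usable) < length(cl))
    warning("cluster(s) with < 2 samples skipped: ",
            paste(setdiff(cl, usable), collapse = ", "), call. = FALSE)
  if (length(usable) < 2L) stop_input("need >= 2 clusters with >= 2 samples")
  pairs <- utils::combn(usable, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- names(labels)[labels == pairs[1L, j]]
    g2 <- names(labels)[labels == pairs[2L, j]]
    do.call(rbind, lapply(panel, function(gene) {
      x1 <- logexpr[gene, g1]; x2 <- logexpr[gene, g2]
      p <- if (stats::sd(x1) == 0 && stats::sd(x2) == 0) {
        if (mean(x1) == mean(x2)) 1 else 0
      } else stats::t.test(x2, x1)$p.value
      data.frame(gene = gene, group1 = pairs[1L, j], group2 = pairs[2L, j],
                 log2_fc = mean(x2) - mean(x1), p_value = p,
                 stars = significance_stars(p), stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
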