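# Mutation-distribution report: per-cluster counts with fractions in
# parentheses, overall and pairwise chi-square p-values.

#' Cluster-by-mutation distribution report
#'
#' Builds, for each mutation, the cluster x status table, the per-cluster
#' counts formatted as `"33 (20.1%)"`, the overall chi-square p-value and
#' all pairwise cluster chi-square p-values.
#'
#' @param labels named cluster factor (discarded samples excluded).
#' @param mutations named list of per-sample binary status vectors, e.g.
#'   `list(EGFR = ..., KRAS = ...)`.
#' @return `mutation_report` object (list with one entry per mutation, each
#'   holding `table`, `fractions`, `formatted`, `overall`, `pairwise`).
#' @export
table2_report <- function(labels, mutations) {
  if (!is.list(mutations)) mutations <- list(status = mutations)
  out <- lapply(mutations, function(status) {
    tab <- build_contingency(labels, status)
    frac <- mutation_fractions(tab)
    formatted <- stats::setNames(sprintf("%d (%.1f%%)", tab[, "mutated"],
                                         100 * frac),
                                 rownames(tab))
    overall <- tryCatch(chi_square_independence(tab),
                        error = function(e) list(statistic = NA_real_,
                                                 df = NA_real_,
                                                 p_value = NA_real_))
    pw <- tryCatch(pairwise_chisq(labels, status),
                   error = function(e) NULL)
    list(table = tab, fractions = frac, formatted = formatted,
         overall = overall, pairwise = pw)
  })
  structure(out, class = "mutation_report")
}

#' @export
print.mutation_report <- function(x, ...) {
  for (m in names(x)) {
    r <- x[[m]]
    cat(m, "distribution across clusters\n")
    wt <- r$table[, "WT"]
    line <- function(vals) paste(formatC(vals, width = 12), collapse = "")
    cat("  ", line(c("", rownames(r$table))), "\n", sep = "")
    cat("  ", line(c("WT", wt)), "\n", sep = "")
    cat("  ", line(c("mutated", r$formatted)), "\n", sep = "")
    cat(sprintf("  overall chi-square p = %.3g\n", r$overall$p_value))
    if (!is.null(r$pairwise))
      for (i in seq_len(nrow(r$pairwise)))
        cat(sprintf("  %s vs %s: p = %.3g\n", r$pairwise$group2[i],
                    r$pairwise$group1[i], r$pairwise$p_value[i]))
    cat("\n")
  }
  invisible(x)
}
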