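# Cluster x mutation (and cluster x covariate) contingency analysis.

#' Build a cluster-by-status contingency table
#'
#' Samples in discarded clusters and samples with missing status are
#' excluded (the exclusion counts are attached as attributes).
#'
#' @param labels named factor of cluster labels (a `discarded` level is
#'   dropped), e.g. from [cluster_labels()].
#' @param status named per-sample binary status: logical, 0/1, or character
#'   coded `"WT"`/`"mutated"` (any second level is treated as positive).
#' @return Integer matrix, clusters x c("WT", "mutated").
#' @export
build_contingency <- function(labels, status) {
  labels <- labels[names(labels) %in% names(status)]
  if (!length(labels))
    stop_input("no samples shared between assignment and status labels")
  status <- status[names(labels)]
  keep <- labels != "discarded" & !is.na(status)
  n_discarded <- sum(labels == "discarded")
  n_missing <- sum(is.na(status) & labels != "discarded")
  labels <- droplevels(labels[keep])
  status <- status[keep]
  pos <- if (is.logical(status)) status
    else if (is.numeric(status)) status != 0
    else status %in% c("mutated", "mut", "yes", "1", "TRUE")
  tab <- table(cluster = labels, status = factor(ifelse(pos, "mutated", "WT"),
                                                 levels = c("WT", "mutated")))
  out <- matrix(as.integer(tab), nrow(tab),
                dimnames = list(rownames(tab), colnames(tab)))
  if (any(colSums(out) == 0))
    attr(out, "degenerate") <- "a status column has zero total"
  attr(out, "n_discarded") <- n_discarded
  attr(out, "n_missing_status") <- n_missing
  out
}

#' Per-cluster fraction of mutated samples
#'
#' @param table contingency table with a `mutated` column (or 2-column
#'   matrix, second column = positive).
#' @param digits significant digits (default 3).
#' @return Named numeric vector; `NA` for clusters with zero total.
#' @export
mutation_fractions <- function(table, digits = 3L) {
  mut_col <- if ("mutated" %in% colnames(table)) "mutated" else ncol(table)
  tot <- rowSums(table)
  f <- ifelse(tot == 0, NA_real_, table[, mut_col] / tot)
  signif(stats::setNames(as.numeric(f), rownames(table)), digits)
}

#' Pearson chi-square test of independence
#'
#' Uncorrected by default; Yates continuity correction is available for
#' 2x2 tables only.
#'
#' @param table contingency matrix (>= 2x2, positive marginals).
#' @param correct apply Yates correction (2x2 only; default FALSE).
#' @return List with `statistic`, `df`, `p_value` and `expected`.
#' @export
chi_square_independence <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_input("chi-square test requires positive row and column marginals")
  if (correct && !all(dim(table) == 2L))
    stop_input("continuity correction applies to 2x2 tables only")
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = ht$expected)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities no larger
#' than that of the observed table. The odds ratio reported is the sample
#' odds ratio `ad / bc` (infinite when `bc = 0` and `ad > 0`), not the
#' conditional maximum-likelihood estimate.
#'
#' @param table 2x2 matrix of non-negative integers.
#' @return List with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop_input("table must be 2x2")
  if (any(table < 0)) stop_input("counts must be non-negative")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  or <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * c)
  p <- stats::fisher.test(table)$p.value
  list(odds_ratio = or, p_value = p)
}

#' Auto-dispatched independence test
#'
#' Chi-square for r x 2 tables; Fisher's exact test for 2x2 tables with any
#' expected count below 5.
#'
#' @param table contingency matrix.
#' @return List as in [chi_square_independence()] or [fisher_exact_2x2()],
#'   plus `method`.
#' @export
association_test <- function(table) {
  table <- as.matrix(table)
  if (all(dim(table) == 2L)) {
    expected <- outer(rowSums(table), colSums(table)) / sum(table)
    if (any(expected < 5)) {
      res <- fisher_exact_2x2(table)
      return(c(res, method = "fisher"))
    }
  }
  c(chi_square_independence(table), method = "chi-square")
}

#' Pairwise cluster chi-square tests for a binary status
#'
#' Uncorrected Pearson chi-square on each 2x2 (cluster pair) x (status)
#' table.
#'
#' @param labels,status as in [build_contingency()].
#' @param correct Yates correction flag (default FALSE).
#' @return data.frame with `group1`, `group2`, `statistic`, `p_value`.
#' @export
pairwise_chisq <- function(labels, status, correct = FALSE) {
  tab <- build_contingency(labels, status)
  cl <- rownames(tab)
  if (length(cl) < 2L) stop_input("need >= 2 retained clusters")
  pairs <- utils::combn(cl, 2L)
  res <- apply(pairs, 2L, function(p) {
    sub <- tab[p, , drop = FALSE]
    if (any(colSums(sub) == 0) || any(rowSums(sub) == 0))
      return(c(NA_real_, NA_real_))
    ht <- chi_square_independence(sub, correct = correct)
    c(ht$statistic, ht$p_value)
  })
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             statistic = res[1L, ], p_value = res[2L, ],
             stringsAsFactors = FALSE)
}

#' Category-versus-rest association tests
#'
#' For each level of a categorical covariate, tests the 2x2 table
#' (this category vs all other non-missing categories) x (status), the
#' construction used for demographic-table rows. Missing covariate values
#' are excluded listwise.
#'
#' @param category named character/factor covariate per sample (NA allowed).
#' @param status named binary status as in [build_contingency()].
#' @return data.frame with `category`, `n_status_positive`, `n_status_negative`,
#'   `p_value`, `method`.
#' @export
category_vs_rest_tests <- function(category, status) {
  shared <- intersect(names(category), names(status))
  category <- category[shared]; status <- status[shared]
  keep <- !is.na(category) & !is.na(status)
  category <- factor(category[keep]); status <- status[keep]
  pos <- if (is.logical(status)) status
    else if (is.numeric(status)) status != 0
    else status %in% c("mutated", "mut", "yes", "1", "TRUE")
  rows <- lapply(levels(category), function(lv) {
    tab <- rbind(table(factor(ifelse(pos[category == lv], "mutated", "WT"),
                              levels = c("WT", "mutated"))),
                 table(factor(ifelse(pos[category != lv], "mutated", "WT"),
                              levels = c("WT", "mutated"))))
    p <- tryCatch(association_test(tab)$p_value, error = function(e) NA_real_)
    method <- tryCatch(association_test(tab)$method,
                       error = function(e) NA_character_)
    data.frame(category = lv,
               n_status_positive = sum(pos[category == lv]),
               n_status_negative = sum(!pos[category == lv]),
               p_value = p, method = method, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
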