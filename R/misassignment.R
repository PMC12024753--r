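# Resampling misassignment test: is a small mutation-positive subset of one
# cluster distinguishable from the same-mutation samples of another cluster,
# beyond what same-size random draws from within a cluster produce?
#
# Procedure: the observed statistic is the number of genes passing the joint
# significance rule (p < p_threshold AND BH q < fdr_threshold) in a
# two-group NB Wald comparison. The null distribution is built by drawing m
# samples at random (without replacement) from a cluster's eligible members
# and comparing them to the remainder of the same cluster, repeated R times;
# the observed count is then z-tested against the replicate mean and
# standard deviation. With small R the normal approximation is crude and
# mildly anti-conservative, so an empirical rank-based p-value against the
# replicate counts is reported alongside.

#' Count significant genes between two sample groups
#'
#' Runs [nb_wald_test()] on the two disjoint groups and counts genes with
#' `p < p_threshold` and `q < fdr_threshold`.
#'
#' @param counts genes x samples count matrix.
#' @param group_a,group_b disjoint character vectors of sample identifiers,
#'   each of size >= 2.
#' @param p_threshold,fdr_threshold joint significance rule (defaults 0.05
#'   and 0.25).
#' @return Integer count of significant genes.
#' @export
observed_count <- function(counts, group_a, group_b,
                           p_threshold = 0.05, fdr_threshold = 0.25) {
  if (length(intersect(group_a, group_b)))
    stop_input("groups must be disjoint")
  missing <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(missing))
    stop_input("samples absent from count matrix: ",
               paste(utils::head(missing, 5L), collapse = ", "))
  sub <- counts[, c(group_a, group_b), drop = FALSE]
  groups <- factor(rep(c("A", "B"), c(length(group_a), length(group_b))),
                   levels = c("A", "B"))
  de <- nb_wald_test(sub, groups)
  sum(de$p_value < p_threshold & de$q_value < fdr_threshold)
}

#' Resampling null distribution of significant-gene counts
#'
#' For each of `R` repetitions, draws `m` samples uniformly without
#' replacement from the eligible set and counts significant genes between
#' the draw and the remainder of the set.
#'
#' @param counts genes x samples count matrix.
#' @param eligible character vector of eligible sample identifiers (e.g. the
#'   mutation-positive members of a cluster); must exceed `m`.
#' @param m draw size (default 4).
#' @param R repetitions (default 18).
#' @param seed integer seed; draws are reproducible and independent of the
#'   order of `eligible`.
#' @param p_threshold,fdr_threshold passed to [observed_count()].
#' @return `null_distribution` object: list with `counts` (length `R`),
#'   `mean`, `sd` (sample, n-1 denominator), `m`, `R`, `degenerate`
#'   (TRUE when `sd` is 0).
#' @export
resampling_null <- function(counts, eligible, m = 4L, R = 18L, seed = 42L,
                            p_threshold = 0.05, fdr_threshold = 0.25) {
  m <- as.integer(m); R <- as.integer(R)
  if (m < 2L) stop_input("m must be >= 2")
  if (R < 2L) stop_input("R must be >= 2")
  eligible <- sort(unique(eligible))
  if (length(eligible) <= m + 1L)
    stop_input("eligible set (", length(eligible),
               ") must exceed m + 1 = ", m + 1L,
               " so the remainder has >= 2 samples")
  reps <- with_seed(seed, {
    vapply(seq_len(R), function(r) {
      draw <- sample(eligible, m)
      observed_count(counts, draw, setdiff(eligible, draw),
                     p_threshold, fdr_threshold)
    }, 0L)
  })
  structure(list(counts = reps, mean = mean(reps), sd = stats::sd(reps),
                 m = m, R = R, degenerate = stats::sd(reps) == 0),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Resampling null (m =", x$m, ", R =", x$R, "):",
      sprintf("%.1f +/- %.1f", x$mean, x$sd),
      if (x$degenerate) "[degenerate: zero spread]" else "", "\n")
  invisible(x)
}

#' Z-test of an observed count against a resampling null
#'
#' `z = (observed - mean) / sd`, with a normal p-value per sidedness, plus
#' an empirical rank p-value `(1 + #{replicates >= observed}) / (R + 1)`
#' (one-sided; doubled and capped at 1 for two-sided use).
#'
#' @param observed observed significant-gene count.
#' @param null a `null_distribution`.
#' @param sidedness `"two-sided"` (default) or `"one-sided"` (upper tail).
#' @return List with `z`, `p_normal`, `p_empirical`, `sidedness`,
#'   `degenerate`.
#' @export
misassignment_z_test <- function(observed, null,
                                 sidedness = c("two-sided", "one-sided")) {
  sidedness <- match.arg(sidedness)
  stopifnot(inherits(null, "null_distribution"))
  if (null$degenerate)
    return(list(z = NA_real_, p_normal = NA_real_,
                p_empirical = NA_real_, sidedness = sidedness,
                degenerate = TRUE))
  z <- (observed - null$mean) / null$sd
  p_normal <- if (sidedness == "two-sided") 2 * stats::pnorm(-abs(z))
              else stats::pnorm(z, lower.tail = FALSE)
  p_upper <- (1 + sum(null$counts >= observed)) / (null$R + 1)
  p_emp <- if (sidedness == "two-sided") {
    p_lower <- (1 + sum(null$counts <= observed)) / (null$R + 1)
    min(1, 2 * min(p_upper, p_lower))
  } else p_upper
  list(z = z, p_normal = p_normal, p_empirical = p_emp,
       sidedness = sidedness, degenerate = FALSE)
}

#' Full misassignment analysis for a suspect subset
#'
#' Observed: significant-gene count between the suspect samples and the
#' cluster's eligible members. Null: [resampling_null()] within the cluster
#' at the suspect subset's size. Returns the z-test of the observed count
#' against that null.
#'
#' @param counts genes x samples count matrix.
#' @param cluster_eligible eligible members of the reference cluster (e.g.
#'   its mutation-positive samples).
#' @param suspects the samples suspected of misassignment (disjoint from
#'   `cluster_eligible`).
#' @param R repetitions (default 18).
#' @param seed integer seed.
#' @param p_threshold,fdr_threshold joint significance rule.
#' @param sidedness passed to [misassignment_z_test()].
#' @return List with `observed`, `null`, `z`, `p_normal`, `p_empirical`,
#'   `config`.
#' @export
misassignment_analysis <- function(counts, cluster_eligible, suspects,
                                   R = 18L, seed = 42L,
                                   p_threshold = 0.05, fdr_threshold = 0.25,
                                   sidedness = "two-sided") {
  m <- length(suspects)
  obs <- observed_count(counts, suspects, cluster_eligible,
                        p_threshold, fdr_threshold)
  null <- resampling_null(counts, cluster_eligible, m = m, R = R,
                          seed = seed, p_threshold = p_threshold,
                          fdr_threshold = fdr_threshold)
  zt <- misassignment_z_test(obs, null, sidedness)
  list(observed = obs, null = null, z = zt$z, p_normal = zt$p_normal,
       p_empirical = zt$p_empirical,
       config = list(m = m, R = R, seed = seed, p_threshold = p_threshold,
                     fdr_threshold = fdr_threshold, sidedness = sidedness))
}
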