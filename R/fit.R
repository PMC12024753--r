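# The central fitting function: expression + signatures -> immune clustering.

#' Cluster a tumor cohort by inferred immune profiles
#'
#' Runs the full subtype-discovery pipeline on a bulk expression matrix:
#' log2 transform (optional), rank-z cell-type scoring against the signature
#' collection, z-scoring of the cell-type features, projection onto the
#' leading principal components, knee-based choice of the number of clusters
#' from the k-means inertia curve, seeded k-means, and removal of clusters
#' below the minimum size. With `signatures = NULL` the same pipeline is
#' applied directly to the (log) expression matrix with genes as features —
#' the "raw expression" comparator used to quantify what immune inference
#' adds.
#'
#' @param expr non-negative genes x samples matrix (linear scale unless
#'   `log_transform = FALSE`).
#' @param signatures named list of signature gene vectors, a
#'   `cell_type_signatures` object, or `NULL` to cluster raw expression.
#' @param k fixed number of clusters; `NULL` (default) selects k by knee
#'   analysis over `k_range`.
#' @param k_range candidate k values for the knee scan (default 1:10).
#' @param n_components principal components retained (default 2).
#' @param min_cluster_size clusters smaller than this are discarded
#'   (default 5).
#' @param min_overlap minimum signature/matrix gene overlap, see
#'   [score_cell_types()].
#' @param log_transform apply `log2(x + 1)` before scoring (rank scores are
#'   invariant to it; it matters only for raw-expression clustering).
#' @param nstart k-means restarts (default 10).
#' @param seed integer seed controlling k-means initialization (default 42).
#' @return An object of class `immune_clustering`; see Details.
#' @details The returned object contains `profiles` (feature x sample score
#'   matrix), `feature_center`/`feature_scale` (z-scoring parameters),
#'   `pc_scores`, `rotation`, `pca_center`, `eigenvalues`, `knee`
#'   (a `knee_result`, `NULL` when `k` was fixed), `k`, `assignment`
#'   (a `cluster_assignment` after small-cluster filtering), `labels`
#'   (named factor with a `discarded` level when applicable) and `config`.
#'   Methods: `print`, `summary`, `plot`, `predict`, `coef` (cluster
#'   centroids in PC space), `fitted` (labels).
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_samples = 120, seed = 7))
#' fit <- immune_cluster(cohort$expression,
#'                       signature_gene_sets(cohort$signatures))
#' table(fitted(fit), cohort$truth)
#' @export
immune_cluster <- function(expr, signatures, k = NULL, k_range = 1:10,
                           n_components = 2L, min_cluster_size = 5L,
                           min_overlap = 3L, log_transform = TRUE,
                           nstart = 10L, seed = 42L) {
  expr <- as.matrix(expr)
  check_ids(colnames(expr), "sample")
  check_ids(rownames(expr), "gene")
  x <- if (log_transform) log_transform(expr) else expr
  if (inherits(signatures, "cell_type_signatures"))
    signatures <- signature_gene_sets(signatures)
  profiles <- if (is.null(signatures)) x
              else score_cell_types(x, signatures, min_overlap = min_overlap)
  feature_center <- rowMeans(profiles)
  feature_scale <- apply(profiles, 1L, sd_pop)
  z <- zscore_matrix(profiles, 1L)
  pcs <- pca_project(z, n_components = n_components)
  knee <- NULL
  if (is.null(k)) {
    curve <- compute_inertia_curve(pcs, k_range = k_range, seed = seed,
                                   nstart = nstart)
    knee <- select_k_knee(curve$k, curve$inertia)
    k <- knee$selected_k
    if (is.na(k))
      stop_input("knee analysis found no elbow in the inertia curve; ",
                 "supply k explicitly")
  }
  assignment <- kmeans_cluster(pcs, k, seed = seed, nstart = nstart)
  assignment <- filter_small_clusters(assignment, min_cluster_size)
  structure(list(
    profiles = profiles, feature_center = feature_center,
    feature_scale = feature_scale,
    pc_scores = structure(pcs[, , drop = FALSE], rotation = NULL),
    rotation = attr(pcs, "rotation"), pca_center = attr(pcs, "center"),
    eigenvalues = attr(pcs, "eigenvalues"),
    knee = knee, k = assignment$k, assignment = assignment,
    labels = assignment$labels,
    config = list(n_components = n_components,
                  min_cluster_size = min_cluster_size,
                  min_overlap = min_overlap, log_transform = log_transform,
                  nstart = nstart, seed = seed,
                  feature_space = if (is.null(signatures)) "expression"
                                  else "immune"),
    call = match.call()), class = "immune_clustering")
}

#' Cluster labels of a fitted immune clustering
#'
#' @param object an `immune_clustering` fit.
#' @param drop_discarded drop samples in discarded clusters (default FALSE).
#' @return Named factor of cluster labels.
#' @export
cluster_labels <- function(object, drop_discarded = FALSE) {
  stopifnot(inherits(object, "immune_clustering"))
  lab <- object$labels
  if (drop_discarded) {
    lab <- lab[lab != "discarded"]
    lab <- droplevels(lab)
  }
  lab
}

#' @export
fitted.immune_clustering <- function(object, ...) object$labels

#' @export
coef.immune_clustering <- function(object, ...) object$assignment$centers

#' @export
print.immune_clustering <- function(x, ...) {
  cat("Immune-profile clustering (", x$config$feature_space,
      " feature space)\n", sep = "")
  cat("  samples:", length(x$labels), " features:", nrow(x$profiles),
      " components:", x$config$n_components, "\n")
  if (!is.null(x$knee))
    cat("  knee-selected K =", x$knee$selected_k, "over k =",
        paste(range(x$knee$k), collapse = ".."), "\n")
  cat("  retained clusters:", x$k, "(",
      paste(sprintf("%s=%d", names(x$assignment$sizes), x$assignment$sizes),
            collapse = ", "), ")\n")
  if (x$assignment$n_discarded > 0)
    cat("  discarded samples:", x$assignment$n_discarded, "\n")
  invisible(x)
}

#' @export
summary.immune_clustering <- function(object, ...) {
  ev <- object$eigenvalues
  res <- list(fit = object,
              var_explained = ev[seq_len(object$config$n_components)] / sum(ev),
              sizes = object$assignment$sizes,
              n_discarded = object$assignment$n_discarded,
              tot_withinss = object$assignment$tot_withinss)
  class(res) <- "summary.immune_clustering"
  res
}

#' @export
print.summary.immune_clustering <- function(x, ...) {
  print(x$fit)
  cat("  variance explained by retained components:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  cat("  total within-cluster SS:", format(x$tot_withinss, digits = 4), "\n")
  invisible(x)
}

#' @export
plot.immune_clustering <- function(x, which = c("clusters", "knee"), ...) {
  which <- match.arg(which)
  if (which == "knee") {
    if (is.null(x$knee)) stop_input("fit has no knee curve (k was fixed)")
    graphics::plot(x$knee$k, x$knee$inertia, type = "b", xlab = "k",
                   ylab = "inertia (normalized)", main = "Knee analysis", ...)
    if (!is.na(x$knee$selected_k))
      graphics::abline(v = x$knee$selected_k, lty = 2)
  } else {
    cols <- c(grDevices::hcl.colors(max(x$k, 1L), "Dark 3"), "grey70")
    lab <- x$labels
    col_i <- as.integer(lab)
    graphics::plot(x$pc_scores[, 1L], x$pc_scores[, 2L],
                   col = cols[col_i], pch = 19,
                   xlab = "PC1", ylab = "PC2",
                   main = "Samples in immune PC space", ...)
    graphics::legend("topright", legend = levels(lab), col = cols[seq_len(nlevels(lab))],
                     pch = 19, cex = 0.8)
  }
  invisible(x)
}

#' Assign new samples to fitted clusters
#'
#' Scores new expression columns with the stored pipeline parameters
#' (scoring, feature z-scoring, PCA rotation) and assigns each sample to the
#' nearest retained cluster centroid in component space.
#'
#' @param object an `immune_clustering` fitted with signatures.
#' @param newdata genes x samples expression matrix on the same gene space.
#' @param signatures the signature collection used at fit time.
#' @param ... unused.
#' @return Named factor of predicted cluster labels.
#' @export
predict.immune_clustering <- function(object, newdata, signatures, ...) {
  x <- if (object$config$log_transform) log_transform(as.matrix(newdata))
       else as.matrix(newdata)
  if (inherits(signatures, "cell_type_signatures"))
    signatures <- signature_gene_sets(signatures)
  prof <- score_cell_types(x, signatures,
                           min_overlap = object$config$min_overlap)
  prof <- prof[rownames(object$profiles), , drop = FALSE]
  scale <- ifelse(object$feature_scale == 0, 1, object$feature_scale)
  z <- (prof - object$feature_center) / scale
  pcs <- crossprod(z - object$pca_center, object$rotation)
  centers <- object$assignment$centers
  d <- outer(rowSums(pcs^2), rowSums(centers^2), `+`) -
    2 * pcs %*% t(centers)
  lab <- rownames(centers)[apply(d, 1L, which.min)]
  factor(stats::setNames(lab, colnames(newdata)), levels = rownames(centers))
}
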