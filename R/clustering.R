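# Dimensionality reduction, knee-based model selection, seeded k-means and
# small-cluster filtering.

#' Project profiles onto leading principal components
#'
#' Principal components of the feature covariance (features are expected to
#' be z-scored already, so this is correlation-matrix PCA). Component signs
#' are fixed so each component's largest-magnitude loading is positive.
#'
#' @param profiles features x samples numeric matrix.
#' @param n_components number of components to keep (default 2).
#' @return samples x components score matrix with attributes `rotation`
#'   (features x components), `center` (feature means) and `eigenvalues`
#'   (all feature-covariance eigenvalues).
#' @export
pca_project <- function(profiles, n_components = 2L) {
  x <- t(profiles)  # samples x features
  nonconst <- apply(x, 2L, function(v) stats::sd(v) > 0)
  if (sum(nonconst) < n_components)
    stop_input("need >= ", n_components, " non-constant features, have ",
               sum(nonconst))
  if (nrow(x) < n_components)
    stop_input("need >= ", n_components, " samples")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    lead <- which.max(abs(rot[, k]))
    if (rot[lead, k] < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(scores, rotation = rot, center = pc$center,
            eigenvalues = pc$sdev^2)
}

#' k-means++ initial centers
#' @noRd
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      pick <- if (all(d2 == 0)) sample.int(n, 1L)
        else sample.int(n, 1L, prob = d2)
      centers[j, ] <- x[pick, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  centers
}

#' Seeded k-means with k-means++ restarts
#'
#' Lloyd iterations from k-means++ initializations; the best of `nstart`
#' restarts (lowest within-cluster sum of squares) is kept. Deterministic
#' given `seed`. Clusters are relabeled `sub0`, `sub1`, ... in decreasing
#' size order (ties broken by first occurrence), so label identity carries no
#' information beyond size rank.
#'
#' @param scores samples x features numeric matrix (typically PCA scores).
#' @param k number of clusters (`k <= nrow(scores)`).
#' @param seed integer seed.
#' @param nstart number of k-means++ restarts (default 10).
#' @param iter_max Lloyd iteration cap per restart.
#' @return `cluster_assignment` object: list with `labels` (named factor,
#'   levels `sub0`...), `k`, `sizes`, `centers` (rows in label order),
#'   `tot_withinss`, `restart_withinss` (all restarts) and `n_discarded = 0`.
#' @export
kmeans_cluster <- function(scores, k, seed = 42L, nstart = 10L,
                           iter_max = 100L) {
  x <- as.matrix(scores)
  if (k > nrow(x)) stop_input("k = ", k, " exceeds n = ", nrow(x), " samples")
  if (k < 1L) stop_input("k must be >= 1")
  with_seed(seed, {
    best <- NULL
    all_ss <- numeric(0)
    for (r in seq_len(nstart)) {
      fit <- NULL
      for (attempt in 1:5) {  # re-draw centers if a Lloyd cluster empties
        init <- kmeanspp_init(x, k)
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(x, centers = init,
                                         iter.max = iter_max,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(fit)) break
      }
      if (is.null(fit)) next
      all_ss <- c(all_ss, fit$tot.withinss)
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) stop_input("k-means failed for k = ", k)
    relabel_by_size(best$cluster, best$centers, rownames(x), best$tot.withinss,
                    all_ss)
  })
}

# Rename integer clusters sub0.. in decreasing-size order.
relabel_by_size <- function(cluster, centers, sample_ids, tot_withinss,
                            restart_withinss) {
  sizes <- table(cluster)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  old <- as.integer(names(sizes))[ord]
  new_names <- sprintf("sub%d", seq_along(old) - 1L)
  map <- stats::setNames(new_names, old)
  labels <- factor(map[as.character(cluster)], levels = new_names)
  names(labels) <- sample_ids
  centers <- centers[old, , drop = FALSE]
  rownames(centers) <- new_names
  structure(list(labels = labels, k = length(old),
                 sizes = stats::setNames(as.integer(sizes[ord]), new_names),
                 centers = centers, tot_withinss = tot_withinss,
                 restart_withinss = restart_withinss, n_discarded = 0L),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment: k =", x$k, "\n  sizes:",
      paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "), "\n")
  if (x$n_discarded > 0) cat("  discarded samples:", x$n_discarded, "\n")
  invisible(x)
}

#' Discard clusters below a minimum size
#'
#' Members of clusters smaller than `min_cluster_size` are relabeled
#' `discarded`; surviving clusters are renumbered `sub0`... in decreasing
#' size order.
#'
#' @param assignment a `cluster_assignment`.
#' @param min_cluster_size smallest retained cluster size (default 5).
#' @return Updated `cluster_assignment` (with a `discarded` factor level when
#'   any sample was dropped).
#' @export
filter_small_clusters <- function(assignment, min_cluster_size = 5L) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  small <- names(assignment$sizes)[assignment$sizes < min_cluster_size]
  if (!length(small)) return(assignment)
  keep <- setdiff(names(assignment$sizes), small)
  if (!length(keep))
    warning("all clusters are below the minimum size; every sample discarded",
            call. = FALSE)
  old_labels <- as.character(assignment$labels)
  discarded <- old_labels %in% small
  ord <- keep[order(-assignment$sizes[keep])]
  map <- stats::setNames(sprintf("sub%d", seq_along(ord) - 1L), ord)
  new_labels <- ifelse(discarded, "discarded", map[old_labels])
  labels <- factor(new_labels, levels = c(unname(map), "discarded"))
  names(labels) <- names(assignment$labels)
  centers <- assignment$centers[ord, , drop = FALSE]
  if (length(ord)) rownames(centers) <- unname(map)
  structure(list(labels = labels, k = length(ord),
                 sizes = stats::setNames(as.integer(assignment$sizes[ord]),
                                         unname(map)),
                 centers = centers, tot_withinss = assignment$tot_withinss,
                 restart_withinss = assignment$restart_withinss,
                 n_discarded = sum(discarded)),
            class = "cluster_assignment")
}

#' k-means inertia over a range of k
#'
#' Computes the best-of-restarts within-cluster sum of squares for each k.
#' Because restarts can land in local minima, the theoretical monotonicity of
#' the curve is enforced with a running minimum before knee detection.
#'
#' @param scores samples x features matrix.
#' @param k_range integer vector of k values (default 1:10).
#' @param seed,nstart passed to [kmeans_cluster()].
#' @return data.frame with columns `k` and `inertia`.
#' @export
compute_inertia_curve <- function(scores, k_range = 1:10, seed = 42L,
                                  nstart = 10L) {
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range <= nrow(scores)]
  inertia <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)) {
    val <- tryCatch(
      kmeans_cluster(scores, k_range[i], seed = child_seed(seed, k_range[i]),
                     nstart = nstart)$tot_withinss,
      error = function(e) NA_real_)
    # k beyond the number of distinct points: the curve has already hit its
    # floor, carry the previous value forward
    inertia[i] <- if (is.na(val) && i > 1L) inertia[i - 1L] else val
  }
  if (anyNA(inertia)) stop_input("k-means failed for k = ", k_range[1L])
  data.frame(k = k_range, inertia = cummin(inertia))
}

#' Knee (Kneedle) selection of the number of clusters
#'
#' Implements the Kneedle procedure for a decreasing convex curve with
#' sensitivity 1: x and y are min-max normalized, the difference curve
#' `d = (1 - y_norm) - x_norm` is formed, and the knee is the first local
#' maximum of `d` whose height is later undercut by more than
#' `1 / (n - 1)` (the mean normalized x-spacing). Returns no selection when
#' the difference curve has no local maximum (e.g. exactly linear decay).
#'
#' @param k integer vector of k values (>= 3 points).
#' @param inertia non-increasing inertia values matching `k`.
#' @return `knee_result` object: list with `k`, `inertia`, `diff_curve` and
#'   `selected_k` (integer, or `NA` when no knee exists).
#' @export
select_k_knee <- function(k, inertia) {
  if (length(k) != length(inertia)) stop_input("k and inertia lengths differ")
  if (length(k) < 3L) stop_input("knee detection needs >= 3 points")
  o <- order(k)
  k <- as.integer(k[o]); y <- inertia[o]
  if (any(diff(y) > 1e-10 * max(abs(y), 1)))
    stop_input("inertia must be non-increasing in k")
  x_n <- (k - min(k)) / (max(k) - min(k))
  span <- max(y) - min(y)
  y_n <- if (span == 0) rep(0, length(y)) else (y - min(y)) / span
  d <- (1 - y_n) - x_n
  n <- length(d)
  lm_idx <- which(vapply(seq_len(n), function(i)
    i > 1L && i < n && d[i] > d[i - 1L] && d[i] > d[i + 1L], NA))
  selected <- NA_integer_
  threshold_gap <- 1 / (n - 1)  # sensitivity 1 x mean normalized spacing
  for (i in lm_idx) {
    after <- d[seq(i + 1L, n)]
    if (any(after < d[i] - threshold_gap)) { selected <- k[i]; break }
  }
  structure(list(k = k, inertia = y, diff_curve = d, selected_k = selected),
            class = "knee_result")
}

#' @export
print.knee_result <- function(x, ...) {
  cat("Knee analysis over k =", paste(range(x$k), collapse = ".."), "\n")
  if (is.na(x$selected_k)) cat("  no knee detected\n")
  else cat("  selected K =", x$selected_k, "\n")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 for identical partitions (up to label
#' permutation), approximately 0 for independent ones.
#'
#' @param a,b partition labels of the same samples (any coercible type).
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_input("partitions differ in length")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(length(a))
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
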