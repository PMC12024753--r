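# Synthetic tumor cohorts with planted immune subgroups.
#
# The generator produces everything the subtyping pipeline consumes: a bulk
# expression matrix built as cell-type mixtures, per-sample driver-mutation
# status (EGFR/KRAS) with subgroup-dependent probabilities, total mutation
# counts with occasional extreme outliers, and right-censored survival times
# with subgroup-dependent exponential hazards.

#' Build cell-type signature gene sets with base expression profiles
#'
#' Each signature is a disjoint block of genes drawn from the simulated
#' genome, with strictly positive per-gene expression weights. These play the
#' role of the cell-type-specific marker sets a deconvolution method scores.
#'
#' @param n_genes total number of genes in the simulated genome.
#' @param n_cell_types number of cell types.
#' @param genes_per_set signature size per cell type.
#' @param base_level scale of per-gene signature weights (arbitrary
#'   linear-expression units).
#' @param seed integer seed; generation is a pure function of it.
#' @return An object of class `cell_type_signatures`: a named list with one
#'   element per cell type, each a list with `genes` (character) and
#'   `base_profile` (named positive numeric).
#' @export
make_signatures <- function(n_genes, n_cell_types = 8L, genes_per_set = 40L,
                            base_level = 100, seed = 42L) {
  if (n_cell_types * genes_per_set > n_genes)
    stop_input("signatures require ", n_cell_types * genes_per_set,
               " genes but the genome has only ", n_genes)
  genes <- sprintf("g%05d", seq_len(n_genes))
  with_seed(seed, {
    picked <- sample(genes, n_cell_types * genes_per_set)
    idx <- split(picked, rep(seq_len(n_cell_types), each = genes_per_set))
    sigs <- lapply(seq_len(n_cell_types), function(c) {
      g <- idx[[c]]
      w <- stats::runif(length(g), 0.5, 1.5) * base_level
      names(w) <- g
      list(genes = g, base_profile = w)
    })
    names(sigs) <- sprintf("celltype_%02d", seq_len(n_cell_types))
    structure(sigs, genome = genes, class = "cell_type_signatures")
  })
}

#' Extract plain gene sets from signatures
#'
#' @param signatures a `cell_type_signatures` object.
#' @return Named list of character vectors, as read from a GMT file.
#' @export
signature_gene_sets <- function(signatures) {
  lapply(unclass(signatures), `[[`, "genes")
}

#' Configuration of a synthetic cohort
#'
#' Defaults encode the study conditions the analysis assumes: three immune
#' subgroups with sizes proportional to the reported cluster sizes
#' (roughly 33/15/52 percent), EGFR mutation probabilities 20.1/5.3/9.5
#' percent and KRAS probabilities 32.6/21.3/29 percent per subgroup, and
#' exponential survival hazards of 0.02/0.02/0.04 events per month so one
#' subgroup has twice the baseline hazard.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param n_subgroups number of planted subgroups (>= 2).
#' @param n_cell_types,genes_per_set signature layout passed to
#'   [make_signatures()].
#' @param subgroup_props per-subgroup sample proportions (sum to 1); realized
#'   sizes are integers summing exactly to `n_samples`.
#' @param mixing_weights optional `n_subgroups x n_cell_types` matrix of mean
#'   mixture weights. Default: weight 1 everywhere, raised to 4 on a
#'   subgroup-specific block of cell types (round-robin assignment).
#' @param noise_sd standard deviation of per-entry log-scale Gaussian noise.
#' @param depth_sd standard deviation of the per-sample log-normal
#'   sequencing-depth factor (0 disables depth variation).
#' @param mutation_probs list with numeric vectors `egfr` and `kras`, one
#'   probability per subgroup.
#' @param hazard per-subgroup exponential event rate (1/month).
#' @param censor_horizon censoring times are uniform on `[0, censor_horizon]`
#'   months.
#' @param outlier_fraction fraction of samples given extreme total mutation
#'   counts (>= 10x the cohort median).
#' @param seed integer seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 300L, n_genes = 1000L, n_subgroups = 3L,
                          n_cell_types = 8L, genes_per_set = 40L,
                          subgroup_props = NULL, mixing_weights = NULL,
                          noise_sd = 0.3, depth_sd = 0.25,
                          mutation_probs = NULL,
                          hazard = NULL, censor_horizon = 120,
                          outlier_fraction = 0.01, seed = 42L) {
  n_subgroups <- as.integer(n_subgroups)
  if (n_subgroups < 2L) stop_input("n_subgroups must be >= 2")
  if (is.null(subgroup_props))
    subgroup_props <- if (n_subgroups == 3L) c(0.33, 0.15, 0.52)
      else rep(1 / n_subgroups, n_subgroups)
  if (length(subgroup_props) != n_subgroups || any(subgroup_props <= 0))
    stop_input("subgroup_props must be ", n_subgroups, " positive values")
  subgroup_props <- subgroup_props / sum(subgroup_props)
  if (is.null(mutation_probs))
    mutation_probs <- list(
      egfr = if (n_subgroups == 3L) c(0.201, 0.053, 0.095)
             else rep(0.1, n_subgroups),
      kras = if (n_subgroups == 3L) c(0.326, 0.213, 0.290)
             else rep(0.25, n_subgroups))
  for (m in names(mutation_probs)) {
    p <- mutation_probs[[m]]
    if (length(p) != n_subgroups || any(p < 0 | p > 1))
      stop_input("mutation_probs$", m, " must be ", n_subgroups,
                 " probabilities in [0, 1]")
  }
  if (is.null(hazard))
    hazard <- if (n_subgroups == 3L) c(0.02, 0.02, 0.04)
              else rep(0.02, n_subgroups)
  if (length(hazard) != n_subgroups || any(hazard <= 0))
    stop_input("hazard must be ", n_subgroups, " positive rates")
  if (is.null(mixing_weights))
    mixing_weights <- default_mixing_weights(n_subgroups, n_cell_types)
  mixing_weights <- as.matrix(mixing_weights)
  if (!identical(dim(mixing_weights), c(n_subgroups, as.integer(n_cell_types))))
    stop_input("mixing_weights must be n_subgroups x n_cell_types (",
               n_subgroups, " x ", n_cell_types, ")")
  if (any(mixing_weights < 0)) stop_input("mixing_weights must be >= 0")
  if (noise_sd < 0 || depth_sd < 0) stop_input("noise sds must be >= 0")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop_input("outlier_fraction must be in [0, 1)")
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_subgroups = n_subgroups, n_cell_types = as.integer(n_cell_types),
    genes_per_set = as.integer(genes_per_set),
    subgroup_props = subgroup_props, mixing_weights = mixing_weights,
    noise_sd = noise_sd, depth_sd = depth_sd,
    mutation_probs = mutation_probs, hazard = hazard,
    censor_horizon = censor_horizon, outlier_fraction = outlier_fraction,
    seed = as.integer(seed)), class = "cohort_config")
}

# Each subgroup up-weights its own round-robin block of cell types.
default_mixing_weights <- function(n_subgroups, n_cell_types) {
  w <- matrix(1, n_subgroups, n_cell_types)
  block <- rep(seq_len(n_subgroups), length.out = n_cell_types)
  for (s in seq_len(n_subgroups)) w[s, block == s] <- 4
  dimnames(w) <- list(sprintf("subgroup%d", seq_len(n_subgroups)),
                      sprintf("celltype_%02d", seq_len(n_cell_types)))
  w
}

# Largest-remainder apportionment: integer sizes summing exactly to n.
subgroup_sizes <- function(n, props) {
  raw <- n * props
  sizes <- floor(raw)
  short <- n - sum(sizes)
  if (short > 0) {
    bump <- order(raw - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[bump] <- sizes[bump] + 1
  }
  as.integer(sizes)
}

#' Generate a synthetic cohort
#'
#' Expression for sample `j` in subgroup `s` is
#' `sum_c w[s, c] * base_profile[g, c] * 1(g in signature c) + background[g]`,
#' multiplied by per-entry log-normal noise `exp(N(0, noise_sd))` and a
#' per-sample depth factor `exp(N(0, depth_sd))`. Mutation statuses are
#' per-subgroup Bernoulli draws; survival times are exponential with the
#' subgroup hazard, censored by an independent uniform draw on
#' `[0, censor_horizon]`. A fraction of samples receives extreme total
#' mutation counts (at least 10x the cohort median). Generation is a pure
#' function of `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param signatures optional `cell_type_signatures`; generated from the
#'   config when omitted.
#' @return An object of class `synthetic_cohort`: list with `expression`
#'   (genes x samples matrix), `signatures`, `mutations` (data.frame with
#'   `sample_id`, `egfr_status`, `kras_status`, `mutation_count`), `clinical`
#'   (data.frame with `sample_id`, `os_months`, `os_event`, `gender`,
#'   `smoker`), `truth` (named factor of planted subgroups) and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), signatures = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(signatures))
    signatures <- make_signatures(config$n_genes, config$n_cell_types,
                                  config$genes_per_set,
                                  seed = child_seed(config$seed, 1L))
  if (length(signatures) != config$n_cell_types)
    stop_input("signatures do not match config: expected ",
               config$n_cell_types, " cell types, got ", length(signatures))
  genes <- attr(signatures, "genome") %||% sprintf("g%05d", seq_len(config$n_genes))
  if (length(genes) != config$n_genes)
    stop_input("signature genome has ", length(genes),
               " genes but config$n_genes is ", config$n_genes)
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  sizes <- subgroup_sizes(n, config$subgroup_props)
  truth <- factor(rep(sprintf("subgroup%d", seq_len(config$n_subgroups)), sizes))
  names(truth) <- samples

  # genes x cell-types signal basis
  basis <- matrix(0, config$n_genes, config$n_cell_types,
                  dimnames = list(genes, names(signatures)))
  for (c in seq_along(signatures))
    basis[signatures[[c]]$genes, c] <- signatures[[c]]$base_profile

  with_seed(child_seed(config$seed, 2L), {
    background <- stats::runif(config$n_genes, 2, 20)
    mean_by_sub <- basis %*% t(config$mixing_weights) + background  # genes x subgroups
    expr <- mean_by_sub[, as.integer(truth), drop = FALSE]
    if (config$noise_sd > 0)
      expr <- expr * exp(matrix(stats::rnorm(length(expr), 0, config$noise_sd),
                                nrow(expr)))
    if (config$depth_sd > 0)
      expr <- sweep(expr, 2, exp(stats::rnorm(n, 0, config$depth_sd)), `*`)
    dimnames(expr) <- list(genes, samples)

    sub_i <- as.integer(truth)
    egfr <- stats::rbinom(n, 1, config$mutation_probs$egfr[sub_i])
    kras <- stats::rbinom(n, 1, config$mutation_probs$kras[sub_i])
    mut_count <- stats::rnbinom(n, size = 3, mu = 150)
    n_out <- floor(config$outlier_fraction * n)
    if (n_out > 0) {
      out_idx <- sample.int(n, n_out)
      med <- stats::median(mut_count)
      mut_count[out_idx] <- ceiling(med * stats::runif(n_out, 10, 20))
    }
    mutations <- data.frame(
      sample_id = samples,
      egfr_status = ifelse(egfr == 1, "mutated", "WT"),
      kras_status = ifelse(kras == 1, "mutated", "WT"),
      mutation_count = mut_count, stringsAsFactors = FALSE)

    event_time <- stats::rexp(n, rate = config$hazard[sub_i])
    censor <- stats::runif(n, 0, config$censor_horizon)
    clinical <- data.frame(
      sample_id = samples,
      os_months = pmin(event_time, censor),
      os_event = as.integer(event_time <= censor),
      gender = ifelse(stats::rbinom(n, 1, 0.5) == 1, "female", "male"),
      smoker = ifelse(stats::rbinom(n, 1, 0.6) == 1, "yes", "no"),
      stringsAsFactors = FALSE)

    structure(list(expression = expr, signatures = signatures,
                   mutations = mutations, clinical = clinical,
                   truth = truth, config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", ncol(x$expression), "samples,",
      nrow(x$expression), "genes,", nlevels(x$truth), "planted subgroups\n")
  cat("  subgroup sizes:", paste(table(x$truth), collapse = ", "), "\n")
  cat("  noise_sd =", x$config$noise_sd, " depth_sd =", x$config$depth_sd,
      " seed =", x$config$seed, "\n")
  invisible(x)
}

#' Poisson count sampling of an expression matrix
#'
#' Produces integer counts for the differential-expression stage by sampling
#' `counts[g, j] ~ Poisson(lib_size * expr[g, j] / sum_g expr[g, j])`.
#'
#' @param expr non-negative genes x samples matrix (e.g. a cohort's
#'   `expression`).
#' @param lib_size target library size per sample.
#' @param seed integer seed.
#' @return Integer matrix with the same dimnames as `expr`.
#' @export
simulate_counts <- function(expr, lib_size = 2e5, seed = 42L) {
  if (any(expr < 0)) stop_input("expression must be non-negative")
  lambda <- sweep(expr, 2, colSums(expr), `/`) * lib_size
  with_seed(seed, {
    counts <- matrix(stats::rpois(length(lambda), lambda), nrow(lambda),
                     dimnames = dimnames(expr))
    storage.mode(counts) <- "integer"
    counts
  })
}

#' Write a cohort's tables to a directory
#'
#' Writes the expression matrix, mutation and clinical tables and planted
#' truth labels as TSV, and the signatures as GMT.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             mutations = file.path(dir, "mutations.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.tsv"),
             signatures = file.path(dir, "signatures.gmt"))
  write_expression_tsv(cohort$expression, paths["expression"])
  utils::write.table(cohort$mutations, paths["mutations"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(cohort$truth),
               subgroup = as.character(cohort$truth)),
    paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(signature_gene_sets(cohort$signatures), paths["signatures"])
  invisible(paths)
}
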