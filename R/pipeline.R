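# End-to-end pipeline: simulate (optional) -> preprocess -> infer -> cluster
# -> associate -> survive -> differential expression -> misassignment, with a
# JSON run manifest. Each stage writes its artifacts before the next begins;
# rerunning with the same config and seed reproduces identical outputs.

#' Run the full subtyping pipeline
#'
#' @param config a configuration list or the path to a YAML file. Either a
#'   `simulation` block (fields of [cohort_config()]) or an `inputs` block
#'   with paths `expression`, `signatures` (GMT), `mutations`, `clinical`.
#'   Optional blocks: `preprocess` (`outlier_z_threshold`, `log_transform`,
#'   `pseudocount`), `clustering` (`n_components`, `k_range` as
#'   `[min, max]`, `k`, `min_cluster_size`, `seed`), `misassignment`
#'   (`m`, `R`, `p_threshold`, `fdr_threshold`).
#' @param outdir output directory (created if needed).
#' @param seed overrides the config seed when non-NULL.
#' @param stages subset of stage names to run (in pipeline order); later
#'   stages require earlier ones in the same call. Default: all.
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, outdir, seed = NULL,
                         stages = c("simulate", "preprocess", "infer",
                                    "cluster", "associate", "survive",
                                    "de", "misassign")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed %||% config$seed %||% 42L)
  manifest <- list(package_version = as.character(utils::packageVersion("immsubtype")),
                   seed = seed, config = config, started = format(Sys.time()),
                   stages = list(), warnings = list())
  warn <- function(stage, msg) {
    manifest$warnings[[stage]] <<- c(manifest$warnings[[stage]], msg)
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest()
      stop_input("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
    manifest$stages[[name]] <<- c(list(status = "ok"), res)
    write_manifest()
  }
  env <- new.env()

  run_stage("simulate", function() {
    if (is.null(config$simulation)) return(list(skipped = "no simulation block"))
    cc_args <- config$simulation
    cc_args$seed <- seed
    if (!is.null(cc_args$mutation_probs))
      cc_args$mutation_probs <- lapply(cc_args$mutation_probs, unlist)
    cc <- do.call(cohort_config, cc_args)
    cohort <- simulate_cohort(cc)
    paths <- write_cohort(cohort, file.path(outdir, "inputs"))
    env$cohort <- cohort
    env$inputs <- as.list(paths)
    list(files = as.list(paths),
         digests = as.list(tools::md5sum(unname(paths))))
  })

  if (is.null(env$inputs)) env$inputs <- config$inputs
  env$expr <- read_expression_tsv(env$inputs$expression)
  env$sets <- read_gmt(env$inputs$signatures)
  env$mut <- read_mutation_tsv(env$inputs$mutations)
  env$clin <- read_clinical_tsv(env$inputs$clinical)

  pp <- config$preprocess %||% list()
  run_stage("preprocess", function() {
    counts <- stats::setNames(env$mut$mutation_count, env$mut$sample_id)
    removed <- remove_mutation_outliers(counts,
                                        pp[["outlier_z_threshold"]] %||% 3)
    keep <- setdiff(colnames(env$expr), removed)
    env$expr <- env$expr[, keep, drop = FALSE]
    env$mut <- env$mut[env$mut$sample_id %in% keep, ]
    env$clin <- env$clin[env$clin$sample_id %in% keep, ]
    writeLines(removed, file.path(outdir, "removed_outliers.txt"))
    list(n_removed = length(removed), removed = as.list(removed),
         log_transform = pp[["log_transform"]] %||% TRUE,
         note = "z-score outlier rule, single pass, population sd")
  })

  run_stage("infer", function() {
    x <- if (isFALSE(pp[["log_transform"]])) env$expr
         else log_transform(env$expr, pp[["pseudocount"]] %||% 1)
    env$profiles <- score_cell_types(x, env$sets)
    write_profiles_tsv(env$profiles,
                       file.path(outdir, "immune_profiles.tsv"))
    list(n_cell_types = nrow(env$profiles))
  })

  cl <- config$clustering %||% list()
  run_stage("cluster", function() {
    k_range <- if (!is.null(cl[["k_range"]])) seq(cl[["k_range"]][[1]], cl[["k_range"]][[2]])
               else 1:10
    fit <- immune_cluster(env$expr, env$sets, k = cl[["k"]],
                          k_range = k_range,
                          n_components = cl[["n_components"]] %||% 2L,
                          min_cluster_size = cl[["min_cluster_size"]] %||% 5L,
                          log_transform = !isFALSE(pp[["log_transform"]]),
                          seed = as.integer(cl[["seed"]] %||% seed))
    env$fit <- fit
    utils::write.table(
      data.frame(sample_id = names(fit$labels),
                 label = as.character(fit$labels)),
      file.path(outdir, "assignment.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (!is.null(fit$knee))
      utils::write.table(
        data.frame(k = fit$knee$k, inertia = fit$knee$inertia,
                   diff_curve = fit$knee$diff_curve),
        file.path(outdir, "knee_curve.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    if (fit$k == 0) warn("cluster", "zero retained clusters")
    list(chosen_k = fit$k,
         knee_k = if (is.null(fit$knee)) NULL else fit$knee$selected_k,
         sizes = as.list(fit$assignment$sizes),
         n_discarded = fit$assignment$n_discarded)
  })

  run_stage("associate", function() {
    if (env$fit$k < 2) return(list(skipped = "fewer than 2 retained clusters"))
    muts <- list(
      EGFR = stats::setNames(env$mut$egfr_status, env$mut$sample_id),
      KRAS = stats::setNames(env$mut$kras_status, env$mut$sample_id))
    rep <- table2_report(cluster_labels(env$fit), muts)
    capture <- utils::capture.output(print(rep))
    writeLines(capture, file.path(outdir, "mutation_report.txt"))
    jsonlite::write_json(
      lapply(rep, function(r) list(
        counts = as.data.frame(r$table), fractions = as.list(r$fractions),
        formatted = as.list(r$formatted),
        overall_p = r$overall$p_value,
        pairwise = r$pairwise)),
      file.path(outdir, "mutation_report.json"), auto_unbox = TRUE,
      digits = NA, force = TRUE)
    list(overall_p = lapply(rep, function(r) r$overall$p_value))
  })

  run_stage("survive", function() {
    if (env$fit$k < 2) return(list(skipped = "fewer than 2 retained clusters"))
    lab <- cluster_labels(env$fit, drop_discarded = TRUE)
    clin <- env$clin[match(names(lab), env$clin$sample_id), ]
    curves <- km_by_group(clin$os_months, clin$os_event, lab)
    curve_df <- do.call(rbind, lapply(names(curves), function(g)
      cbind(group = g, curves[[g]])))
    utils::write.table(curve_df, file.path(outdir, "km_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pw <- logrank_pairwise(clin$os_months, clin$os_event, lab)
    utils::write.table(pw, file.path(outdir, "logrank_pairwise.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(pairwise_p = stats::setNames(
      as.list(pw$p_value), paste(pw$group1, pw$group2, sep = "_vs_")))
  })

  run_stage("de", function() {
    if (env$fit$k < 2) return(list(skipped = "fewer than 2 retained clusters"))
    env$counts <- simulate_counts(env$expr, seed = child_seed(seed, 99L))
    lab <- cluster_labels(env$fit, drop_discarded = TRUE)
    panel_genes <- intersect(checkpoint_panel(extended = TRUE),
                             rownames(env$expr))
    panel_res <- NULL
    if (length(panel_genes) >= 1L) {
      logx <- log_transform(env$expr)
      panel_res <- checkpoint_panel_test(logx, lab, panel_genes)
      utils::write.table(panel_res, file.path(outdir, "checkpoint_panel.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else warn("de", "no checkpoint-panel gene in the matrix")
    top2 <- names(sort(table(lab), decreasing = TRUE))[1:2]
    g <- factor(as.character(lab[lab %in% top2]), levels = top2)
    de <- nb_wald_test(env$counts[, names(lab)[lab %in% top2]], g)
    utils::write.table(de, file.path(outdir, "de_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(comparison = paste(top2, collapse = "_vs_"),
         n_significant = sum(de$p_value < 0.05 & de$q_value < 0.25),
         panel_genes_tested = length(panel_genes))
  })

  mis <- config$misassignment %||% list()
  run_stage("misassign", function() {
    if (env$fit$k < 2) return(list(skipped = "fewer than 2 retained clusters"))
    lab <- cluster_labels(env$fit, drop_discarded = TRUE)
    egfr <- stats::setNames(env$mut$egfr_status, env$mut$sample_id)
    egfr_pos <- names(egfr)[egfr == "mutated"]
    by_cluster <- split(names(lab), lab)
    eligible <- lapply(by_cluster, intersect, egfr_pos)
    sizes <- lengths(eligible)
    suspect_cluster <- names(sizes)[which.min(sizes)]
    m <- mis[["m"]] %||% max(2L, sizes[suspect_cluster])
    suspects <- eligible[[suspect_cluster]]
    results <- list()
    for (ref in setdiff(names(eligible), suspect_cluster)) {
      if (length(eligible[[ref]]) <= length(suspects) + 1L ||
          length(suspects) < 2L) {
        warn("misassign", paste0("skipping ", ref,
                                 ": too few eligible samples"))
        next
      }
      results[[ref]] <- misassignment_analysis(
        env$counts, eligible[[ref]], suspects,
        R = mis[["R"]] %||% 18L, seed = child_seed(seed, 7L),
        p_threshold = mis[["p_threshold"]] %||% 0.05,
        fdr_threshold = mis[["fdr_threshold"]] %||% 0.25)
    }
    jsonlite::write_json(
      lapply(results, function(r) list(
        observed = r$observed, null_counts = r$null$counts,
        null_mean = r$null$mean, null_sd = r$null$sd, z = r$z,
        p_normal = r$p_normal, p_empirical = r$p_empirical,
        config = r$config)),
      file.path(outdir, "misassignment.json"), auto_unbox = TRUE,
      digits = NA, force = TRUE)
    list(suspect_cluster = suspect_cluster, n_suspects = length(suspects),
         reference_clusters = names(results))
  })

  manifest$finished <- format(Sys.time())
  write_manifest()
  invisible(manifest)
}

validate_pipeline_config <- function(config) {
  if (!is.list(config)) stop_input("config must be a list or YAML path")
  if (is.null(config$simulation) && is.null(config$inputs))
    stop_input("config needs a 'simulation' or an 'inputs' block")
  if (!is.null(config$inputs)) {
    need <- c("expression", "signatures", "mutations", "clinical")
    missing <- setdiff(need, names(config$inputs))
    if (length(missing))
      stop_input("inputs block lacks: ", paste(missing, collapse = ", "))
    absent <- need[!vapply(config$inputs[need], file.exists, NA)]
    if (length(absent))
      stop_input("input file(s) not found: ",
                 paste(unlist(config$inputs[absent]), collapse = ", "))
  }
  invisible(config)
}
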