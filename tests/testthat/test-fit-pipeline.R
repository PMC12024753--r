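test_that("the fitted model object carries the full pipeline state", {
  cohort <- small_cohort(seed = 91, n = 120)
  fit <- immune_cluster(cohort$expression,
                        signature_gene_sets(cohort$signatures))
  expect_s3_class(fit, "immune_clustering")
  expect_identical(fit$knee$selected_k, fit$k + 0L)
  expect_identical(length(fitted(fit)), 120L)
  expect_identical(rownames(coef(fit)), levels(cluster_labels(fit))[
    seq_len(fit$k)])
  expect_output(print(fit), "knee-selected K")
  expect_output(print(summary(fit)), "variance explained")
  # zero-noise cohorts are recovered exactly
  clean <- simulate_cohort(cohort_config(n_samples = 90, n_genes = 400,
                                         n_cell_types = 6, genes_per_set = 25,
                                         noise_sd = 0, seed = 92))
  fit_clean <- immune_cluster(clean$expression,
                              signature_gene_sets(clean$signatures))
  expect_equal(adjusted_rand_index(cluster_labels(fit_clean), clean$truth), 1)
})

test_that("predict() assigns training samples to their own clusters", {
  cohort <- small_cohort(seed = 93, n = 100)
  sets <- signature_gene_sets(cohort$signatures)
  fit <- immune_cluster(cohort$expression, sets)
  pred <- predict(fit, cohort$expression, sets)
  lab <- cluster_labels(fit)
  keep <- lab != "discarded"
  agreement <- mean(as.character(pred[keep]) == as.character(lab[keep]))
  expect_gte(agreement, 0.95)
  # fresh samples from the same generator land in the matching clusters
  cohort2 <- small_cohort(seed = 94, n = 60)
  pred2 <- predict(fit, cohort2$expression, sets)
  expect_identical(length(pred2), 60L)
  expect_true(all(!is.na(pred2)))
})

test_that("fixing k bypasses knee selection", {
  cohort <- small_cohort(seed = 95, n = 80)
  fit <- immune_cluster(cohort$expression,
                        signature_gene_sets(cohort$signatures), k = 2)
  expect_null(fit$knee)
  expect_identical(fit$k, 2L)
})

test_that("the pipeline is deterministic end to end", {
  config <- system.file("extdata", "demo_config.yaml", package = "immsubtype")
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  m1 <- run_pipeline(config, out1, seed = 42)
  m2 <- run_pipeline(config, out2, seed = 42)
  for (f in c("assignment.tsv", "knee_curve.tsv", "immune_profiles.tsv",
              "mutation_report.txt", "logrank_pairwise.tsv",
              "de_results.tsv", "misassignment.json")) {
    expect_true(file.exists(file.path(out1, f)), info = f)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
  }
  expect_identical(m1$stages$cluster$chosen_k, 3L)
  expect_true(file.exists(file.path(out1, "manifest.json")))
  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_identical(manifest$stages$cluster$status, "ok")
})

test_that("a tiny cohort yields zero retained clusters, not a crash", {
  dir <- withr::local_tempdir()
  cohort <- small_cohort(seed = 96, n = 4)
  write_cohort(cohort, file.path(dir, "inputs"))
  config <- list(
    seed = 1,
    inputs = list(expression = file.path(dir, "inputs", "expression.tsv"),
                  signatures = file.path(dir, "inputs", "signatures.gmt"),
                  mutations = file.path(dir, "inputs", "mutations.tsv"),
                  clinical = file.path(dir, "inputs", "clinical.tsv")),
    clustering = list(k = 2))
  out <- file.path(dir, "out")
  suppressWarnings(m <- run_pipeline(config, out))
  expect_identical(m$stages$cluster$chosen_k, 0L)
  expect_identical(m$stages$cluster$n_discarded, 4L)
  expect_match(unlist(m$warnings$cluster), "zero retained")
  expect_identical(m$stages$associate$skipped,
                   "fewer than 2 retained clusters")
})

test_that("pipeline config validation catches malformed inputs", {
  expect_error(run_pipeline(list(), tempdir()), "simulation.*inputs")
  expect_error(run_pipeline(list(inputs = list(expression = "x")), tempdir()),
               "lacks")
  expect_error(
    run_pipeline(list(inputs = list(expression = "/nope", signatures = "/n",
                                    mutations = "/n", clinical = "/n")),
                 tempdir()),
    "not found")
})

test_that("the mutation report prints counts with fractions in parentheses", {
  labels <- factor(rep(c("sub0", "sub1", "sub2"), c(164, 75, 264)))
  names(labels) <- sprintf("S%03d", seq_along(labels))
  egfr <- rep("WT", length(labels))
  egfr[c(1:33, 165:168, 240:264)] <- "mutated"
  names(egfr) <- names(labels)
  rep <- table2_report(labels, list(EGFR = egfr))
  expect_identical(unname(rep$EGFR$formatted),
                   c("33 (20.1%)", "4 (5.3%)", "25 (9.5%)"))
  out <- capture.output(print(rep))
  expect_true(any(grepl("33 (20.1%)", out, fixed = TRUE)))
  expect_true(any(grepl("overall chi-square p = 0.000672", out)))
  # zero mutated anywhere: all fractions 0, overall test degenerate
  none <- table2_report(labels, list(EGFR = setNames(rep("WT", 503),
                                                     names(labels))))
  expect_identical(unname(none$EGFR$formatted),
                   rep("0 (0.0%)", 3))
  expect_true(is.na(none$EGFR$overall$p_value))
})
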