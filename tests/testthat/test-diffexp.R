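test_that("median-of-ratios size factors match closed forms", {
  m <- matrix(c(10, 40, 90, 10, 40, 90), 3,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- cbind(a = c(10, 40, 90), b = c(20, 80, 180))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # scaling one sample by c multiplies its factor by c (relative to the
  # geometric-mean renormalization shared by all samples)
  set.seed(71)
  m3 <- matrix(rpois(60, 50) + 1, 10, 6)
  sf <- size_factors(m3)
  m3c <- m3; m3c[, 3] <- m3c[, 3] * 5
  sfc <- size_factors(m3c)
  expect_equal(sfc[3] / sf[3] / (sfc[1] / sf[1]), 5, tolerance = 1e-12)
  expect_error(size_factors(rbind(c(0, 5), c(5, 0))), "no gene")
})

test_that("identical groups give zero fold change and p = 1", {
  set.seed(72)
  block <- matrix(rpois(40 * 3, 60), 40)
  counts <- cbind(block, block)  # group means equal in every gene
  rownames(counts) <- paste0("g", 1:40)
  colnames(counts) <- paste0("S", 1:6)
  de <- nb_wald_test(counts, rep(c("A", "B"), each = 3))
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$p_value == 1))
  expect_true(all(de$q_value == 1))
})

test_that("under the NB null p-values are uniform and BH finds ~0 genes", {
  set.seed(73)
  counts <- nb_count_matrix(1000, 20)
  de <- nb_wald_test(counts, rep(c("A", "B"), each = 10))
  expect_lt(abs(mean(de$p_value) - 0.5), 0.05)
  expect_lt(suppressWarnings(
    ks.test(de$p_value, "punif")$statistic), 0.08)
  # the unshrunken moment-based Wald test runs mildly anti-conservative at
  # n = 10/10, so a handful of null genes can clear the joint rule
  expect_lt(mean(de$p_value < 0.05), 0.10)
  expect_lte(sum(de$p_value < 0.05 & de$q_value < 0.25), 30)
})

test_that("a planted 4-fold change in 5% of genes is mostly recovered", {
  set.seed(74)
  counts <- nb_count_matrix(1000, 40)
  planted <- 1:50
  counts[planted, 21:40] <- matrix(
    rnbinom(50 * 20, mu = rowMeans(counts[planted, 1:20]) * 4, size = 10),
    50, 20)
  de <- nb_wald_test(counts, rep(c("A", "B"), each = 20))
  hits <- which(de$p_value < 0.05 & de$q_value < 0.25)
  expect_gte(length(intersect(hits, planted)), 40)  # >= 80% of planted genes
})

test_that("fold-change estimates absorb per-sample count rescaling", {
  set.seed(75)
  counts <- nb_count_matrix(300, 12)
  groups <- rep(c("A", "B"), each = 6)
  base <- nb_wald_test(counts, groups)
  scaled <- counts; scaled[, 4] <- scaled[, 4] * 3L
  rescaled <- nb_wald_test(scaled, groups)
  expect_equal(rescaled$log2fc, base$log2fc, tolerance = 1e-3)
})

test_that("BH step-up matches hand computation and brute force", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.04, 0.06)), c(0.015, 0.06, 0.06))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(76)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted order
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("checkpoint panel comparison handles effects, nulls and labels", {
  set.seed(77)
  n <- 60
  labels <- factor(rep(c("sub0", "sub1"), each = n / 2))
  names(labels) <- paste0("S", 1:n)
  logexpr <- matrix(rnorm(4 * n, 8), 4, n,
                    dimnames = list(c("TIGIT", "CD274", "CTLA4", "PDCD1"),
                                    names(labels)))
  logexpr["CD274", labels == "sub1"] <-
    logexpr["CD274", labels == "sub1"] + 2
  res <- checkpoint_panel_test(logexpr, labels)
  cd274 <- res[res$gene == "CD274", ]
  expect_lt(cd274$p_value, 0.001)
  expect_identical(cd274$stars, "***")
  expect_gt(cd274$log2_fc, 1.5)
  # label swap: p identical, fold change negated
  swapped <- factor(ifelse(labels == "sub0", "sub1", "sub0"))
  names(swapped) <- names(labels)
  res_sw <- checkpoint_panel_test(logexpr, swapped)
  expect_equal(res_sw$p_value, res$p_value)
  expect_equal(res_sw$log2_fc, -res$log2_fc)
  # missing panel genes are skipped with a warning
  expect_warning(res2 <- checkpoint_panel_test(logexpr, labels,
                                               panel = c("TIGIT", "NOPE")),
                 "NOPE")
  expect_identical(unique(res2$gene), "TIGIT")
})

test_that("identical cluster columns give fold change 0, p 1, no star", {
  labels <- factor(rep(c("sub0", "sub1"), each = 3))
  names(labels) <- paste0("S", 1:6)
  logexpr <- matrix(rep(c(5, 6, 7), 2), 1, 6,
                    dimnames = list("TIGIT", names(labels)))
  res <- checkpoint_panel_test(logexpr, labels, panel = "TIGIT")
  expect_equal(res$log2_fc, 0)
  expect_gt(res$p_value, 0.9)
  expect_identical(res$stars, "")
})

test_that("a 2-sd shift at n = 30/30 is essentially always starred ***", {
  set.seed(78)
  labels <- factor(rep(c("sub0", "sub1"), each = 30))
  names(labels) <- paste0("S", 1:60)
  hits <- sum(replicate(100, {
    logexpr <- matrix(c(rnorm(30, 8), rnorm(30, 10)), 1, 60,
                      dimnames = list("TIGIT", names(labels)))
    checkpoint_panel_test(logexpr, labels, panel = "TIGIT")$p_value < 0.001
  }))
  expect_gte(hits, 99)
})

test_that("significance stars follow the printed thresholds", {
  labels <- factor(rep(c("sub0", "sub1"), each = 30))
  names(labels) <- paste0("S", 1:60)
  expect_identical(immsubtype:::significance_stars(
    c(5e-4, 5e-3, 0.04, 0.2)), c("***", "**", "*", ""))
})
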