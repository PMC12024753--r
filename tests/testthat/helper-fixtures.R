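# Shared fixtures and independent brute-force oracles used across tests.

# Printed cluster-by-mutation distribution used throughout the package docs.
table2_egfr <- function() {
  m <- rbind(sub0 = c(131, 33), sub1 = c(71, 4), sub2 = c(239, 25))
  colnames(m) <- c("WT", "mutated")
  m
}
table2_kras <- function() {
  m <- rbind(sub0 = c(178, 86), sub1 = c(59, 16), sub2 = c(116, 48))
  colnames(m) <- c("WT", "mutated")
  m
}

small_cohort <- function(seed = 1, n = 90, ...) {
  simulate_cohort(cohort_config(n_samples = n, n_genes = 400,
                                n_cell_types = 6, genes_per_set = 25,
                                seed = seed, ...))
}

# --- independent oracles (deliberately naive implementations) ---

chisq_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

fisher_oracle_p <- function(tab) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - m2):min(c1, m1)
  probs <- stats::dhyper(support, m1, m2, c1)
  p_obs <- stats::dhyper(a, m1, m2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Product-limit estimator: deaths processed before censorings at tied times.
km_oracle <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    at_risk <- sum(time >= times[i])
    d <- sum(time == times[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = times, surv = surv)
}

# Two-group log-rank: O/E/V accumulated over pooled event times.
logrank_oracle <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(NA_real_)
  (O - E)^2 / V
}

# NB counts with gamma-distributed gene means, one homogeneous population.
nb_count_matrix <- function(n_genes, n_samples, dispersion = 0.1,
                            mean_range = c(20, 200)) {
  mu <- stats::runif(n_genes, mean_range[1], mean_range[2])
  m <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu,
                             size = 1 / dispersion),
              n_genes, n_samples,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_samples))))
  m
}
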