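# Kaplan-Meier estimation and pairwise log-rank comparison.

#' Kaplan-Meier product-limit survival curve
#'
#' Wraps [survival::survfit()] for a single group. Deaths at a tied time are
#' processed together before censorings at the same time. A censored-only
#' dataset yields the constant curve 1. Records with missing time or event
#' are excluded; the count of exclusions is attached as an attribute.
#'
#' @param time follow-up times in months (>= 0).
#' @param event binary event indicator (1 = death observed).
#' @return `km_curve` data.frame with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @export
kaplan_meier <- function(time, event) {
  keep <- !is.na(time) & !is.na(event)
  n_excluded <- sum(!keep)
  time <- time[keep]; event <- as.integer(event[keep])
  if (!length(time)) stop_input("no usable survival records")
  if (any(time < 0)) stop_input("negative survival times")
  if (!all(event %in% 0:1)) stop_input("event flag must be binary")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  attr(out, "n") <- length(time)
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Kaplan-Meier curves per group
#'
#' @param time,event as in [kaplan_meier()].
#' @param group per-sample group labels.
#' @return Named list of `km_curve` objects.
#' @export
km_by_group <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  lapply(split(seq_along(time), group),
         function(i) kaplan_meier(time[i], event[i]))
}

#' Pairwise two-group log-rank tests
#'
#' For each pair of groups, the standard log-rank chi-square
#' `(O1 - E1)^2 / V` accumulated over distinct pooled event times with the
#' hypergeometric variance (df = 1), via [survival::survdiff()]. Pairs with
#' zero pooled events are reported as missing. Records with missing
#' time/event are excluded.
#'
#' @param time,event survival records.
#' @param group per-sample group labels (>= 2 groups).
#' @param p_adjust multiplicity correction across pairs passed to
#'   [stats::p.adjust()] (default `"none"`; the raw pairwise p-values are
#'   the primary output).
#' @return data.frame with `group1`, `group2`, `statistic`, `p_value`,
#'   `p_adjusted`.
#' @export
logrank_pairwise <- function(time, event, group, p_adjust = "none") {
  keep <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[keep]; event <- as.integer(event[keep])
  group <- droplevels(factor(group[keep]))
  if (nlevels(group) < 2L) stop_input("need >= 2 groups")
  if (any(time < 0)) stop_input("negative survival times")
  pairs <- utils::combn(levels(group), 2L)
  res <- apply(pairs, 2L, function(p) {
    i <- group %in% p
    if (sum(event[i]) == 0) return(c(NA_real_, NA_real_))
    sd <- survival::survdiff(
      survival::Surv(time[i], event[i]) ~ droplevels(group[i]))
    c(sd$chisq, stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
  })
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    statistic = res[1L, ], p_value = res[2L, ],
                    stringsAsFactors = FALSE)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' Plot Kaplan-Meier curves per group
#'
#' Thin base-graphics step-function rendering of [km_by_group()] output.
#'
#' @param curves named list of `km_curve` objects.
#' @param ... passed to [graphics::plot()].
#' @export
plot_km <- function(curves, ...) {
  xmax <- max(vapply(curves, function(cv) max(cv$time, 0), 0))
  cols <- grDevices::hcl.colors(length(curves), "Dark 3")
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "months", ylab = "survival probability", ...)
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    graphics::lines(stats::stepfun(cv$time, c(1, cv$surv)), col = cols[i],
                    do.points = FALSE)
  }
  graphics::legend("bottomleft", legend = names(curves), col = cols, lty = 1)
  invisible(curves)
}
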