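#' Kaplan-Meier curve for one group
#'
#' Product-limit estimate of post-sorting survival; censored individuals
#' leave the risk set at their censor time, and deaths are processed before
#' censorings tied at the same day (standard convention).
#'
#' @param tab Survival table (see [read_survival()]).
#' @param group Group label to estimate.
#' @return data.frame `time`, `n_risk`, `n_event`, `n_censor`, `surv`
#'   (rows at event/censor times), with attribute `group`.
#' @export
km_curve <- function(tab, group) {
  validate_survival(tab)
  sub <- tab[tab$group == group, , drop = FALSE]
  if (!nrow(sub)) stop_physage("no records for group '%s'", group)
  if (!any(sub$event == "death"))
    stop_physage("group '%s' has no death events; estimator undefined", group)
  fit <- survival::survfit(
    survival::Surv(sub$day, sub$event == "death") ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  attr(out, "group") <- group
  out
}

#' Log-rank (Mantel-Cox) test between two groups
#'
#' @param tab Survival table.
#' @param group_a,group_b Group labels to compare.
#' @return List with `chi2` and `p` (chi-square, 1 df).
#' @export
logrank_test <- function(tab, group_a, group_b) {
  validate_survival(tab)
  if (identical(group_a, group_b))
    stop_physage("log-rank test needs two distinct groups")
  sub <- tab[tab$group %in% c(group_a, group_b), , drop = FALSE]
  for (g in c(group_a, group_b)) {
    if (!any(sub$group == g & sub$event == "death"))
      stop_physage("group '%s' has no death events", g)
  }
  sd <- survival::survdiff(
    survival::Surv(day, event == "death") ~ group, data = sub)
  chi2 <- sd$chisq
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Median survival: first time at which S(t) <= 0.5.
km_median <- function(curve) {
  idx <- which(curve$surv <= 0.5)
  if (!length(idx))
    stop_physage("survival never reaches 0.5; median undefined")
  curve$time[idx[1L]]
}

#' Percent difference in median lifespan between two KM curves
#'
#' `100 * (median_a - median_b) / median_b`, with the median defined as the
#' first time the survival curve drops to 0.5 or below.
#'
#' @param curve_a,curve_b KM curves from [km_curve()].
#' @return Percent difference (scalar).
#' @export
median_diff <- function(curve_a, curve_b) {
  ma <- km_median(curve_a)
  mb <- km_median(curve_b)
  100 * (ma - mb) / mb
}

#' Survival summary for all sorted marker groups
#'
#' For every marker with `<marker>_high` / `<marker>_low` groups in the
#' table: the log-rank chi-square and p-value, group medians, and the
#' percent difference in median lifespan (predicted long-lived minus
#' predicted short-lived).
#'
#' @param tab Survival table.
#' @param markers Named vector of marker signs (+1: high fluorescence
#'   predicts long life).
#' @return data.frame, one row per marker.
#' @export
survival_summary <- function(tab, markers) {
  rows <- lapply(names(markers), function(m) {
    hi <- paste0(m, "_high")
    lo <- paste0(m, "_low")
    lr <- logrank_test(tab, hi, lo)
    ch <- km_curve(tab, hi)
    cl <- km_curve(tab, lo)
    long_curve <- if (markers[[m]] > 0) ch else cl
    short_curve <- if (markers[[m]] > 0) cl else ch
    data.frame(marker = m, chi2 = lr$chi2, p = lr$p,
               median_high = km_median(ch), median_low = km_median(cl),
               median_diff_pct = median_diff(long_curve, short_curve),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
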