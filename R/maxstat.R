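## Maximally selected rank statistics for survival-driven dichotomization:
## the standardized two-group log-rank statistic is scanned over all
## admissible candidate cutpoints and the maximizing cut is selected.

#' Candidate cutpoints for maximally selected statistics
#'
#' Midpoints between consecutive sorted unique values, restricted so each
#' induced split leaves at least an `eps` fraction of cases on both
#' sides.
#'
#' @param values Numeric vector of at least 10 values.
#' @param eps Quantile margin in (0, 0.5); default 0.1.
#' @return Sorted numeric vector of candidate cutpoints.
#' @export
candidate_cutpoints <- function(values, eps = 0.1) {
  if (length(values) < 10) stop("need at least 10 values")
  if (eps <= 0 || eps >= 0.5) stop("`eps` must lie in (0, 0.5)")
  u <- sort(unique(values))
  if (length(u) < 2) stop("all values identical; no cutpoint exists")
  mids <- (u[-1] + u[-length(u)]) / 2
  n <- length(values)
  keep <- vapply(mids, function(cut) {
    lo <- sum(values <= cut)
    min(lo, n - lo) >= eps * n
  }, logical(1))
  if (!any(keep))
    stop("no candidate cutpoint satisfies the eps-quantile margin")
  mids[keep]
}

## O - E and hypergeometric variance of the log-rank statistic, group 1 =
## `above` TRUE. Ties handled by the standard discrete-time correction.
.logrank_oe <- function(above, time, event) {
  et <- sort(unique(time[event == 1]))
  oe <- v <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & above)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & above)
    oe <- oe + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(oe = oe, v = v)
}

#' Standardized two-group log-rank statistic
#'
#' `z = (O - E) / sqrt(V)` over the distinct event times: observed minus
#' expected events in group 1 (the cases with `above = TRUE`, i.e. above
#' the cutpoint), with the hypergeometric variance. Positive `z` means
#' group 1 experienced more events than expected.
#'
#' @param above Logical vector: group-1 membership per case.
#' @param time Positive survival/censoring times.
#' @param event Event indicators (1 = observed, 0 = censored).
#' @return Scalar standardized statistic.
#' @export
logrank_z <- function(above, time, event) {
  if (length(unique(above)) < 2) stop("both groups must be non-empty")
  if (any(time <= 0)) stop("times must be positive")
  if (sum(event) < 1) stop("at least one event is required")
  s <- .logrank_oe(as.logical(above), time, event)
  if (s$v <= 0) stop("log-rank variance is zero; statistic undefined")
  s$oe / sqrt(s$v)
}

## Miller-Siegmund / Lausen-Schumacher style improved-Bonferroni normal
## approximation for P(max |Z| > b) over the [eps, 1-eps] candidate band.
.p_maxstat_approx <- function(b, eps) {
  if (b <= 0) return(1)
  q <- (1 - eps) * (1 - eps) / (eps * eps)
  p <- stats::dnorm(b) * (b - 1 / b) * log(q) + 4 * stats::dnorm(b) / b
  min(1, max(p, 2 * stats::pnorm(-b)))
}

#' Maximally selected log-rank cutpoint
#'
#' Computes `|z|` of [logrank_z()] at every admissible candidate
#' cutpoint and selects the maximizer; ties break toward the smaller
#' cutoff. Candidates where the statistic is undefined (degenerate
#' variance) are skipped.
#'
#' @param values Continuous marker values (e.g. positive-cell ratios).
#' @param time,event Survival outcome per case.
#' @param eps Quantile margin for [candidate_cutpoints()].
#' @param p_approx Also report an approximate multiplicity-adjusted
#'   p-value (improved-Bonferroni normal approximation; approximate by
#'   construction).
#' @return Object of class `maxstat_cutpoint`: list with `cutoff`,
#'   `max_statistic` (the maximal `|z|`), `z_at_cutoff` (signed), `eps`,
#'   `grid` (data.frame `cutoff`, `z`, `abs_z`) and optionally
#'   `p_value_approx`.
#' @export
maxstat_cutpoint <- function(values, time, event, eps = 0.1,
                             p_approx = FALSE) {
  if (length(values) != length(time) || length(values) != length(event))
    stop("`values`, `time` and `event` must have equal length")
  cand <- candidate_cutpoints(values, eps)
  z <- vapply(cand, function(cut) {
    above <- values > cut
    s <- .logrank_oe(above, time, event)
    if (s$v <= 0) NA_real_ else s$oe / sqrt(s$v)
  }, numeric(1))
  ok <- is.finite(z)
  if (!any(ok)) stop("log-rank statistic undefined at every candidate")
  best <- which(ok)[which.max(abs(z[ok]))]  # which.max -> smallest index on ties
  out <- list(
    cutoff = cand[best],
    max_statistic = abs(z[best]),
    z_at_cutoff = z[best],
    eps = eps,
    grid = data.frame(cutoff = cand, z = z, abs_z = abs(z))
  )
  if (p_approx)
    out$p_value_approx <- .p_maxstat_approx(out$max_statistic, eps)
  class(out) <- "maxstat_cutpoint"
  out
}

#' @export
print.maxstat_cutpoint <- function(x, ...) {
  cat("Maximally selected log-rank cutpoint\n")
  cat(sprintf("  cutoff: %.6g  (eps = %.2f, %d candidates)\n",
              x$cutoff, x$eps, nrow(x$grid)))
  cat(sprintf("  max |z|: %.4f (signed z at cutoff: %.4f)\n",
              x$max_statistic, x$z_at_cutoff))
  if (!is.null(x$p_value_approx))
    cat(sprintf("  approx. adjusted p: %.4g (improved-Bonferroni approximation)\n",
                x$p_value_approx))
  invisible(x)
}
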