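## Four-quadrant tumor-immune-microenvironment typing from dichotomized
## PD-L1 and CD8 positive-cell ratios, plus the cohort-level statistics
## built on top of it: contingency/chi-square, Kruskal-Wallis,
## ratio-mRNA correlation and Kaplan-Meier/log-rank by TME type.

TME_LEVELS <- c("I", "II", "III", "IV")

#' Cutoff pair for PD-L1 and CD8 ratio dichotomization
#'
#' @param pdl1_cutoff,cd8_cutoff Ratio cutoffs, each in (0, 1). "High"
#'   is a ratio strictly greater than the cutoff.
#' @return A `tme_cutoffs` list.
#' @export
tme_cutoffs <- function(pdl1_cutoff, cd8_cutoff) {
  if (pdl1_cutoff <= 0 || pdl1_cutoff >= 1 ||
      cd8_cutoff <= 0 || cd8_cutoff >= 1)
    stop("cutoffs must lie in (0, 1)")
  structure(list(pdl1_cutoff = pdl1_cutoff, cd8_cutoff = cd8_cutoff),
            class = "tme_cutoffs")
}

#' Classify one case into a TME quadrant
#'
#' Type I = PD-L1 high & CD8 high; II = both low; III = PD-L1 high &
#' CD8 low; IV = PD-L1 low & CD8 high. "High" is strict `>` at the
#' cutoff, so a ratio exactly at the cutoff is low.
#'
#' @param pdl1_ratio,cd8_ratio Ratios in \[0, 1\] (vectorized).
#' @param cutoffs A [tme_cutoffs()].
#' @return Factor with levels `I`, `II`, `III`, `IV`.
#' @export
classify_tme <- function(pdl1_ratio, cd8_ratio, cutoffs) {
  if (any(pdl1_ratio < 0 | pdl1_ratio > 1 | cd8_ratio < 0 | cd8_ratio > 1,
          na.rm = FALSE))
    stop("ratios must lie in [0, 1]")
  p_high <- pdl1_ratio > cutoffs$pdl1_cutoff
  c_high <- cd8_ratio > cutoffs$cd8_cutoff
  type <- ifelse(p_high & c_high, "I",
          ifelse(!p_high & !c_high, "II",
          ifelse(p_high, "III", "IV")))
  factor(type, levels = TME_LEVELS)
}

#' Classify a cohort and tabulate quadrant composition
#'
#' @param cases data.frame with `pdl1_ratio` and `cd8_ratio` columns.
#' @param cutoffs A [tme_cutoffs()].
#' @return List with `cases` (input plus `tme_type`), `counts` (named
#'   integer vector over types I-IV), `percentages` (100 x count / N,
#'   rounded half-up to one decimal) and the marginal totals
#'   `pdl1_high`, `cd8_high`.
#' @export
classify_cohort <- function(cases, cutoffs) {
  if (nrow(cases) == 0) stop("cohort is empty")
  cases$tme_type <- classify_tme(cases$pdl1_ratio, cases$cd8_ratio, cutoffs)
  counts <- table(cases$tme_type)
  n <- nrow(cases)
  pct <- floor(1000 * as.numeric(counts) / n + 0.5) / 10  # round half-up
  names(pct) <- names(counts)
  list(
    cases = cases,
    counts = stats::setNames(as.integer(counts), names(counts)),
    percentages = pct,
    pdl1_high = as.integer(counts["I"] + counts["III"]),
    cd8_high = as.integer(counts["I"] + counts["IV"])
  )
}

#' Contingency table of TME type against a categorical variable
#'
#' @param cases Typed cohort (with `tme_type`).
#' @param row_variable Column name of the categorical variable.
#' @return List with `table` (variable levels x TME types, zero columns
#'   retained) and `n_excluded` (cases with a missing variable value).
#' @export
tme_contingency <- function(cases, row_variable) {
  if (!row_variable %in% names(cases))
    stop(sprintf("variable '%s' not present in the cohort", row_variable))
  v <- cases[[row_variable]]
  miss <- is.na(v)
  if (any(miss))
    message(sprintf("excluding %d cases with missing '%s'", sum(miss),
                    row_variable))
  tab <- table(v[!miss], factor(cases$tme_type[!miss], levels = TME_LEVELS))
  list(table = unclass(tab), n_excluded = sum(miss))
}

#' Pearson chi-square test of independence
#'
#' `X^2 = sum (O - E)^2 / E` with `E = row x col / N`;
#' `df = (r - 1)(c - 1)`; p from the upper chi-square tail.
#'
#' @param tab Numeric matrix of counts.
#' @return List `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0))
    stop(sprintf("zero marginal in row %s", which(rs == 0)[1]))
  if (any(cs == 0))
    stop(sprintf("zero marginal in column %s", which(cs == 0)[1]))
  e <- outer(rs, cs) / n
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = e)
}

#' Kruskal-Wallis rank test across groups
#'
#' Standard rank-based H with the tie correction; p from the chi-square
#' distribution with k - 1 degrees of freedom.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length (>= 2 non-empty
#'   groups).
#' @return List `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need at least two non-empty groups")
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ni <- tabulate(groups)
  h <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) h <- h / corr
  list(statistic = h, df = k - 1L,
       p_value = stats::pchisq(h, k - 1L, lower.tail = FALSE))
}

#' Correlation between positive-cell ratio and mRNA expression
#'
#' @param cases data.frame with `<marker>_ratio` and `mrna_<marker>`
#'   columns.
#' @param marker `"pdl1"` or `"cd8"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List `r`, `n_used`, `n_excluded` (missing pairs dropped).
#' @export
ratio_mrna_correlation <- function(cases, marker = c("pdl1", "cd8"),
                                   method = c("pearson", "spearman")) {
  marker <- match.arg(marker)
  method <- match.arg(method)
  x <- cases[[paste0(marker, "_ratio")]]
  y <- cases[[paste0("mrna_", marker)]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 complete ratio/mRNA pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("zero variance; correlation undefined")
  list(r = stats::cor(x[ok], y[ok], method = method),
       n_used = sum(ok), n_excluded = sum(!ok))
}

#' Kaplan-Meier curves and log-rank comparison of two TME types
#'
#' Product-limit survival estimates per group (via
#' [survival::survfit()]) and the two-group log-rank p-value computed
#' from the squared standardized statistic of [logrank_z()].
#'
#' @param cases Typed cohort with survival columns (`os_time`,
#'   `os_event`, `dfs_time`, `dfs_event`).
#' @param endpoint `"OS"` or `"DFS"`.
#' @param type_a,type_b The two TME types to compare.
#' @return List with `curves` (data.frame `tme_type`, `time`, `surv`,
#'   `n_risk`, `n_event`), `z`, `p_value`.
#' @export
km_logrank_by_type <- function(cases, endpoint = c("OS", "DFS"),
                               type_a = "I", type_b = "IV") {
  endpoint <- match.arg(endpoint)
  tcol <- if (endpoint == "OS") "os_time" else "dfs_time"
  ecol <- if (endpoint == "OS") "os_event" else "dfs_event"
  sub <- cases[cases$tme_type %in% c(type_a, type_b), ]
  if (!all(c(type_a, type_b) %in% sub$tme_type))
    stop("both TME types must be represented")
  time <- sub[[tcol]]; event <- sub[[ecol]]
  grp <- factor(as.character(sub$tme_type), levels = c(type_a, type_b))
  fit <- survival::survfit(survival::Surv(time, event) ~ grp)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(
    tme_type = sub("^grp=", "", strata),
    time = fit$time, surv = fit$surv,
    n_risk = fit$n.risk, n_event = fit$n.event
  )
  if (sum(event) == 0)
    return(list(curves = curves, z = NA_real_, p_value = NA_real_))
  z <- logrank_z(grp == type_b, time, event)
  list(curves = curves, z = z,
       p_value = stats::pchisq(z^2, 1, lower.tail = FALSE))
}
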