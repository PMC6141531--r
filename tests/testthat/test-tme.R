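test_that("quadrant classification follows the strict-cutoff convention", {
  cuts <- published_cutoffs()
  expect_equal(as.character(classify_tme(0.19, 0.25, cuts)), "I")
  expect_equal(as.character(classify_tme(0.06, 0.18, cuts)), "IV")
  expect_equal(as.character(classify_tme(0.10, 0.16, cuts)), "II")
  expect_equal(as.character(classify_tme(0.15, 0.10, cuts)), "III")
  # boundary equality is low
  expect_equal(as.character(classify_tme(0.136441, 0.25, cuts)), "IV")
  expect_equal(as.character(classify_tme(0.19, 0.1636454, cuts)), "III")
  expect_error(classify_tme(1.2, 0.5, cuts), "\\[0, 1\\]")
  expect_error(tme_cutoffs(0, 0.5))
})

test_that("cohort classification reproduces the published quadrant bookkeeping", {
  cls <- classify_cohort(table2_cohort(), published_cutoffs())
  expect_equal(cls$counts, c(I = 45L, II = 106L, III = 8L, IV = 82L))
  expect_equal(unname(cls$percentages), c(18.7, 44.0, 3.3, 34.0))
  expect_equal(sum(cls$counts), 241)
  expect_equal(cls$pdl1_high, 53L)
  expect_equal(cls$cd8_high, 127L)
  # marginal consistency
  expect_equal(cls$pdl1_high,
               sum(cls$cases$pdl1_ratio > published_cutoffs()$pdl1_cutoff))
  # single-case cohort -> 100% in its quadrant
  one <- classify_cohort(data.frame(pdl1_ratio = 0.5, cd8_ratio = 0.5),
                         published_cutoffs())
  expect_equal(unname(one$percentages), c(100, 0, 0, 0))
})

test_that("raising the PD-L1 cutoff never increases the PD-L1-high total", {
  co <- table2_cohort()
  highs <- vapply(c(0.05, 0.1, 0.136441, 0.2, 0.5), function(cp)
    classify_cohort(co, tme_cutoffs(cp, 0.1636454))$pdl1_high, integer(1))
  expect_true(all(diff(highs) <= 0))
})

test_that("contingency tables keep marginals and flag missing values", {
  co <- table2_cohort()
  cls <- classify_cohort(co, published_cutoffs())
  ct <- tme_contingency(cls$cases, "ebv")
  expect_equal(unname(ct$table["Positive", ]), c(20, 8, 3, 9))
  expect_equal(unname(ct$table["Negative", ]), c(25, 98, 5, 73))
  expect_equal(sum(ct$table), 241)
  # empty level retained as a zero column
  sub <- cls$cases[cls$cases$tme_type != "III", ]
  ct2 <- tme_contingency(sub, "ebv")
  expect_equal(unname(colSums(ct2$table)["III"]), 0)
  # missing values excluded and counted
  cls$cases$ebv[1:5] <- NA
  expect_message(ct3 <- tme_contingency(cls$cases, "ebv"), "5")
  expect_equal(ct3$n_excluded, 5)
})

test_that("the chi-square statistic matches closed forms and stats::chisq.test", {
  # table equal to its expected counts -> statistic 0, p = 1
  t0 <- outer(c(10, 20), c(3, 7)) / 10
  r0 <- pearson_chi2(t0)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)
  # published EBV x TME rows
  tab <- rbind(c(20, 8, 3, 9), c(25, 98, 5, 73))
  r <- pearson_chi2(tab)
  expect_equal(r$statistic, 35.88, tolerance = 0.005)
  expect_equal(r$df, 3L)
  # diagonal 2x2 closed form
  r2 <- pearson_chi2(rbind(c(10, 0), c(0, 10)))
  expect_equal(r2$statistic, 20)
  expect_equal(r2$df, 1L)
  # brute-force / reference agreement on random tables
  set.seed(71)
  for (i in 1:50) {
    tt <- matrix(rpois(12, 8) + 1, 3, 4)
    mine <- pearson_chi2(tt)
    ref <- suppressWarnings(chisq.test(tt, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
    # double-loop brute force
    e <- outer(rowSums(tt), colSums(tt)) / sum(tt)
    acc <- 0
    for (a in 1:3) for (bb in 1:4) acc <- acc + (tt[a, bb] - e[a, bb])^2 / e[a, bb]
    expect_equal(mine$statistic, acc, tolerance = 1e-10)
  }
  expect_error(pearson_chi2(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("the Kruskal-Wallis H matches closed forms and stats::kruskal.test", {
  # identical group distributions -> H = 0
  expect_equal(kruskal_wallis(rep(1:5, 2), rep(c("a", "b"), each = 5))$statistic,
               0, tolerance = 1e-12)
  # fully separated groups attain the no-overlap closed-form maximum
  v <- c(1:4, 11:14, 21:24); g <- rep(1:3, each = 4)
  mine <- kruskal_wallis(v, g)
  ref <- kruskal.test(v, g)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  # reference agreement on random data with ties
  set.seed(72)
  for (i in 1:50) {
    n <- sample(20:50, 1)
    vv <- sample(round(rnorm(n), 1))  # induces ties
    gg <- sample(1:3, n, replace = TRUE)
    if (length(unique(gg)) < 2) gg[1:2] <- 1:2
    m <- kruskal_wallis(vv, gg)
    r <- kruskal.test(vv, gg)
    expect_equal(m$statistic, unname(r$statistic), tolerance = 1e-8)
    expect_equal(m$p_value, r$p.value, tolerance = 1e-8)
  }
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "two")
})

test_that("subtype ratio distributions differ as generated", {
  co <- sample_cohort(seed = 73)
  kw <- kruskal_wallis(co$true_pdl1_fraction, co$subtype)
  expect_lt(kw$p_value, 0.001)
})

test_that("ratio-mRNA correlation handles identity, independence, missingness", {
  d <- data.frame(pdl1_ratio = seq(0.01, 0.99, length.out = 50))
  d$mrna_pdl1 <- d$pdl1_ratio
  expect_equal(ratio_mrna_correlation(d, "pdl1")$r, 1)
  set.seed(74)
  d2 <- data.frame(pdl1_ratio = runif(400), mrna_pdl1 = rnorm(400))
  expect_lt(abs(ratio_mrna_correlation(d2, "pdl1")$r), 3 / sqrt(400))
  d2$mrna_pdl1[1:10] <- NA
  rr <- ratio_mrna_correlation(d2, "pdl1")
  expect_equal(rr$n_excluded, 10)
  expect_equal(rr$n_used, 390)
  d3 <- data.frame(pdl1_ratio = rep(0.5, 10), mrna_pdl1 = rnorm(10))
  expect_error(ratio_mrna_correlation(d3, "pdl1"), "variance")
  # spearman flag
  expect_equal(ratio_mrna_correlation(d, "pdl1", method = "spearman")$r, 1)
})

test_that("Kaplan-Meier by TME type matches survdiff and degenerate cases", {
  set.seed(75)
  n <- 120
  cases <- data.frame(
    pdl1_ratio = runif(n), cd8_ratio = runif(n),
    os_time = rexp(n, 0.1), os_event = rbinom(n, 1, 0.7),
    dfs_time = rexp(n, 0.1), dfs_event = rbinom(n, 1, 0.7)
  )
  cls <- classify_cohort(cases, tme_cutoffs(0.5, 0.5))
  km <- km_logrank_by_type(cls$cases, "OS", "I", "IV")
  sub <- cls$cases[cls$cases$tme_type %in% c("I", "IV"), ]
  ref <- survival::survdiff(survival::Surv(os_time, os_event) ~ tme_type,
                            data = sub)
  expect_equal(km$z^2, ref$chisq, tolerance = 1e-8)
  expect_equal(km$p_value,
               pchisq(ref$chisq, 1, lower.tail = FALSE), tolerance = 1e-8)
  expect_true(all(km$curves$surv >= 0 & km$curves$surv <= 1))
  # no events at all -> flat curves, NA statistic
  cases0 <- cases; cases0$os_event <- 0
  cls0 <- classify_cohort(cases0, tme_cutoffs(0.5, 0.5))
  km0 <- km_logrank_by_type(cls0$cases, "OS", "I", "IV")
  expect_true(all(km0$curves$surv == 1))
  expect_true(is.na(km0$p_value))
  # identical groups -> statistic ~ 0, p ~ 1
  dup <- rbind(sub, sub)
  dup$tme_type <- rep(c("I", "IV"), each = nrow(sub))
  dup$os_time <- rep(sub$os_time, 2); dup$os_event <- rep(sub$os_event, 2)
  km1 <- km_logrank_by_type(dup, "OS", "I", "IV")
  expect_equal(km1$z, 0, tolerance = 1e-12)
  expect_equal(km1$p_value, 1, tolerance = 1e-8)
})
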