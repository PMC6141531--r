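test_that("moment-matched Beta reproduces requested mean and sd", {
  # uniform case
  expect_equal(moment_match_beta(0.5, sqrt(1 / 12)),
               c(alpha = 1, beta = 1), tolerance = 1e-12)
  # closed-form moment equations at the published subtype summaries
  for (ms in list(c(0.19, 0.13), c(0.06, 0.06), c(0.25, 0.14))) {
    ab <- moment_match_beta(ms[1], ms[2])
    expect_true(all(ab > 0))
    expect_equal(ab[["alpha"]] / sum(ab), ms[1], tolerance = 1e-12)
    expect_equal(sqrt(prod(ab) / (sum(ab)^2 * (sum(ab) + 1))), ms[2],
                 tolerance = 1e-12)
  }
  # Monte-Carlo check that samples actually follow the matched law
  ab <- moment_match_beta(0.19, 0.13)
  set.seed(1)
  x <- rbeta(2e5, ab[1], ab[2])
  expect_lt(abs(mean(x) - 0.19), 3 * 0.13 / sqrt(2e5))
  expect_lt(abs(sd(x) - 0.13), 0.005)
})

test_that("infeasible Beta moments raise an error naming the bound", {
  expect_error(moment_match_beta(0.19, 0.45), "feasib|sd\\^2")
  expect_error(moment_match_beta(0, 0.1), "\\(0, 1\\)")
  expect_error(moment_match_beta(0.5, 0), "sd")
})

test_that("sample_cohort reproduces the cohort structure deterministically", {
  co <- sample_cohort(n_per_subtype = c(40, 76, 125), corr_mrna = 0.7,
                      seed = 1)
  expect_equal(nrow(co), 241)
  expect_equal(as.numeric(table(factor(co$subtype,
                                       c("EBVpos", "MSIH", "MSS")))),
               c(40, 76, 125))
  expect_true(all(co$true_pdl1_fraction >= 0 & co$true_pdl1_fraction <= 1))
  expect_true(all(co$os_time > 0 & co$dfs_time > 0))
  expect_true(all(co$n_nuclei >= 64 & co$n_nuclei <= 128))
  # same seed twice -> identical tables
  expect_identical(co, sample_cohort(n_per_subtype = c(40, 76, 125),
                                     corr_mrna = 0.7, seed = 1))
  # different seed -> different draw
  co2 <- sample_cohort(seed = 2)
  expect_false(identical(co$true_pdl1_fraction, co2$true_pdl1_fraction))
})

test_that("mRNA coupling hits the requested correlation", {
  co <- sample_cohort(n_per_subtype = c(300, 300, 300), corr_mrna = 0.7,
                      seed = 3)
  expect_equal(cor(co$true_pdl1_fraction, co$mrna_pdl1), 0.7,
               tolerance = 3 / sqrt(900))
  # independence case
  co0 <- sample_cohort(n_per_subtype = c(300, 300, 300), corr_mrna = 0,
                       seed = 4)
  expect_lt(abs(cor(co0$true_pdl1_fraction, co0$mrna_pdl1)), 3 / sqrt(900))
  # invalid parameters
  expect_error(sample_cohort(corr_mrna = 1.2), "corr_mrna")
  expect_error(sample_cohort(n_per_subtype = c(0, 5, 5)), "at least one")
})

test_that("rendered slides honor the true gate state at the extremes", {
  sl0 <- tiny_slide(fraction = 0, seed = 21)
  expect_equal(sum(sl0$cells$is_positive), 0)
  sl1 <- tiny_slide(fraction = 1, seed = 22)
  expect_equal(sum(sl1$cells$is_positive), nrow(sl1$cells))
  # one unique positive label per nucleus
  expect_setequal(setdiff(unique(as.vector(sl1$labels)), 0L),
                  sl1$cells$nucleus_id)
})

test_that("noiseless rendering matches the closed-form forward model", {
  b <- stain_basis()
  sl <- tiny_slide(n_nuclei = 6L, fraction = 0, seed = 23,
                   noise_sd = 0, hema = 0.8)
  bg <- sl$labels == 0
  for (ch in 1:3) {
    chan <- sl$rgb[, , ch]
    expect_true(all(chan[bg] == 255))
    expected <- pmin(pmax(round(255 * 10^(-0.8 * unclass(b)[ch, "hema"])), 0), 255)
    expect_true(all(chan[!bg] == expected))
  }
})

test_that("rendering and unmixing round-trip nuclear OD within quantization", {
  b <- stain_basis()
  sl <- tiny_slide(n_nuclei = 12L, fraction = 0.5, seed = 24, noise_sd = 0)
  conc <- unmix(rgb_to_od(sl$rgb), b)
  hema <- conc[, , "hema"]; dab <- conc[, , "dab"]
  # quantization of 1/255 in transmitted intensity maps to ~0.01 OD here
  inside <- sl$labels > 0
  expect_lt(max(abs(hema[inside] - 0.8)), 0.02)
  pos_px <- sl$labels %in% sl$cells$nucleus_id[sl$cells$is_positive]
  if (any(pos_px)) expect_lt(max(abs(dab[pos_px] - 0.6)), 0.02)
  neg_px <- inside & !pos_px
  expect_lt(max(abs(dab[neg_px])), 0.02)
})

test_that("marked-nucleus fractions are binomially consistent over seeds", {
  p <- 0.3; reps <- 40; k <- 40L
  fr <- vapply(seq_len(reps), function(s)
    mean(tiny_slide(n_nuclei = k, fraction = p, seed = 1000 + s,
                    noise_sd = 2)$cells$is_positive),
    numeric(1))
  expect_lt(abs(mean(fr) - p), 3 * sqrt(p * (1 - p) / (k * reps)))
})

test_that("identical seeds give identical slides; infeasible packing errors", {
  a <- tiny_slide(seed = 31)
  b <- tiny_slide(seed = 31)
  expect_identical(a$rgb, b$rgb)
  expect_identical(a$labels, b$labels)
  expect_identical(a$cells, b$cells)
  case <- data.frame(n_nuclei = 5000L, true_pdl1_fraction = 0.1)
  expect_error(render_slide(case, slide_spec(), stain_basis(), "pdl1",
                            seed = 1),
               "achieved")
})
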