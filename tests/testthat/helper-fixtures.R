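# Shared fixtures, all generated in code.

# A cohort whose quadrant membership reproduces the published counts:
# 45 type I, 106 type II, 8 type III, 82 type IV at the published
# cutoffs, with EBV status distributed per the published contingency
# rows (I..IV positives 20, 8, 3, 9).
table2_cohort <- function() {
  cut_p <- 0.136441
  cut_c <- 0.1636454
  hi_p <- cut_p + 0.05; lo_p <- cut_p - 0.05
  hi_c <- cut_c + 0.05; lo_c <- cut_c - 0.05
  counts <- c(I = 45L, II = 106L, III = 8L, IV = 82L)
  ebv_pos <- c(I = 20L, II = 8L, III = 3L, IV = 9L)
  quadrant <- rep(names(counts), counts)
  d <- data.frame(
    case_id = sprintf("case_%03d", seq_len(sum(counts))),
    pdl1_ratio = ifelse(quadrant %in% c("I", "III"), hi_p, lo_p),
    cd8_ratio = ifelse(quadrant %in% c("I", "IV"), hi_c, lo_c)
  )
  d$ebv <- unlist(lapply(names(counts), function(q)
    rep(c("Positive", "Negative"),
        c(ebv_pos[q], counts[q] - ebv_pos[q]))))
  d
}

published_cutoffs <- function() tme_cutoffs(0.136441, 0.1636454)

# Small noiseless slide for exact forward-model checks.
tiny_slide <- function(n_nuclei = 10L, fraction = 0.5, seed = 11L,
                       noise_sd = 0, hema = 0.8, dab = 0.6) {
  case <- data.frame(n_nuclei = n_nuclei, true_pdl1_fraction = fraction)
  render_slide(case,
               slide_spec(noise_sd = noise_sd, hema_od_level = hema,
                          dab_od_level = dab),
               stain_basis(), marker = "pdl1", seed = seed)
}

# Independent exhaustive-scan maxstat oracle built on survival::survdiff,
# sharing no code with maxstat_cutpoint().
maxstat_oracle <- function(values, time, event, eps = 0.1) {
  u <- sort(unique(values))
  mids <- (u[-1] + u[-length(u)]) / 2
  n <- length(values)
  keep <- vapply(mids, function(cut) {
    lo <- sum(values <= cut)
    min(lo, n - lo) >= eps * n
  }, logical(1))
  mids <- mids[keep]
  absz <- vapply(mids, function(cut) {
    g <- factor(values > cut)
    if (nlevels(g) < 2) return(NA_real_)
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    sqrt(sd$chisq)
  }, numeric(1))
  best <- which.max(absz)
  list(cutoff = mids[best], max_statistic = absz[best], grid_abs_z = absz)
}
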