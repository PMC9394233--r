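test_that("the band QC score is the popcount of present bands, exhaustively", {
  for (m in 0:(2^7 - 1)) {
    bands <- bitwAnd(m, 2^(0:6)) > 0
    rec <- qc_score(bands)
    expect_equal(rec$score, sum(bands))
    expect_equal(rec$pass, sum(bands) >= 5)
  }
  full <- qc_score(rep(TRUE, 7))
  expect_equal(full$score, 7)
  expect_equal(full$max_score, 7)
  expect_true(full$pass)
  expect_false(qc_score(c(rep(TRUE, 4), rep(FALSE, 3)))$pass)
  expect_false(qc_score(rep(FALSE, 7))$pass)

  a1 <- qc_score(rep(TRUE, 4), method = "ampli1", pass_threshold = 3)
  expect_equal(a1$max_score, 4)
  expect_true(a1$pass)
  expect_error(qc_score(rep(TRUE, 4)), "7")
  expect_error(qc_score(rep(TRUE, 7), method = "ampli1"), "4")
})

test_that("arm distribution ratios match hand arithmetic, including leave-one-out", {
  arms <- c("1p", "1q", "2p")
  sample_counts <- tibble::tibble(arm = arms, count = c(60, 30, 10))
  panel <- tibble::tibble(
    sample_id = rep(c("L1", "L2", "L3"), each = 3),
    arm = rep(arms, 3),
    count = c(50, 30, 20,  40, 40, 20,  60, 20, 20)
  )
  ar <- arm_ratios(sample_counts, panel, excluded_arms = character(0))
  panel_mean <- c(mean(c(.5, .4, .6)), mean(c(.3, .4, .2)), mean(c(.2, .2, .2)))
  expect_equal(ar$fraction, c(0.6, 0.3, 0.1))
  expect_equal(ar$ratio, c(0.6, 0.3, 0.1) / panel_mean)

  # leave-one-out for a member: mean over the other two only
  l1 <- panel[panel$sample_id == "L1", c("arm", "count")]
  loo <- arm_ratios(l1, panel, excluded_arms = character(0),
                    leave_one_out = TRUE, sample_id = "L1")
  mean_others <- c(mean(c(.4, .6)), mean(c(.4, .2)), mean(c(.2, .2)))
  expect_equal(loo$ratio, c(0.5, 0.3, 0.2) / mean_others)

  # a sample identical to every member has ratio 1 everywhere
  same <- tibble::tibble(arm = arms, count = c(50, 30, 20))
  panel_same <- tibble::tibble(sample_id = rep(c("a", "b"), each = 3),
                               arm = rep(arms, 2), count = rep(c(50, 30, 20), 2))
  expect_equal(arm_ratios(same, panel_same, excluded_arms = character(0))$ratio,
               rep(1, 3))
})

test_that("arm ratios are invariant to scaling the sample's counts", {
  arms <- paste0(rep(1:4, each = 2), c("p", "q"))
  set.seed(21)
  panel <- tidyr::crossing(sample_id = c("L1", "L2", "L3"), arm = arms) %>%
    dplyr::mutate(count = rpois(dplyr::n(), 500))
  s <- tibble::tibble(arm = arms, count = rpois(8, 300))
  r1 <- arm_ratios(s, panel, excluded_arms = character(0))$ratio
  s10 <- dplyr::mutate(s, count = count * 10)
  r2 <- arm_ratios(s10, panel, excluded_arms = character(0))$ratio
  expect_equal(r1, r2)
})

test_that("the default exclusion list retains 39 of the 48 hg19 arms", {
  arms <- hg19_arms()
  expect_equal(nrow(arms), 48)
  set.seed(22)
  panel <- tidyr::crossing(sample_id = c("L1", "L2"), arm = arms$arm) %>%
    dplyr::mutate(count = rpois(dplyr::n(), 200))
  s <- tibble::tibble(arm = arms$arm, count = rpois(48, 200))
  ar <- arm_ratios(s, panel)
  expect_equal(sum(ar$retained), 39)
  expect_true(all(is.na(ar$ratio[!ar$retained])))
})

test_that("a zero panel-mean on a retained arm yields a missing ratio with a warning", {
  arms <- c("1p", "1q", "2p")
  panel <- tibble::tibble(sample_id = rep(c("a", "b"), each = 3),
                          arm = rep(arms, 2), count = c(50, 50, 0, 60, 40, 0))
  s <- tibble::tibble(arm = arms, count = c(40, 40, 20))
  expect_warning(ar <- arm_ratios(s, panel, excluded_arms = character(0)), "2p")
  expect_true(is.na(ar$ratio[3]))
})

test_that("the uniformity verdict follows the starved-arm and top-k rules strictly", {
  arms <- paste0(rep(1:5, each = 2), c("p", "q"))
  panel <- tidyr::crossing(sample_id = c("L1", "L2"), arm = arms) %>%
    dplyr::mutate(count = 100)
  uniform <- arm_ratios(tibble::tibble(arm = arms, count = rep(100, 10)),
                        panel, excluded_arms = character(0))
  expect_equal(wga_uniformity_flag(uniform)$verdict, "pass")

  collapsed <- arm_ratios(tibble::tibble(arm = arms, count = c(600, 200, 100, rep(2, 7))),
                          panel, excluded_arms = character(0))
  expect_equal(wga_uniformity_flag(collapsed)$verdict, "fail")

  # exactly at the top-k share threshold: strict inequality, still a pass
  at_edge <- arm_ratios(
    tibble::tibble(arm = arms, count = c(60, 50, 40, 30, 30, 30, 20, 20, 10, 10)),
    panel, excluded_arms = character(0))
  flag <- wga_uniformity_flag(at_edge, low_cut = 0)
  expect_equal(flag$topk_read_share, 0.5)
  expect_equal(flag$verdict, "pass")
})

test_that("profile MAD matches hand computations and respects scope", {
  g <- make_bin_grid(c(chr1 = 1.1e6, chr2 = 1.1e6), 1e5)  # 11 + 11 bins
  prof <- profile_from_log2(g, c(rep(0.5, 11), rep(-1, 5), 0, rep(1, 5)))
  expect_equal(profile_mad(prof, chrom = "chr1", min_bins = 5), 0)
  expect_equal(profile_mad(prof, chrom = "chr2", min_bins = 5), 1)

  vals <- c(0.1, 0.2, 0.2, 0.3, 0.9)
  g5 <- make_bin_grid(c(chrA = 5e5), 1e5)
  expect_equal(profile_mad(profile_from_log2(g5, vals), min_bins = 5), 0.1)

  expect_error(profile_mad(profile_from_log2(g5, vals), chrom = "chr7"), "chr7")
  expect_error(profile_mad(profile_from_log2(g5, vals), min_bins = 10), "need")
})

test_that("empty-bin flagging works in relative and absolute modes", {
  g <- sim_grid(1, 200)
  make_p <- function(n_empty, id) {
    x <- rep(100L, 200)
    if (n_empty > 0) x[seq_len(n_empty)] <- 0L
    suppressWarnings(normalize_profile(counts_from_vector(g, x, id), do_gc = FALSE))
  }
  cohort <- c(lapply(1:5, function(i) make_p(4, paste0("ok", i))),
              list(make_p(80, "bad")))
  rel <- empty_bin_flag(cohort)
  expect_equal(rel$flagged, c(rep(FALSE, 5), TRUE))
  none <- empty_bin_flag(lapply(1:4, function(i) make_p(0, paste0("z", i))))
  expect_false(any(none$flagged))

  abs_mode <- empty_bin_flag(cohort, mode = "absolute", max_empty_fraction = 0.1)
  expect_equal(abs_mode$flagged, c(rep(FALSE, 5), TRUE))

  expect_warning(single <- empty_bin_flag(cohort[6]), "cohort")
  expect_false(single$flagged)
})

test_that("paired Wilcoxon handles degenerate and error cases per contract", {
  expect_error(paired_wilcoxon(1:4, 2:5), "5 complete pairs")
  expect_warning(res <- paired_wilcoxon(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)),
                 "zero")
  expect_equal(res$p_value, 1)
  # incomplete pairs dropped before the length check
  x <- c(1, 2, 3, 4, 5, NA); y <- c(2, 1, 5, 2, 9, 3)
  expect_equal(paired_wilcoxon(x, y)$n, 5)
})

test_that("the exact path matches full 2^n sign enumeration (no ties)", {
  set.seed(23)
  for (n in c(5, 8, 12)) {
    for (rep in 1:3) {
      x <- round(rnorm(n, 0, 1), 3)
      y <- round(rnorm(n, 0.3, 1), 3)
      d <- x - y
      if (any(d == 0) || any(duplicated(abs(signif(d, 8))))) next
      res <- paired_wilcoxon(x, y)
      expect_equal(res$method, "exact")
      expect_equal(res$p_value, oracle_signed_rank(d), tolerance = 1e-12)
    }
  }
})

test_that("ties trigger the tie-corrected normal approximation", {
  # tie at |0.5| with mixed signs: the exact p would depend on the tie
  x <- c(1.0, 2.0, 3.0, 4.0, 5.0, 6.0)
  y <- c(0.5, 2.5, 2.6, 4.6, 4.8, 5.1)
  d <- x - y
  res <- paired_wilcoxon(x, y)
  expect_equal(res$method, "approximate")
  # against the classical formula
  r <- rank(abs(d)); V <- sum(r[d > 0]); n <- length(d)
  tab <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
  z <- (V - n * (n + 1) / 4)
  z <- (z - sign(z) * 0.5) / sqrt(sig2)
  expect_equal(res$p_value, 2 * pnorm(-abs(z)))

  # an extreme statistic is tie-invariant, so the exact value applies
  ext <- paired_wilcoxon(c(1, 2, 3, 4.0, 5, 6), c(1.5, 2.5, 3.4, 4.5, 5.2, 6.9))
  expect_equal(ext$method, "exact")
  expect_equal(ext$p_value, 2 / 2^6)
})

test_that("benchmark method comparisons reproduce the published p-values", {
  yields <- wga_library_yields()
  t1 <- paired_wilcoxon(yields$yield_truseq, yields$yield_lowpass)
  expect_equal(t1$n, 23)
  expect_equal(t1$method, "exact")
  expect_equal(signif(t1$p_value, 3), 7.15e-7)

  mads <- mcf7_wga_mads()
  t5 <- paired_wilcoxon(mads$mad_ampli1, mads$mad_replig)
  expect_equal(t5$n, 6)
  expect_equal(round(t5$p_value, 2), 0.03)

  leuko <- leukocyte_mads()
  t3 <- paired_wilcoxon(leuko$mad_truseq, leuko$mad_lowpass)
  expect_equal(t3$method, "approximate")
  expect_equal(round(t3$p_value, 2), 0.15)
})

test_that("binomial thinning preserves expectation and supports depth analysis", {
  g <- make_bin_grid(c(chrA = 2e7), 1e5)  # 200 bins
  cc <- counts_from_vector(g, rep(1000L, 200))
  set.seed(24)
  acc <- numeric(200)
  iters <- 400
  for (i in seq_len(iters)) acc <- acc + thin_counts(cc, 1e5)$count
  expect_lt(max(abs(acc / iters - 500) / 500), 0.02)

  expect_warning(unchanged <- thin_counts(cc, 1e9), "unchanged")
  expect_identical(unchanged$count, cc$count)
})
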