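#' Multiplex-band QC score for a WGA product
#'
#' Whole-genome-amplification products are screened by multiplex PCR: the
#' QC score is simply the number of bands present. The modified VyCAP
#' multiplex has 7 informative bands for WGA products (an 8th appears
#' only in undigested genomic DNA, whose restriction site survives); the
#' Ampli1 QC multiplex has 4. Products at or above the pass threshold
#' (default QC-5) proceed to library preparation.
#'
#' @param bands Logical vector of band-presence flags: length 7 for
#'   `"modified_vycap"`, 4 for `"ampli1"`.
#' @param method `"modified_vycap"` (default) or `"ampli1"`.
#' @param pass_threshold Minimum score to pass (default 5).
#' @param sample_id Sample identifier.
#' @return One-row tibble: `sample_id`, `method`, `score`, `max_score`,
#'   `pass`.
#' @export
qc_score <- function(bands, method = c("modified_vycap", "ampli1"),
                     pass_threshold = 5, sample_id = "sample") {
  method <- match.arg(method)
  expected <- if (method == "modified_vycap") 7L else 4L
  if (!is.logical(bands) || length(bands) != expected || anyNA(bands)) {
    abort(sprintf("`bands` must be %d non-missing logical flags for method '%s'",
                  expected, method))
  }
  score <- sum(bands)
  tibble(sample_id = sample_id, method = method, score = score,
         max_score = expected, pass = score >= pass_threshold)
}

#' Chromosome-arm distribution ratios against a normal panel
#'
#' The arm-level QC statistic (mFAST-SeqS style): per-arm read counts are
#' normalized to fractions of the sample's total mapped reads and divided
#' by the mean fraction of a leukocyte panel, giving a distribution ratio
#' per arm that is about 1 when amplification was uniform and euploid.
#' Arms with few mappable repeat reads (acrocentric p arms) and the sex
#' chromosomes are excluded from the ratios. When the sample is itself a
#' panel member and `leave_one_out = TRUE`, its own contribution is
#' removed from the panel mean.
#'
#' @param sample_counts Tibble with columns `arm`, `count` for one
#'   sample.
#' @param panel_counts Tibble with columns `sample_id`, `arm`, `count`
#'   for at least 2 panel members.
#' @param excluded_arms Arms dropped from the ratios (default
#'   [default_excluded_arms()]).
#' @param leave_one_out Exclude the sample itself from the panel mean
#'   when `sample_id` matches a panel member.
#' @param sample_id Sample identifier.
#' @return An `arm_ratio_profile` tibble: one row per arm with `count`,
#'   `fraction`, `panel_mean`, `ratio` and `retained`. Attributes store
#'   the sample id and settings.
#' @export
arm_ratios <- function(sample_counts, panel_counts,
                       excluded_arms = default_excluded_arms(),
                       leave_one_out = FALSE, sample_id = "sample") {
  need <- c("arm", "count")
  if (!all(need %in% names(sample_counts))) {
    abort("`sample_counts` needs columns arm, count")
  }
  if (!all(c("sample_id", need) %in% names(panel_counts))) {
    abort("`panel_counts` needs columns sample_id, arm, count")
  }
  members <- unique(panel_counts$sample_id)
  use_members <- members
  if (leave_one_out) use_members <- setdiff(members, sample_id)
  if (length(use_members) < 2) abort("panel needs at least 2 (other) members")
  arms <- sample_counts$arm
  if (anyDuplicated(arms)) abort("duplicated arm labels in `sample_counts`")

  frac <- sample_counts$count / sum(sample_counts$count)
  panel_frac <- panel_counts %>%
    filter(.data$sample_id %in% use_members) %>%
    group_by(.data$sample_id) %>%
    mutate(fraction = .data$count / sum(.data$count)) %>%
    ungroup() %>%
    group_by(.data$arm) %>%
    summarise(panel_mean = mean(.data$fraction), .groups = "drop")
  if (!all(arms %in% panel_frac$arm)) {
    abort("panel arm labels do not cover the sample's arms")
  }
  out <- tibble(arm = arms, count = sample_counts$count, fraction = frac) %>%
    left_join(panel_frac, by = "arm") %>%
    mutate(
      retained = !(.data$arm %in% excluded_arms),
      ratio = ifelse(.data$retained, .data$fraction / .data$panel_mean, NA_real_)
    )
  undef <- out$retained & (is.na(out$ratio) | !is.finite(out$ratio))
  if (any(undef)) {
    warn(sprintf("panel mean fraction is 0 on retained arm(s) %s; ratio undefined",
                 paste(out$arm[undef], collapse = ", ")))
    out$ratio[undef] <- NA_real_
  }
  structure(out,
    class = c("arm_ratio_profile", "tbl_df", "tbl", "data.frame"),
    sample_id = sample_id,
    leave_one_out = leave_one_out,
    excluded_arms = excluded_arms
  )
}

#' Flag non-uniform read distribution over chromosome arms
#'
#' A failed WGA reaction collapses nearly all reads onto a few
#' chromosome arms while most arms receive almost none. The verdict is
#' `"fail"` when the fraction of retained arms with distribution ratio
#' below `low_cut` exceeds `low_fraction_max`, or when the share of
#' retained-arm reads concentrated on the `topk` highest-count arms
#' exceeds `topk_share_max` (both strict inequalities); otherwise
#' `"pass"`.
#'
#' @param arms An `arm_ratio_profile` from [arm_ratios()].
#' @param low_cut Ratio below which an arm counts as starved (default
#'   0.1).
#' @param low_fraction_max Maximum tolerated fraction of starved arms
#'   (default 0.5).
#' @param topk Number of top arms in the concentration check (default 3).
#' @param topk_share_max Maximum tolerated read share of the top arms
#'   (default 0.5).
#' @return One-row tibble with the two metrics and the `verdict`.
#' @export
wga_uniformity_flag <- function(arms, low_cut = 0.1, low_fraction_max = 0.5,
                                topk = 3, topk_share_max = 0.5) {
  stopifnot(inherits(arms, "arm_ratio_profile"))
  kept <- arms[arms$retained & !is.na(arms$ratio), , drop = FALSE]
  if (nrow(kept) == 0) abort("no retained arm has a defined ratio")
  low_fraction <- mean(kept$ratio < low_cut)
  shares <- sort(kept$count, decreasing = TRUE)
  topk_share <- sum(head(shares, topk)) / sum(kept$count)
  fail <- (low_fraction > low_fraction_max) || (topk_share > topk_share_max)
  tibble(
    sample_id = attr(arms, "sample_id"),
    low_ratio_fraction = low_fraction,
    topk_read_share = topk_share,
    verdict = if (fail) "fail" else "pass"
  )
}

#' Median absolute deviation of a profile's log2 ratios
#'
#' Raw MAD (no consistency constant), genome wide or for a single
#' chromosome: `median(|x - median(x)|)` over the non-missing log2
#' ratios. Noise metric for comparing library preparations; roughly
#' 0.2-0.3 for single-cell 100-kb profiles.
#'
#' @param profile A `cnv_profile`.
#' @param chrom Optional chromosome to restrict to (`NULL` = genome
#'   wide). A cell line with ploidy shifts is best measured on a
#'   chromosome little affected by copy-number changes.
#' @param min_bins Minimum non-missing bins required (default 10).
#' @return The MAD.
#' @export
profile_mad <- function(profile, chrom = NULL, min_bins = 10) {
  stopifnot(inherits(profile, "cnv_profile"))
  x <- profile$log2
  if (!is.null(chrom)) {
    x <- x[sub("^chr", "", profile$chrom) %in% sub("^chr", "", chrom)]
    if (length(x) == 0) abort(sprintf("chromosome '%s' not in the profile", chrom))
  }
  x <- x[!is.na(x)]
  if (length(x) < min_bins) {
    abort(sprintf("only %d non-missing bin(s) in scope (need >= %d)",
                  length(x), min_bins))
  }
  median(abs(x - median(x)))
}

#' Flag samples with excess empty bins
#'
#' Empty bins (usable bins with zero reads) indicate a low-complexity
#' library; samples deviating from the cohort are excluded before
#' heterogeneity analysis. `"absolute"` mode flags samples whose empty
#' fraction exceeds `max_empty_fraction`; `"relative"` mode flags samples
#' exceeding `relative_multiple` times the cohort median empty fraction.
#'
#' @param profiles List of `cnv_profile` objects.
#' @param max_empty_fraction Threshold for absolute mode (default 0.1).
#' @param mode `"relative"` (default) or `"absolute"`.
#' @param relative_multiple Multiple of the cohort median for relative
#'   mode (default 3).
#' @return Tibble with one row per sample: `sample_id`,
#'   `empty_fraction`, `flagged`.
#' @export
empty_bin_flag <- function(profiles, max_empty_fraction = 0.1,
                           mode = c("relative", "absolute"),
                           relative_multiple = 3) {
  mode <- match.arg(mode)
  if (length(profiles) < 1) abort("need at least one profile")
  frac <- vapply(profiles, function(p) {
    attr(p, "empty_bin_count") / max(sum(p$usable), 1)
  }, numeric(1))
  ids <- vapply(profiles, function(p) attr(p, "sample_id"), character(1))
  if (mode == "absolute") {
    flagged <- frac > max_empty_fraction
  } else {
    if (length(profiles) < 2) {
      warn("relative mode needs a cohort; single sample not flagged")
      flagged <- rep(FALSE, length(frac))
    } else {
      ref <- median(frac)
      # a cohort median of zero makes any non-zero sample an outlier
      flagged <- if (ref == 0) frac > 0 else frac > relative_multiple * ref
    }
  }
  tibble(sample_id = ids, empty_fraction = frac, flagged = flagged)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test used for method comparisons (e.g.
#' library yields or MAD noise between two preparations of the same
#' samples). Incomplete pairs are dropped, then zero differences are
#' dropped (signed-rank convention). With n at most `exact_max`, the
#' exact signed-rank null distribution is used when there are no ties
#' among the absolute differences, and also when the statistic is at an
#' extreme (all differences share one sign), where the exact p-value is
#' tie-invariant. Otherwise a normal approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param x,y Paired measurement vectors.
#' @param exact_max Largest n for the exact path (default 25).
#' @param correct Apply a continuity correction in the approximate path
#'   (default `TRUE`).
#' @return List with `statistic` (V, the positive-rank sum), `n` (pairs
#'   used), `p_value` and `method` (`"exact"` or `"approximate"`).
#' @export
paired_wilcoxon <- function(x, y, exact_max = 25, correct = TRUE) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  if (length(d) < 5) abort("need at least 5 complete pairs")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("all differences are zero")
    return(list(statistic = 0, n = 0L, p_value = 1, method = "degenerate"))
  }
  # rank the absolute differences at 8 significant digits: measurement
  # inputs carry limited precision, and floating-point jitter must not
  # split true ties (which would silently switch to the exact path)
  a <- signif(abs(d), 8)
  r <- rank(a)
  V <- sum(r[d > 0])
  ties <- any(duplicated(a))
  # at the extremes the exact p depends only on the sign pattern, so rank
  # ties cannot affect it
  extreme <- V == 0 || V == n * (n + 1) / 2
  if ((!ties || extreme) && n <= exact_max) {
    p <- min(1, 2 * min(psignrank(V, n), 1 - psignrank(V - 1, n)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
    z <- V - mu
    if (correct) z <- z - sign(z) * 0.5
    z <- z / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "approximate"
  }
  list(statistic = V, n = n, p_value = p, method = method)
}
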