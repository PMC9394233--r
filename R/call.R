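#' Expected log2 ratio of an integral copy-number state
#'
#' Under the standard admixture model a segment carrying `cn` copies in a
#' tumour fraction `cellularity` of the sample, against a diploid
#' background, has expected ratio
#' `(cellularity * cn + (1 - cellularity) * normal_cn) / 2`. For a pure
#' single tumour cell (`cellularity = 1`) this puts a single-copy loss at
#' -1, neutral at 0, a single-copy gain at +0.585 and four copies at +1.
#' `cn = 0` is floored at `min_ratio` to keep the log finite.
#'
#' @param cn Non-negative integer copy number.
#' @param cellularity Tumour fraction in (0, 1]; 1 for single tumour
#'   cells.
#' @param normal_cn Copies carried by the admixed normal background
#'   (2 for autosomes; 1 for chromosome X against a male-only panel).
#' @param min_ratio Floor on the ratio before the log (default 0.05).
#' @return Expected log2 ratio.
#' @examples
#' expected_center(1) # -1
#' expected_center(4) # +1
#' @export
expected_center <- function(cn, cellularity = 1, normal_cn = 2,
                            min_ratio = 0.05) {
  if (any(cn < 0)) abort("`cn` must be non-negative")
  if (cellularity <= 0 || cellularity > 1) {
    abort("`cellularity` must be in (0, 1]")
  }
  ratio <- (cellularity * cn + (1 - cellularity) * normal_cn) / 2
  log2(pmax(ratio, min_ratio))
}

.call_states <- function(five_states = FALSE) {
  if (five_states) {
    tibble(state = c("double_loss", "loss", "neutral", "gain", "amplification"),
           call = c(-2L, -1L, 0L, 1L, 2L), cn = c(0, 1, 2, 3, 4))
  } else {
    tibble(state = c("loss", "neutral", "gain", "amplification"),
           call = c(-1L, 0L, 1L, 2L), cn = c(1, 2, 3, 4))
  }
}

# Per-segment state likelihood matrix. Centers are fixed at integral-CN
# log2 ratios; each segment mean is treated as Gaussian around a center
# with sd sigma/sqrt(n_bins), halved again (divided by relSDlong) for
# long segments whose means are that much better determined in practice.
# The amplification state absorbs arbitrarily high amplitudes through a
# right-broadened sd (x2 above its center).
.segment_likelihoods <- function(means, n_bins, sigma, cellularity, relSDlong,
                                 long_threshold, states, normal_cn = 2) {
  sd_seg <- sigma / sqrt(pmax(n_bins, 1))
  sd_seg[n_bins >= long_threshold] <- sd_seg[n_bins >= long_threshold] / relSDlong
  sd_seg <- pmax(sd_seg, 1e-12)
  centers <- expected_center(states$cn, cellularity, normal_cn = normal_cn)
  loglik <- matrix(-Inf, length(means), nrow(states),
                   dimnames = list(NULL, states$state))
  for (s in seq_len(nrow(states))) {
    sd_s <- sd_seg
    if (states$state[s] == "amplification") {
      sd_s <- ifelse(means > centers[s], 2 * sd_seg, sd_seg)
    }
    loglik[, s] <- dnorm(means, mean = centers[s], sd = sd_s, log = TRUE)
  }
  # row-rescaled densities: posteriors and EM updates are invariant to a
  # per-row factor, and tiny segment SDs would otherwise underflow to 0
  exp(loglik - apply(loglik, 1, max))
}

# EM over mixing proportions only (centers fixed). Deterministic
# initialization; the observed-data log-likelihood is checked to be
# non-decreasing at every iteration.
.em_proportions <- function(lik, init, tol = 1e-8, max_iter = 500) {
  pi_s <- init / sum(init)
  eps <- 1e-300
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    joint <- sweep(lik, 2, pi_s, `*`)
    rowsum_ <- rowSums(joint) + eps
    ll <- sum(log(rowsum_))
    if (ll < ll_old - 1e-6) {
      abort("EM log-likelihood decreased; this is a bug")
    }
    resp <- joint / rowsum_
    pi_new <- colMeans(resp)
    if (ll - ll_old < tol) {
      pi_s <- pi_new
      break
    }
    pi_s <- pi_new
    ll_old <- ll
  }
  list(proportions = pi_s, posteriors = resp, loglik = ll)
}

#' Call discrete copy-number states on a segmented profile
#'
#' Converts segment means into hard calls (loss / neutral / gain /
#' amplification) with per-state posterior probabilities, via a
#' constrained Gaussian mixture whose component means are fixed at the
#' integral-copy-number log2 ratios of [expected_center()] and whose
#' mixing proportions are fitted by EM over the sample's segments.
#' Posteriors are assigned per segment and broadcast to all member bins,
#' so every bin of a segment shares one call.
#'
#' Sex chromosomes are excluded by default (their baseline depends on
#' donor sex); `male_x = TRUE` instead calls chromosome X against a
#' one-copy baseline, for use with a male-only calibration panel.
#'
#' @param segmented A `cnv_segments` object.
#' @param profile The `cnv_profile` that was segmented (provides the
#'   noise scale and grid).
#' @param cellularity Tumour fraction (default 1, a pure single cell).
#' @param relSDlong Divisor on the segment-mean SD for long segments
#'   (default 2).
#' @param long_threshold Segments with at least this many bins count as
#'   long (default 10).
#' @param five_states Add a double-loss state at copy number 0 (default
#'   `FALSE`).
#' @param exclude_sex Drop chromosomes X and Y from calling (default
#'   `TRUE`).
#' @param male_x Call chromosome X against a single-copy male baseline
#'   (implies keeping X; default `FALSE`).
#' @param priors Optional fixed mixing proportions (skips EM); used by
#'   [call_cohort()] to share priors across samples.
#' @return A `cnv_calls` tibble: `bin`, `chrom`, `start`, `end`,
#'   `segment`, `call` (-1, 0, 1, 2) and one posterior column per state
#'   (`p_loss`, `p_neutral`, `p_gain`, `p_amp`, ...). Attributes carry
#'   the settings and fitted priors.
#' @export
call_profile <- function(segmented, profile, cellularity = 1, relSDlong = 2,
                         long_threshold = 10, five_states = FALSE,
                         exclude_sex = TRUE, male_x = FALSE, priors = NULL) {
  stopifnot(inherits(segmented, "cnv_segments"), inherits(profile, "cnv_profile"))
  states <- .call_states(five_states)
  seg <- segmented$segments
  sigma <- segmented$sigma
  is_x <- sub("^chr", "", seg$chrom) == "X"
  is_y <- sub("^chr", "", seg$chrom) == "Y"
  keep <- rep(TRUE, nrow(seg))
  if (exclude_sex) keep <- !(is_x | is_y)
  if (male_x) keep <- keep | is_x

  post <- matrix(NA_real_, nrow(seg), nrow(states),
                 dimnames = list(NULL, states$state))
  if (any(keep)) {
    norm_cn <- ifelse(male_x & is_x[keep], 1, 2)
    lik <- matrix(0, sum(keep), nrow(states), dimnames = list(NULL, states$state))
    for (ncn in unique(norm_cn)) {
      rows <- norm_cn == ncn
      st <- states
      if (ncn == 1) st$cn <- st$cn - 1  # X vs male baseline: neutral is one copy
      lik[rows, ] <- .segment_likelihoods(
        seg$mean_log2[keep][rows], seg$n_bins[keep][rows], sigma,
        cellularity, relSDlong, long_threshold, st, normal_cn = ncn
      )
    }
    if (sigma <= 0) {
      # degenerate noise: hard-assign each segment to its nearest center
      inform("degenerate noise scale; collapsing posteriors to the nearest center")
      centers <- expected_center(states$cn, cellularity)
      nearest <- apply(outer(seg$mean_log2[keep], centers,
                             function(a, b) abs(a - b)), 1, which.min)
      pk <- matrix(0, sum(keep), nrow(states))
      pk[cbind(seq_len(sum(keep)), nearest)] <- 1
      post[keep, ] <- pk
      fitted_priors <- colMeans(pk)
    } else if (!is.null(priors)) {
      joint <- sweep(lik, 2, priors / sum(priors), `*`)
      post[keep, ] <- joint / rowSums(joint)
      fitted_priors <- priors / sum(priors)
    } else {
      init <- if (five_states) c(0.02, 0.1, 0.68, 0.15, 0.05)
              else c(0.1, 0.7, 0.15, 0.05)
      em <- .em_proportions(lik, init)
      post[keep, ] <- em$posteriors
      fitted_priors <- em$proportions
    }
  } else {
    fitted_priors <- rep(NA_real_, nrow(states))
  }
  hard <- states$call[apply(post, 1, function(p) {
    if (all(is.na(p))) NA_integer_ else which.max(p)
  })]

  bins <- segmented$bins
  seg_tbl <- tibble(segment = seg$segment, call = hard)
  for (s in seq_len(nrow(states))) {
    seg_tbl[[paste0("p_", .state_abbrev(states$state[s]))]] <- post[, s]
  }
  grid_cols <- as_tibble(profile)[, c("bin", "chrom", "start", "end")]
  out <- bins %>%
    left_join(seg_tbl, by = "segment") %>%
    left_join(grid_cols, by = "bin") %>%
    select("bin", "chrom", "start", "end", "segment", dplyr::everything()) %>%
    arrange(.data$bin)
  structure(out,
    class = c("cnv_calls", "tbl_df", "tbl", "data.frame"),
    sample_id = segmented$sample_id,
    priors = fitted_priors,
    states = states,
    settings = list(cellularity = cellularity, relSDlong = relSDlong,
                    long_threshold = long_threshold,
                    five_states = five_states, exclude_sex = exclude_sex,
                    male_x = male_x)
  )
}

.state_abbrev <- function(state) {
  c(double_loss = "dloss", loss = "loss", neutral = "neutral",
    gain = "gain", amplification = "amp")[state]
}

#' Call a cohort of segmented profiles with shared priors
#'
#' Fits the mixture proportions once, by EM over the pooled segments of
#' all samples, then applies them to each sample. Pooling stabilizes the
#' priors when individual cells contribute few segments.
#'
#' @param segmented_list List of `cnv_segments`.
#' @param profiles List of matching `cnv_profile` objects.
#' @param ... Passed on to [call_profile()].
#' @return Named list of `cnv_calls`.
#' @export
call_cohort <- function(segmented_list, profiles, ...) {
  stopifnot(length(segmented_list) == length(profiles))
  args <- list(...)
  five_states <- isTRUE(args$five_states)
  states <- .call_states(five_states)
  cellularity <- args$cellularity %||% 1
  relSDlong <- args$relSDlong %||% 2
  long_threshold <- args$long_threshold %||% 10
  exclude_sex <- args$exclude_sex %||% TRUE

  lik_all <- list()
  for (i in seq_along(segmented_list)) {
    seg <- segmented_list[[i]]$segments
    keep <- if (exclude_sex) !.is_sex_chrom(seg$chrom) else rep(TRUE, nrow(seg))
    if (!any(keep)) next
    lik_all[[length(lik_all) + 1L]] <- .segment_likelihoods(
      seg$mean_log2[keep], seg$n_bins[keep], segmented_list[[i]]$sigma,
      cellularity, relSDlong, long_threshold, states
    )
  }
  lik <- do.call(rbind, lik_all)
  init <- if (five_states) c(0.02, 0.1, 0.68, 0.15, 0.05) else c(0.1, 0.7, 0.15, 0.05)
  priors <- if (!is.null(lik) && all(rowSums(lik) > 0)) {
    .em_proportions(lik, init)$proportions
  } else {
    init / sum(init)
  }
  out <- purrr::map2(segmented_list, profiles, function(s, p) {
    call_profile(s, p, priors = priors, ...)
  })
  names(out) <- vapply(segmented_list, function(s) s$sample_id, character(1))
  out
}

#' @export
print.cnv_calls <- function(x, ...) {
  tabulated <- table(factor(x$call, levels = -2:2))
  cat(sprintf("<cnv_calls> '%s': %d bin(s); loss/neutral/gain/amp = %d/%d/%d/%d\n",
              attr(x, "sample_id"), nrow(x),
              tabulated[["-1"]], tabulated[["0"]], tabulated[["1"]], tabulated[["2"]]))
  NextMethod()
}

#' Per-segment call summary
#'
#' @param x A `cnv_calls` tibble.
#' @param ... Unused.
#' @return Tibble with one row per segment: coordinates, bin count, hard
#'   call and posteriors.
#' @method tidy cnv_calls
#' @export
tidy.cnv_calls <- function(x, ...) {
  post_cols <- grep("^p_", names(x), value = TRUE)
  x %>%
    group_by(.data$segment, .data$chrom, .data$call) %>%
    summarise(
      first_bin = min(.data$bin), last_bin = max(.data$bin),
      start = min(.data$start), end = max(.data$end), n_bins = n(),
      across(all_of(post_cols), ~ .x[1]),
      .groups = "drop"
    ) %>%
    arrange(.data$segment)
}
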