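#' Normalize a bin-count profile to log2 ratios
#'
#' Converts raw per-bin counts into a median-centred log2-ratio profile.
#' Usable bins with zero count become missing and are tallied as empty
#' bins (a sample-level QC quantity); unusable bins are always missing.
#' When enabled, counts are first divided by a locally weighted (loess)
#' fit against GC fraction, then against mappability, removing the smooth
#' coverage dependence on base composition. The corrected counts are
#' scaled to median 1 and log2-transformed, so the median of the
#' non-missing log2 ratios is exactly 0 and a diploid bin sits at the
#' baseline.
#'
#' The first-difference noise variance
#' \eqn{\hat\sigma^2_\Delta = \mathrm{var}(\mathrm{diff}(x)) / 2}
#' (differences taken within chromosomes) is stored alongside the empty
#' bin count; both drive bin-size selection and sample QC.
#'
#' @param counts A `cnv_counts` tibble.
#' @param do_gc,do_mappability Apply the loess correction against the
#'   grid's GC / mappability annotation (skipped with a warning when the
#'   annotation is absent).
#' @param loess_span Smoothing span of the loess fits (default 0.65).
#' @param min_usable_bins Profiles with fewer non-missing usable bins are
#'   flagged unusable (default 100).
#' @return A `cnv_profile` tibble: grid columns plus `count` and `log2`,
#'   with attributes `sample_id`, `sigma_delta`, `empty_bin_count`,
#'   `usable_profile` and `corrections`.
#' @export
normalize_profile <- function(counts, do_gc = TRUE, do_mappability = FALSE,
                              loess_span = 0.65, min_usable_bins = 100) {
  stopifnot(inherits(counts, "cnv_counts"))
  x <- as.numeric(counts$count)
  usable <- counts$usable
  empty <- usable & x == 0
  value <- ifelse(usable & x > 0, x, NA_real_)

  gc_done <- FALSE
  map_done <- FALSE
  if (do_gc) {
    if (all(is.na(counts$gc))) {
      warn("GC correction requested but the grid has no GC annotation; skipped")
    } else {
      value <- .loess_correct(value, counts$gc, loess_span)
      gc_done <- TRUE
    }
  }
  if (do_mappability) {
    if (all(is.na(counts$mappability))) {
      warn("mappability correction requested but the grid has no mappability annotation; skipped")
    } else {
      value <- .loess_correct(value, counts$mappability, loess_span)
      map_done <- TRUE
    }
  }

  med <- median(value, na.rm = TRUE)
  log2r <- log2(value / med)
  # exact re-centring: with an even bin count the median of the log is not
  # the log of the median
  log2r <- log2r - median(log2r, na.rm = TRUE)
  n_ok <- sum(!is.na(log2r))
  usable_profile <- n_ok >= min_usable_bins
  if (!usable_profile) {
    warn(sprintf("profile '%s' has only %d non-missing usable bins (< %d); flagged unusable",
                 attr(counts, "sample_id"), n_ok, min_usable_bins))
  }

  out <- as_tibble(counts)
  out$log2 <- log2r
  structure(out,
    class = c("cnv_profile", "tbl_df", "tbl", "data.frame"),
    sample_id = attr(counts, "sample_id"),
    bin_size = attr(counts, "bin_size"),
    total_mapped_reads = attr(counts, "total_mapped_reads"),
    sigma_delta = sigma_delta(log2r, out$chrom),
    empty_bin_count = sum(empty),
    usable_profile = usable_profile,
    corrections = list(gc = gc_done, mappability = map_done, dewaved = FALSE)
  )
}

# Divide counts by a loess fit against a covariate; preserves the mean scale.
.loess_correct <- function(value, covariate, span) {
  ok <- !is.na(value) & !is.na(covariate)
  if (sum(ok) < 10) return(value)
  fit <- loess(value[ok] ~ covariate[ok], span = span, degree = 2,
               family = "symmetric",
               control = stats::loess.control(surface = "direct"))
  pred <- predict(fit, newdata = covariate[ok])
  pred[!is.finite(pred) | pred <= 0] <- NA_real_
  value[ok] <- value[ok] / pred
  value
}

#' First-difference noise variance of a log2 profile
#'
#' @param log2r Numeric vector of log2 ratios (may contain `NA`).
#' @param chrom Chromosome of each bin; differences never cross
#'   chromosome boundaries.
#' @return `var(diff(x)) / 2` pooled over chromosomes, the standard
#'   first-difference estimator of per-bin noise variance.
#' @export
sigma_delta <- function(log2r, chrom = NULL) {
  if (is.null(chrom)) chrom <- rep("all", length(log2r))
  d <- unlist(lapply(split(log2r, factor(chrom, levels = unique(chrom))),
                     function(x) diff(x[!is.na(x)])), use.names = FALSE)
  if (length(d) < 2) return(NA_real_)
  var(d) / 2
}

#' Robust per-bin noise scale of a profile
#'
#' MAD (with the 1.4826 Gaussian consistency factor) of successive
#' non-missing bin differences, divided by sqrt(2). Smooth waves and true
#' copy-number structure contribute little because differencing removes
#' them; this is the scale used by undo-splits pruning and by the caller.
#'
#' @param log2r Numeric vector of log2 ratios.
#' @param chrom Optional chromosome vector; differences stay within
#'   chromosomes.
#' @return Single non-negative number.
#' @export
noise_scale <- function(log2r, chrom = NULL) {
  if (is.null(chrom)) chrom <- rep("all", length(log2r))
  d <- unlist(lapply(split(log2r, factor(chrom, levels = unique(chrom))),
                     function(x) diff(x[!is.na(x)])), use.names = FALSE)
  if (length(d) < 2) return(0)
  mad(d) / sqrt(2)
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf("<cnv_profile> '%s': %d bins, sigma_delta = %.4g, %d empty bin(s)%s\n",
              attr(x, "sample_id"), nrow(x), attr(x, "sigma_delta"),
              attr(x, "empty_bin_count"),
              if (isTRUE(attr(x, "corrections")$dewaved)) ", dewaved" else ""))
  NextMethod()
}

#' Profile-level summary
#'
#' @param x A `cnv_profile`.
#' @param ... Unused.
#' @return One-row tibble with the sample's noise and QC metrics.
#' @method glance cnv_profile
#' @export
glance.cnv_profile <- function(x, ...) {
  tibble(
    sample_id = attr(x, "sample_id"),
    n_bins = nrow(x),
    n_usable = sum(x$usable),
    n_missing = sum(is.na(x$log2)),
    empty_bins = attr(x, "empty_bin_count"),
    sigma_delta = attr(x, "sigma_delta"),
    mad_genome = profile_mad(x),
    usable_profile = attr(x, "usable_profile"),
    dewaved = isTRUE(attr(x, "corrections")$dewaved)
  )
}
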