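#' @name segmentation
#' @title Circular binary segmentation of log2-ratio profiles
#'
#' @description
#' A corrected profile is partitioned per chromosome into mean-constant
#' segments by circular binary segmentation (CBS): the pair of cut points
#' (i, j) maximizing a circularized two-sample statistic between the arc
#' and its complement is located recursively, each candidate split is
#' accepted only when its permutation p-value falls below `alpha`, and
#' accepted splits are finally pruned by the undo-splits rule, which
#' merges adjacent segments whose mean difference is smaller than
#' `undo_sd` noise standard deviations. A minimum segment width
#' suppresses short single-cell artefacts.
NULL

# Maximal circular two-sample statistic over all arcs (i+1)..j whose arc,
# complement, and any flanking piece left behind are at least min_width
# bins. Compiled scan (see src/cbs.cpp); ties broken to the smallest
# (i, then j) for determinism.
.cbs_max_stat <- function(x, min_width = 1L) {
  n <- length(x)
  if (n < 2L * min_width) return(NULL)
  .cbs_max_stat_cpp(x, as.integer(min_width))
}

# Permutation p-value of the observed maximal statistic, permuting values
# within the segment under test (R RNG, so seeded runs reproduce). Stops
# early once significance at `alpha` is impossible; the returned value is
# then a lower bound (>= alpha).
.cbs_perm_p <- function(x, obs, alpha, nperm, min_width) {
  .cbs_perm_p_cpp(x, obs, alpha, as.integer(nperm), as.integer(min_width))
}

.cbs_recurse <- function(x, alpha, nperm, min_width) {
  n <- length(x)
  res <- .cbs_max_stat(x, min_width)
  if (is.null(res) || res$stat <= 0) return(integer(0))
  p <- .cbs_perm_p(x, res$stat, alpha, nperm, min_width)
  if (p >= alpha) return(integer(0))
  bps <- c(if (res$i > 0L) res$i, if (res$j < n) res$j)
  bounds <- c(0L, bps, n)
  out <- integer(0)
  for (q in seq_len(length(bounds) - 1L)) {
    lo <- bounds[q]
    hi <- bounds[q + 1L]
    if (hi - lo >= 2L * min_width) {
      out <- c(out, lo + .cbs_recurse(x[(lo + 1L):hi], alpha, nperm, min_width))
    }
  }
  sort(unique(c(out, bps)))
}

#' Segment a profile by circular binary segmentation
#'
#' @param profile A `cnv_profile` (typically dewaved).
#' @param alpha Significance level for accepting a split (default 0.01).
#' @param n_permutations Permutations per candidate split (default 1000).
#' @param undo_sd Undo-splits multiplier: adjacent segments closer than
#'   `undo_sd` noise SDs are merged after segmentation (default 4; 0
#'   disables pruning).
#' @param min_width Minimum segment length in bins (default 10).
#' @param seed Optional RNG seed recorded in the settings; fixed seed +
#'   identical input gives identical breakpoints.
#' @return A `cnv_segments` object: `segments` tibble (`segment`,
#'   `chrom`, `first_bin`, `last_bin`, `start`, `end`, `n_bins`,
#'   `mean_log2`), a `bins` tibble mapping non-missing bins to segments,
#'   the noise scale used, and the settings.
#' @seealso [undo_splits()]
#' @export
segment_profile <- function(profile, alpha = 0.01, n_permutations = 1000,
                            undo_sd = 4, min_width = 10, seed = NULL) {
  stopifnot(inherits(profile, "cnv_profile"))
  if (!is.null(seed)) set.seed(seed)
  sigma <- noise_scale(profile$log2, profile$chrom)
  chroms <- unique(profile$chrom)
  seg_rows <- list()
  bin_rows <- list()
  seg_id <- 0L
  for (ch in chroms) {
    idx <- which(profile$chrom == ch & !is.na(profile$log2))
    if (length(idx) == 0) next
    x <- profile$log2[idx]
    n <- length(x)
    if (n < min_width) {
      warn(sprintf("chromosome %s has %d non-missing bin(s) (< min_width); single segment",
                   ch, n))
      bps <- integer(0)
    } else {
      bps <- .cbs_recurse(x, alpha, n_permutations, min_width)
    }
    bounds <- c(0L, bps, n)
    for (q in seq_len(length(bounds) - 1L)) {
      lo <- bounds[q] + 1L
      hi <- bounds[q + 1L]
      seg_id <- seg_id + 1L
      member <- idx[lo:hi]
      seg_rows[[seg_id]] <- tibble(
        segment = seg_id, chrom = ch,
        first_bin = profile$bin[member[1]],
        last_bin = profile$bin[member[length(member)]],
        start = profile$start[member[1]],
        end = profile$end[member[length(member)]],
        n_bins = length(member),
        mean_log2 = mean(x[lo:hi])
      )
      bin_rows[[seg_id]] <- tibble(bin = profile$bin[member], segment = seg_id)
    }
  }
  out <- structure(
    list(
      segments = bind_rows(seg_rows),
      bins = bind_rows(bin_rows),
      sigma = sigma,
      sample_id = attr(profile, "sample_id"),
      settings = list(alpha = alpha, n_permutations = n_permutations,
                      undo_sd = undo_sd, min_width = min_width, seed = seed)
    ),
    class = "cnv_segments"
  )
  if (undo_sd > 0) out <- undo_splits(out, undo_sd = undo_sd) else out
}

#' Merge segments whose means differ by less than a noise multiple
#'
#' Iteratively merges, within each chromosome, the adjacent segment pair
#' with the smallest mean difference while that difference is below
#' `undo_sd * sigma`, where sigma is the profile's robust noise scale
#' (MAD of successive bin differences / sqrt(2)). Merged means are
#' bin-weighted, so the partition and weighted-mean invariants are
#' preserved. Raising `undo_sd` can only reduce the segment count.
#'
#' @param segments A `cnv_segments` object.
#' @param undo_sd Multiplier on the noise scale (default: value stored in
#'   the settings).
#' @param sigma Noise scale; defaults to the scale stored at
#'   segmentation time.
#' @return The pruned `cnv_segments` object.
#' @export
undo_splits <- function(segments, undo_sd = NULL, sigma = NULL) {
  stopifnot(inherits(segments, "cnv_segments"))
  if (is.null(undo_sd)) undo_sd <- segments$settings$undo_sd
  if (is.null(sigma)) sigma <- segments$sigma
  thr <- undo_sd * sigma
  seg <- segments$segments
  if (nrow(seg) <= 1 || thr <= 0) return(segments)
  pieces <- split(seq_len(nrow(seg)), factor(seg$chrom, levels = unique(seg$chrom)))
  new_rows <- list()
  bin_map <- segments$bins
  new_id <- 0L
  for (rows in pieces) {
    s <- seg[rows, , drop = FALSE]
    repeat {
      if (nrow(s) <= 1) break
      d <- abs(diff(s$mean_log2))
      m <- which.min(d)
      if (d[m] >= thr) break
      n1 <- s$n_bins[m]; n2 <- s$n_bins[m + 1]
      s$mean_log2[m] <- (s$mean_log2[m] * n1 + s$mean_log2[m + 1] * n2) / (n1 + n2)
      s$n_bins[m] <- n1 + n2
      s$last_bin[m] <- s$last_bin[m + 1]
      s$end[m] <- s$end[m + 1]
      bin_map$segment[bin_map$segment == s$segment[m + 1]] <- s$segment[m]
      s <- s[-(m + 1), , drop = FALSE]
    }
    new_rows[[length(new_rows) + 1L]] <- s
  }
  merged <- bind_rows(new_rows)
  # renumber segments 1..K in genome order, remapping the bin table
  remap <- setNames(seq_len(nrow(merged)), merged$segment)
  merged$segment <- seq_len(nrow(merged))
  bin_map$segment <- unname(remap[as.character(bin_map$segment)])
  segments$segments <- merged
  segments$bins <- bin_map
  segments$settings$undo_sd <- undo_sd
  segments
}

#' @export
print.cnv_segments <- function(x, ...) {
  cat(sprintf("<cnv_segments> '%s': %d segment(s) on %d chromosome(s), sigma = %.4g\n",
              x$sample_id, nrow(x$segments), length(unique(x$segments$chrom)),
              x$sigma))
  invisible(x)
}

#' Segment table of a segmented profile
#'
#' @param x A `cnv_segments` object.
#' @param ... Unused.
#' @return Tibble of segments with coordinates, sizes and means.
#' @method tidy cnv_segments
#' @export
tidy.cnv_segments <- function(x, ...) x$segments

#' Per-bin segment means
#'
#' Expands a segmentation to one value per non-missing bin; useful for
#' plotting and for comparing segmentations against the underlying
#' profile.
#'
#' @param segments A `cnv_segments` object.
#' @return Tibble with `bin`, `segment` and `seg_mean`.
#' @export
segment_means_by_bin <- function(segments) {
  stopifnot(inherits(segments, "cnv_segments"))
  left_join(segments$bins,
            segments$segments[, c("segment", "mean_log2")],
            by = "segment") %>%
    dplyr::rename(seg_mean = "mean_log2")
}
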