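#' Binomially thin a count profile to a target depth
#'
#' Each bin count is thinned with probability `depth / total`, which is
#' statistically equivalent to random read subsampling for a counting
#' pipeline but runs at desk scale.
#'
#' @param counts A `cnv_counts` tibble.
#' @param depth Target number of retained reads (expectation).
#' @return A thinned `cnv_counts` tibble.
#' @export
thin_counts <- function(counts, depth) {
  stopifnot(inherits(counts, "cnv_counts"))
  total <- sum(counts$count)
  if (depth > total) {
    warn(sprintf("target depth %g > total %g; counts returned unchanged",
                 depth, total))
    return(counts)
  }
  if (depth == total) return(counts)  # probability-1 thinning is the identity
  p <- depth / total
  out <- counts
  out$count <- rbinom(nrow(counts), counts$count, p)
  attr(out, "total_mapped_reads") <- sum(out$count)
  out
}

#' Determine the minimum sequencing depth for stable profiles
#'
#' Subsamples a deeply sequenced cell to each candidate depth (binomial
#' thinning, `iterations` times per depth), re-runs normalization (and
#' dewaving when a panel is given), and computes the Spearman correlation
#' of each subsampled log2 profile with the full-depth profile over their
#' common non-missing bins. The recommended minimum depth is the smallest
#' tested depth whose mean correlation reaches `r_threshold`; when every
#' depth fails, the recommendation is `NA` ("none").
#'
#' @param counts A `cnv_counts` tibble, deeper than the largest tested
#'   depth.
#' @param depths Candidate depths in reads (default 0.5, 1, 2.5 and 5
#'   million).
#' @param iterations Thinning replicates per depth (default 10).
#' @param r_threshold Mean Spearman correlation required (default 0.9).
#' @param panel Optional `cnv_panel` for dewaving each replicate.
#' @param seed Optional RNG seed.
#' @param ... Passed to [normalize_profile()].
#' @return A `depth_recommendation` object: per-depth tibble
#'   (`depth`, `mean_r`, `min_r`, `max_r`), the per-iteration
#'   correlations, and `recommended` (smallest passing depth or `NA`).
#' @export
determine_min_depth <- function(counts, depths = c(0.5e6, 1e6, 2.5e6, 5e6),
                                iterations = 10, r_threshold = 0.9,
                                panel = NULL, seed = NULL, ...) {
  stopifnot(inherits(counts, "cnv_counts"))
  total <- sum(counts$count)
  usable <- depths[depths <= total]
  skipped <- depths[depths > total]
  if (length(skipped) > 0) {
    warn(sprintf("depth(s) %s > total reads %g skipped",
                 paste(format(skipped, big.mark = ","), collapse = ", "), total))
  }
  if (length(usable) == 0) abort("total reads must exceed the smallest depth")
  if (!is.null(seed)) set.seed(seed)

  full <- normalize_profile(counts, ...)
  if (!is.null(panel)) full <- dewave(full, panel)
  ref <- full$log2

  cors <- tidyr::crossing(depth = sort(usable), iteration = seq_len(iterations))
  r_vals <- numeric(nrow(cors))
  for (i in seq_len(nrow(cors))) {
    thin <- suppressWarnings(thin_counts(counts, cors$depth[i]))
    prof <- suppressWarnings(normalize_profile(thin, ...))
    if (!is.null(panel)) prof <- suppressWarnings(dewave(prof, panel))
    common <- !is.na(ref) & !is.na(prof$log2)
    r_vals[i] <- cor(ref[common], prof$log2[common], method = "spearman")
  }
  cors$r <- r_vals
  summary <- cors %>%
    group_by(.data$depth) %>%
    summarise(mean_r = mean(.data$r), min_r = min(.data$r),
              max_r = max(.data$r), .groups = "drop")
  passing <- summary$depth[summary$mean_r >= r_threshold]
  structure(
    list(
      summary = summary, correlations = cors,
      recommended = if (length(passing) > 0) min(passing) else NA_real_,
      r_threshold = r_threshold, iterations = iterations,
      sample_id = attr(counts, "sample_id")
    ),
    class = "depth_recommendation"
  )
}

#' @export
print.depth_recommendation <- function(x, ...) {
  rec <- if (is.na(x$recommended)) "none" else
    format(x$recommended, big.mark = ",")
  cat(sprintf("<depth_recommendation> '%s': recommended minimum depth %s (mean r >= %g)\n",
              x$sample_id, rec, x$r_threshold))
  print(x$summary)
  invisible(x)
}

#' @method tidy depth_recommendation
#' @export
tidy.depth_recommendation <- function(x, ...) x$summary

#' @method glance depth_recommendation
#' @export
glance.depth_recommendation <- function(x, ...) {
  tibble(sample_id = x$sample_id, recommended_depth = x$recommended,
         r_threshold = x$r_threshold, iterations = x$iterations)
}
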