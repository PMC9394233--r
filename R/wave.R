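#' Build a calibration panel of copy-number-neutral profiles
#'
#' Single-cell low-pass profiles carry a smooth, GC-correlated "wave"
#' bias plus locus-specific amplification bias that is shared across
#' cells prepared the same way. A panel of copy-number-neutral cells
#' (leukocytes) captures this shared structure so it can be regressed out
#' of tumour-cell profiles.
#'
#' Each member is regressed (ordinary least squares with intercept) on
#' all other members over the bins where every member is non-missing and
#' usable; the variance of its residuals is its wave variance. Members
#' whose wave variance exceeds `variance_threshold` are excluded in one
#' pass -- their own noise dominates the shared wave and they would
#' dilute the correction. A singular design (e.g. duplicated profiles)
#' falls back to a lightly ridged solve (penalty 1e-6), with a message.
#'
#' @param normals List of `cnv_profile` objects sharing one grid.
#' @param variance_threshold Exclusion threshold on the leave-one-out
#'   residual variance (default 0.05).
#' @param min_common_bins Minimum jointly non-missing bins required
#'   (default 50).
#' @param autosomes_only Restrict the panel to autosomes (default
#'   `TRUE`); set `FALSE` together with a single-sex panel to correct the
#'   sex chromosomes as well.
#' @return A `cnv_panel` object: the member log2 matrix, a member table
#'   (`sample_id`, `wave_variance`, `retained`) and the settings used.
#' @export
build_calibration_panel <- function(normals, variance_threshold = 0.05,
                                    min_common_bins = 50,
                                    autosomes_only = TRUE) {
  if (length(normals) < 2) abort("a calibration panel needs at least 2 normals")
  ids <- vapply(normals, function(p) attr(p, "sample_id"), character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  ref <- normals[[1]]
  for (p in normals[-1]) {
    if (nrow(p) != nrow(ref) || !all(p$chrom == ref$chrom & p$start == ref$start)) {
      abort("all panel members must share one bin grid")
    }
  }
  keep_bins <- ref$usable
  if (autosomes_only) keep_bins <- keep_bins & !.is_sex_chrom(ref$chrom)
  mat <- vapply(normals, function(p) p$log2, numeric(nrow(ref)))
  colnames(mat) <- ids
  mat[!keep_bins, ] <- NA_real_

  common <- complete.cases(mat)
  if (sum(common) < min_common_bins) {
    abort(sprintf("only %d jointly non-missing bins (need >= %d)",
                  sum(common), min_common_bins))
  }
  m <- mat[common, , drop = FALSE]
  wave_var <- vapply(seq_along(ids), function(i) {
    res <- .ols_residuals(m[, i], m[, -i, drop = FALSE])
    var(res)
  }, numeric(1))
  retained <- wave_var <= variance_threshold
  if (!any(retained)) abort("no panel member passed the variance threshold")
  if (sum(retained) < 6) {
    warn(sprintf("only %d panel member(s) retained; at least 6 are recommended",
                 sum(retained)))
  }
  structure(
    list(
      log2 = mat,
      members = tibble(sample_id = ids, wave_variance = wave_var,
                       retained = retained),
      variance_threshold = variance_threshold,
      autosomes_only = autosomes_only,
      grid_info = list(chrom = ref$chrom, start = ref$start,
                       bin_size = attr(ref, "bin_size"))
    ),
    class = "cnv_panel"
  )
}

.is_sex_chrom <- function(chrom) {
  sub("^chr", "", chrom) %in% c("X", "Y")
}

# OLS residuals with intercept; ridge fallback (penalty 1e-6) on singular fits
.ols_residuals <- function(y, X, return_fitted = FALSE) {
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- lm.fit(Xi, y)
  if (fit$rank < ncol(Xi)) {
    inform("singular panel design; using ridge fallback (penalty 1e-6)")
    XtX <- crossprod(Xi) + diag(1e-6, ncol(Xi))
    beta <- solve(XtX, crossprod(Xi, y))
    fitted <- drop(Xi %*% beta)
  } else {
    fitted <- fit$fitted.values
  }
  if (return_fitted) fitted else y - fitted
}

#' @export
print.cnv_panel <- function(x, ...) {
  cat(sprintf("<cnv_panel> %d member(s), %d retained at variance <= %g\n",
              nrow(x$members), sum(x$members$retained), x$variance_threshold))
  invisible(x)
}

#' Per-member panel summary
#'
#' @param x A `cnv_panel`.
#' @param ... Unused.
#' @return Tibble with one row per member: `sample_id`, `wave_variance`,
#'   `retained`.
#' @method tidy cnv_panel
#' @export
tidy.cnv_panel <- function(x, ...) x$members

#' Remove shared wave bias from a profile
#'
#' Regresses the profile's log2 ratios (OLS with intercept) on the
#' retained calibration-panel members over the jointly non-missing bins,
#' subtracts the fitted shared component, and re-centres the result to
#' median 0. True copy-number structure is essentially orthogonal to the
#' panel (the panel is copy-number neutral), so segment means survive
#' while wave and shared amplification bias are removed. Bins missing in
#' the input remain missing; bins without panel coverage are only
#' re-centred.
#'
#' @param profile A `cnv_profile`.
#' @param panel A `cnv_panel` built on the same grid.
#' @param min_common_bins Below this number of jointly non-missing bins
#'   the profile is returned unchanged with a warning (default 50).
#' @return The corrected `cnv_profile` (attribute
#'   `corrections$dewaved = TRUE`; noise metrics recomputed).
#' @export
dewave <- function(profile, panel, min_common_bins = 50) {
  stopifnot(inherits(profile, "cnv_profile"), inherits(panel, "cnv_panel"))
  if (nrow(profile) != nrow(panel$log2) ||
      !all(profile$chrom == panel$grid_info$chrom)) {
    abort("profile and panel do not share a grid")
  }
  keep <- panel$members$retained
  if (!any(keep)) abort("panel has no retained members")
  X <- panel$log2[, keep, drop = FALSE]
  y <- profile$log2
  common <- !is.na(y) & complete.cases(X)
  if (sum(common) < min_common_bins) {
    warn(sprintf("only %d bins shared with the panel; profile returned unchanged",
                 sum(common)))
    return(profile)
  }
  fitted <- .ols_residuals(y[common], X[common, , drop = FALSE],
                           return_fitted = TRUE)
  out <- y
  out[common] <- y[common] - fitted
  out <- out - median(out, na.rm = TRUE)

  res <- profile
  res$log2 <- out
  attr(res, "sigma_delta") <- sigma_delta(out, res$chrom)
  corr <- attr(res, "corrections")
  corr$dewaved <- TRUE
  attr(res, "corrections") <- corr
  res
}
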