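#' Tile chromosomes into fixed-width bins
#'
#' Divides each chromosome into contiguous, non-overlapping, half-open
#' bins of `bin_size` bp. The last bin of a chromosome is truncated at the
#' chromosome end, so every chromosome contributes
#' `ceiling(length / bin_size)` bins. The grid is the coordinate system
#' for all downstream per-bin profiles; the global bin index is a stable
#' key.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp;
#'   chromosome order is taken from the vector's order.
#' @param bin_size Bin width in bp (default 100 000, the resolution at
#'   which low-pass single-cell profiles retain most usable bins).
#' @return A `cnv_grid` tibble with columns `bin` (1-based global index),
#'   `chrom`, `start`, `end` (0-based half-open), `gc`, `mappability`
#'   (both `NA` until annotated) and `usable` (all `TRUE` until
#'   annotated). Attributes `bin_size` and `chrom_lengths` record the
#'   construction.
#' @examples
#' grid <- make_bin_grid(c(chrA = 250000), bin_size = 100000)
#' grid$end # 100000 200000 250000
#' @export
make_bin_grid <- function(chrom_lengths, bin_size = 1e5) {
  if (length(bin_size) != 1 || !is.finite(bin_size) || bin_size <= 0) {
    abort("`bin_size` must be a single positive number")
  }
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    abort("`chrom_lengths` must be a named vector")
  }
  bad <- names(chrom_lengths)[!is.finite(chrom_lengths) | chrom_lengths <= 0]
  if (length(bad) > 0) {
    abort(paste0("non-positive length for chromosome(s): ",
                 paste(bad, collapse = ", ")))
  }
  bin_size <- as.numeric(bin_size)
  pieces <- lapply(names(chrom_lengths), function(ch) {
    len <- as.numeric(chrom_lengths[[ch]])
    n <- ceiling(len / bin_size)
    start <- (seq_len(n) - 1) * bin_size
    tibble(chrom = ch, start = start, end = pmin(start + bin_size, len))
  })
  grid <- bind_rows(pieces)
  grid <- tibble(
    bin = seq_len(nrow(grid)), chrom = grid$chrom,
    start = grid$start, end = grid$end,
    gc = NA_real_, mappability = NA_real_, usable = TRUE
  )
  structure(grid,
    class = c("cnv_grid", class(grid)),
    bin_size = bin_size,
    chrom_lengths = chrom_lengths
  )
}

#' @export
print.cnv_grid <- function(x, ...) {
  cat(sprintf("<cnv_grid> %d bins of %s bp on %d chromosome(s); %d usable\n",
              nrow(x), format(attr(x, "bin_size"), big.mark = ","),
              length(unique(x$chrom)), sum(x$usable)))
  NextMethod()
}

.check_intervals <- function(x, what) {
  need <- c("chrom", "start", "end")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort(paste0("`", what, "` must be a data frame with columns chrom, start, end"))
  }
  if (any(x$start >= x$end)) {
    abort(paste0("malformed interval in `", what, "`: start >= end"))
  }
  invisible(x)
}

# bp overlap of each grid bin with a set of intervals (per chromosome sweep)
.bin_overlap_bp <- function(grid, intervals) {
  ov <- numeric(nrow(grid))
  for (ch in unique(intervals$chrom)) {
    idx <- which(grid$chrom == ch)
    if (length(idx) == 0) next
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(iv))) {
      ov[idx] <- ov[idx] + pmax(
        0, pmin(grid$end[idx], iv$end[k]) - pmax(grid$start[idx], iv$start[k])
      )
    }
  }
  ov
}

# mean of a (chrom,start,end,value) track over each bin, weighted by overlap
.bin_track_mean <- function(grid, track) {
  num <- numeric(nrow(grid))
  den <- numeric(nrow(grid))
  for (ch in unique(track$chrom)) {
    idx <- which(grid$chrom == ch)
    if (length(idx) == 0) next
    tr <- track[track$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(tr))) {
      w <- pmax(0, pmin(grid$end[idx], tr$end[k]) - pmax(grid$start[idx], tr$start[k]))
      num[idx] <- num[idx] + w * tr$value[k]
      den[idx] <- den[idx] + w
    }
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Annotate a bin grid with blacklist, GC and mappability
#'
#' Marks bins unusable when their overlap with blacklisted regions
#' (telomeres, centromeres, poorly mappable regions and similar) reaches
#' `overlap_fraction_threshold`, or when their mean mappability falls
#' below `min_mappability`. When GC or mappability tracks are supplied,
#' per-bin overlap-weighted means are stored for use by
#' [normalize_profile()].
#'
#' @param grid A `cnv_grid`.
#' @param blacklist Data frame of excluded intervals (`chrom`, `start`,
#'   `end`; 0-based half-open), or `NULL`.
#' @param gc_track,mappability_track Optional data frames (`chrom`,
#'   `start`, `end`, `value`) giving GC fraction and mappability in
#'   `[0, 1]`.
#' @param overlap_fraction_threshold A bin is unusable when its
#'   blacklist-overlap fraction is at least this value (default 0.5).
#' @param min_mappability Bins with annotated mappability below this are
#'   unusable (default 0, i.e. no filter).
#' @return The grid with `gc`, `mappability` and `usable` filled in.
#' @export
annotate_bins <- function(grid, blacklist = NULL, gc_track = NULL,
                          mappability_track = NULL,
                          overlap_fraction_threshold = 0.5,
                          min_mappability = 0) {
  stopifnot(inherits(grid, "cnv_grid"))
  usable <- rep(TRUE, nrow(grid))
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    .check_intervals(blacklist, "blacklist")
    stray <- setdiff(unique(blacklist$chrom), unique(grid$chrom))
    if (length(stray) > 0) {
      warn(paste0("blacklist chromosome(s) not in grid, ignored: ",
                  paste(stray, collapse = ", ")))
    }
    frac <- .bin_overlap_bp(grid, blacklist) / (grid$end - grid$start)
    usable <- usable & (frac < overlap_fraction_threshold)
  }
  if (!is.null(gc_track)) {
    .check_intervals(gc_track, "gc_track")
    grid$gc <- .bin_track_mean(grid, gc_track)
  }
  if (!is.null(mappability_track)) {
    .check_intervals(mappability_track, "mappability_track")
    grid$mappability <- .bin_track_mean(grid, mappability_track)
  }
  if (min_mappability > 0) {
    usable <- usable & (!is.na(grid$mappability) & grid$mappability >= min_mappability)
  }
  grid$usable <- usable
  grid
}
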