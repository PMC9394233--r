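#' Count aligned reads per bin
#'
#' Assigns each retained alignment record to exactly one bin, keyed by the
#' leftmost aligned base. Secondary, supplementary and unmapped records
#' are always excluded; duplicates are excluded when `dedup = TRUE`;
#' records below `min_mapq` are excluded. In `"fragment"` mode a properly
#' paired fragment is counted once, via its leftmost mate (ties broken by
#' the first-of-pair flag); `"read"` mode counts every retained read.
#' Chromosome naming is normalized so that `chr1`/`1` mismatches between
#' the grid and the alignment header are tolerated.
#'
#' Reads on chromosomes absent from the grid are tallied as unassigned
#' (reported in the result's attributes), not dropped silently.
#'
#' @param bam_file Path to a coordinate-sorted, indexed BAM file.
#' @param grid A `cnv_grid`.
#' @param min_mapq Minimum mapping quality (default 20).
#' @param dedup Exclude records flagged as PCR/optical duplicates
#'   (default `TRUE`).
#' @param paired_mode `"fragment"` (default) or `"read"`.
#' @return A `cnv_counts` tibble: the grid columns plus `count`, with
#'   attributes `sample_id`, `total_mapped_reads` (retained records),
#'   `unassigned` and `filter_settings`.
#' @export
count_reads <- function(bam_file, grid, min_mapq = 20, dedup = TRUE,
                        paired_mode = c("fragment", "read")) {
  stopifnot(inherits(grid, "cnv_grid"))
  paired_mode <- match.arg(paired_mode)
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("count_reads() requires the Rsamtools package")
  }
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (dedup) FALSE else NA
  )
  param <- Rsamtools::ScanBamParam(
    flag = flags, what = c("rname", "pos", "mapq", "flag", "mpos")
  )
  rec <- Rsamtools::scanBam(bam_file, param = param)[[1]]
  keep <- !is.na(rec$pos) & !is.na(rec$mapq) & rec$mapq >= min_mapq
  if (paired_mode == "fragment") {
    fl <- rec$flag
    paired <- bitwAnd(fl, 1L) > 0L
    mate_unmapped <- bitwAnd(fl, 8L) > 0L
    first <- bitwAnd(fl, 64L) > 0L
    leftmost <- !paired | mate_unmapped | is.na(rec$mpos) |
      rec$pos < rec$mpos | (rec$pos == rec$mpos & first)
    keep <- keep & leftmost
  }
  chrom <- as.character(rec$rname)[keep]
  pos <- rec$pos[keep]
  assemble_bin_counts(grid, chrom, pos, sample_id = basename(bam_file),
                      filter_settings = list(min_mapq = min_mapq, dedup = dedup,
                                             paired_mode = paired_mode))
}

# Shared by count_reads() and tests: per-record bin assignment from
# (chrom, 1-based leftmost pos) vectors.
#' Assemble per-bin counts from read positions
#'
#' Low-level constructor used by [count_reads()]: bins records by their
#' 1-based leftmost position. Exposed so count tables can be built from
#' any alignment source.
#'
#' @param grid A `cnv_grid`.
#' @param chrom,pos Equal-length vectors of chromosome names and 1-based
#'   leftmost positions of retained records.
#' @param sample_id Sample identifier stored on the result.
#' @param filter_settings List recording the filters applied upstream.
#' @return A `cnv_counts` tibble.
#' @export
assemble_bin_counts <- function(grid, chrom, pos, sample_id = "sample",
                                filter_settings = list()) {
  stopifnot(inherits(grid, "cnv_grid"), length(chrom) == length(pos))
  norm <- function(x) sub("^chr", "", x)
  grid_chroms <- unique(grid$chrom)
  map <- setNames(grid_chroms, norm(grid_chroms))
  matched <- map[norm(chrom)]
  unassigned <- sum(is.na(matched))
  if (unassigned > 0) {
    warn(sprintf("%d record(s) on chromosomes absent from the grid counted as unassigned",
                 unassigned))
  }
  bin_size <- attr(grid, "bin_size")
  counts <- integer(nrow(grid))
  ok <- !is.na(matched)
  if (any(ok)) {
    # offset of first bin of each chromosome in the global index
    first_bin <- vapply(grid_chroms, function(ch) min(grid$bin[grid$chrom == ch]),
                        numeric(1))
    n_bins <- vapply(grid_chroms, function(ch) sum(grid$chrom == ch), numeric(1))
    within <- floor((pos[ok] - 1) / bin_size)          # 0-based bin within chrom
    within <- pmin(within, n_bins[matched[ok]] - 1)    # clamp tail positions
    gbin <- first_bin[matched[ok]] + within
    tab <- tabulate(gbin, nbins = nrow(grid))
    counts <- as.integer(tab)
  }
  out <- as_tibble(grid)
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out$count <- counts
  structure(out,
    class = c("cnv_counts", class(out)),
    sample_id = sample_id,
    total_mapped_reads = sum(ok),
    unassigned = unassigned,
    bin_size = bin_size,
    filter_settings = filter_settings
  )
}

#' Read a per-bin count table from TSV
#'
#' Accepts the tab-separated format written by [write_counts_tsv()]
#' (header `chrom`, `start`, `end`, `count`); rows must match the grid
#' bin-for-bin.
#'
#' @param path TSV file path.
#' @param grid A `cnv_grid`.
#' @param sample_id Sample identifier; defaults to the file name.
#' @return A `cnv_counts` tibble.
#' @export
read_bin_counts <- function(path, grid, sample_id = basename(path)) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "count")
  if (!all(need %in% names(tab))) {
    abort("count TSV must have columns chrom, start, end, count")
  }
  if (nrow(tab) != nrow(grid) ||
      !all(tab$chrom == grid$chrom & tab$start == grid$start)) {
    abort("count TSV does not match the bin grid")
  }
  out <- as_tibble(grid)
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out$count <- as.integer(tab$count)
  structure(out,
    class = c("cnv_counts", class(out)),
    sample_id = sample_id,
    total_mapped_reads = sum(out$count),
    unassigned = 0L,
    bin_size = attr(grid, "bin_size"),
    filter_settings = list(source = "tsv")
  )
}

#' Write a per-bin count table to TSV
#'
#' @param counts A `cnv_counts` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "cnv_counts"))
  utils::write.table(
    counts[, c("chrom", "start", "end", "count")], path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
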