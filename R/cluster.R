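#' Condense per-bin calls into constant-call regions
#'
#' Across a set of called profiles sharing one grid, maximal runs of
#' consecutive same-chromosome bins over which *every* sample's hard call
#' is unchanged are collapsed into single regions. Regions are the unit
#' of the clustering heatmap: their widths reflect informative breakpoint
#' structure, not physical size. Region posteriors are the bin means
#' within the region (constant by construction for the hard call, and in
#' practice for posteriors, which are shared within segments).
#'
#' Only bins called in every sample (the common usable intersection)
#' participate.
#'
#' @param profiles List of `cnv_calls` tibbles on one grid.
#' @return A `cnv_regions` object: `regions` tibble (`region`, `chrom`,
#'   `first_bin`, `last_bin`, `n_bins`), a regions x samples `calls`
#'   matrix, and a regions x samples x states `posteriors` array.
#' @export
condense_calls <- function(profiles) {
  if (length(profiles) < 1) abort("need at least one called profile")
  ids <- vapply(profiles, function(p) attr(p, "sample_id"), character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  common <- Reduce(intersect, lapply(profiles, function(p) p$bin[!is.na(p$call)]))
  if (length(common) == 0) abort("no bin is called in every sample")
  common <- sort(common)

  ref <- profiles[[1]]
  pos <- match(common, ref$bin)
  chrom <- ref$chrom[pos]
  post_cols <- grep("^p_", names(ref), value = TRUE)
  states <- sub("^p_", "", post_cols)

  calls <- vapply(profiles, function(p) p$call[match(common, p$bin)],
                  integer(length(common)))
  colnames(calls) <- ids
  n <- length(common)
  if (n == 1) {
    new_region <- TRUE
  } else {
    changed <- rowSums(calls[-1, , drop = FALSE] != calls[-n, , drop = FALSE]) > 0
    new_region <- c(TRUE, chrom[-1] != chrom[-n] | changed)
  }
  region_id <- cumsum(new_region)

  regions <- tibble(bin = common, chrom = chrom, region = region_id) %>%
    group_by(.data$region, .data$chrom) %>%
    summarise(first_bin = min(.data$bin), last_bin = max(.data$bin),
              n_bins = n(), .groups = "drop") %>%
    arrange(.data$region)

  k <- nrow(regions)
  call_mat <- matrix(NA_integer_, k, length(ids), dimnames = list(NULL, ids))
  post <- array(NA_real_, dim = c(k, length(ids), length(states)),
                dimnames = list(NULL, ids, states))
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    rows <- match(common, p$bin)
    rf <- factor(region_id, levels = unique(region_id))
    call_mat[, j] <- vapply(split(p$call[rows], rf),
                            function(v) v[1], integer(1))
    for (s in seq_along(states)) {
      post[, j, s] <- vapply(split(p[[post_cols[s]]][rows], rf),
                             mean, numeric(1))
    }
  }
  structure(
    list(regions = regions, calls = call_mat, posteriors = post,
         sample_ids = ids, states = states),
    class = "cnv_regions"
  )
}

#' @export
print.cnv_regions <- function(x, ...) {
  cat(sprintf("<cnv_regions> %d region(s) x %d sample(s) over %d bin(s)\n",
              nrow(x$regions), length(x$sample_ids), sum(x$regions$n_bins)))
  invisible(x)
}

#' Expand condensed regions back to per-bin calls
#'
#' Inverse of [condense_calls()] on the common bins; mainly a
#' consistency check.
#'
#' @param regions A `cnv_regions` object.
#' @return Tibble with `bin` and one call column per sample.
#' @export
expand_regions <- function(regions) {
  stopifnot(inherits(regions, "cnv_regions"))
  reg <- regions$regions
  idx <- rep(seq_len(nrow(reg)), reg$n_bins)
  out <- tibble(region = idx)
  for (j in seq_along(regions$sample_ids)) {
    out[[regions$sample_ids[j]]] <- regions$calls[idx, j]
  }
  out
}

#' Weighted call-concordance distance between called samples
#'
#' `d(A, B) = 1 - sum_r w_r sum_s p_Ars p_Brs / sum_r w_r`, where `w_r`
#' is the region's bin count and `p` are per-state posteriors ("soft"
#' mode): the bin-weighted probability that two samples share the same
#' call, subtracted from 1. `"hard"` mode uses the bin-weighted Hamming
#' distance of the hard calls instead. Both are symmetric and bounded in
#' `[0, 1]`; the soft distance is 0 on identical samples only when the
#' posteriors are certain.
#'
#' @param regions A `cnv_regions` object.
#' @param method `"soft"` (default) or `"hard"`.
#' @return Symmetric distance matrix (samples x samples).
#' @export
region_distance <- function(regions, method = c("soft", "hard")) {
  stopifnot(inherits(regions, "cnv_regions"))
  method <- match.arg(method)
  w <- regions$regions$n_bins
  ids <- regions$sample_ids
  m <- length(ids)
  k <- nrow(regions$regions)
  ns <- length(regions$states)
  slice <- function(j) {
    p <- regions$posteriors[, j, , drop = FALSE]
    dim(p) <- c(k, ns)
    p
  }
  d <- matrix(0, m, m, dimnames = list(ids, ids))
  for (a in seq_len(m - 1)) {
    for (b in (a + 1):m) {
      if (method == "soft") {
        conc <- rowSums(slice(a) * slice(b))
      } else {
        conc <- as.numeric(regions$calls[, a] == regions$calls[, b])
      }
      d[a, b] <- d[b, a] <- 1 - sum(w * conc) / sum(w)
    }
  }
  d
}

#' Cluster called samples on condensed regions
#'
#' Agglomerative hierarchical clustering of the weighted call-concordance
#' distances, the backbone of the cohort heatmap: tumour cells group by
#' clone while copy-number-flat ("leukocyte-like") cells collect in their
#' own branch.
#'
#' @param regions A `cnv_regions` object with at least 2 samples.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param method Distance mode, `"soft"` or `"hard"` (see
#'   [region_distance()]).
#' @return A `cnv_clustering` object: the distance matrix, the `hclust`
#'   tree, the leaf order and a long heatmap tibble (`region`, `chrom`,
#'   `weight`, `sample_id`, `call`).
#' @export
cluster_samples <- function(regions, linkage = "average",
                            method = c("soft", "hard")) {
  stopifnot(inherits(regions, "cnv_regions"))
  ids <- regions$sample_ids
  if (length(ids) < 2) {
    warn("fewer than 2 samples; returning a degenerate clustering")
  }
  d <- region_distance(regions, method = method)
  tree <- if (length(ids) >= 2) hclust(as.dist(d), method = linkage) else NULL
  heat <- tidyr::crossing(
    region = regions$regions$region, sample_id = ids
  ) %>%
    left_join(regions$regions[, c("region", "chrom", "n_bins")], by = "region") %>%
    mutate(call = regions$calls[cbind(.data$region, match(.data$sample_id, ids))]) %>%
    dplyr::rename(weight = "n_bins")
  structure(
    list(distance = d, tree = tree,
         order = if (is.null(tree)) ids else ids[tree$order],
         heatmap = heat, linkage = linkage),
    class = "cnv_clustering"
  )
}

#' @export
print.cnv_clustering <- function(x, ...) {
  cat(sprintf("<cnv_clustering> %d sample(s), %s linkage; leaf order: %s\n",
              nrow(x$distance), x$linkage, paste(x$order, collapse = ", ")))
  invisible(x)
}

#' Export a clustering dendrogram as Newick
#'
#' @param clustering A `cnv_clustering` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(clustering, path) {
  stopifnot(inherits(clustering, "cnv_clustering"))
  if (is.null(clustering$tree)) abort("degenerate clustering has no tree")
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("export_newick() requires the ape package")
  }
  ape::write.tree(ape::as.phylo(clustering$tree), file = path)
  invisible(path)
}

#' Aggregate calls over a genomic interval
#'
#' Reports, per sample, a single call for a region of interest (a gene
#' locus, say): amplification when any overlapped bin is amplified,
#' otherwise the majority call over the overlapped bins, ties broken
#' towards the higher state. Samples with no usable called bin in the
#' interval get the explicit verdict `"no_resolution"` rather than a
#' call.
#'
#' @param profiles List of `cnv_calls`.
#' @param grid The shared `cnv_grid`.
#' @param interval Either a string `"chrom:start-end"` (1-based,
#'   inclusive, as in a genome browser) or a list/one-row data frame with
#'   `chrom`, `start`, `end` in 0-based half-open coordinates.
#' @return Tibble with `sample_id`, `n_bins`, `call` and `verdict`
#'   (`"called"` or `"no_resolution"`).
#' @export
query_region <- function(profiles, grid, interval) {
  iv <- .parse_interval(interval)
  hit <- grid$bin[grid$chrom == iv$chrom & grid$start < iv$end &
                    grid$end > iv$start]
  if (length(hit) == 0) {
    abort(sprintf("interval %s:%d-%d overlaps no bin of the grid",
                  iv$chrom, iv$start, iv$end))
  }
  rows <- lapply(profiles, function(p) {
    calls <- p$call[p$bin %in% hit & !is.na(p$call)]
    if (length(calls) == 0) {
      tibble(sample_id = attr(p, "sample_id"), n_bins = 0L,
             call = NA_integer_, verdict = "no_resolution")
    } else {
      call <- if (any(calls == 2L)) 2L else {
        tab <- table(calls)
        best <- as.integer(names(tab)[tab == max(tab)])
        max(best) # ties towards the higher state
      }
      tibble(sample_id = attr(p, "sample_id"), n_bins = length(calls),
             call = call, verdict = "called")
    }
  })
  bind_rows(rows)
}

.parse_interval <- function(interval) {
  if (is.character(interval) && length(interval) == 1) {
    m <- regmatches(interval,
                    regexec("^([^:]+):([0-9]+)-([0-9]+)$", interval))[[1]]
    if (length(m) != 4) abort("interval string must look like 'chr8:128700000-128800000'")
    # browser convention is 1-based inclusive; convert to 0-based half-open
    list(chrom = m[2], start = as.numeric(m[3]) - 1, end = as.numeric(m[4]))
  } else if (is.list(interval) && all(c("chrom", "start", "end") %in% names(interval))) {
    list(chrom = interval$chrom[1], start = as.numeric(interval$start[1]),
         end = as.numeric(interval$end[1]))
  } else {
    abort("cannot interpret `interval`")
  }
}
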