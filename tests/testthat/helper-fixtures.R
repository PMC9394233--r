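# Shared fixture builders: everything is generated in code at test time.

# counts object with an explicit count vector on a given grid
counts_from_vector <- function(grid, counts, sample_id = "s") {
  cc <- assemble_bin_counts(grid, character(0), numeric(0),
                            sample_id = sample_id)
  cc$count <- as.integer(counts)
  attr(cc, "total_mapped_reads") <- sum(counts)
  cc
}

# profile with an explicit log2 vector (bypasses normalization), for
# exercising segmentation/calling on exactly controlled data
profile_from_log2 <- function(grid, log2r, sample_id = "s") {
  cc <- counts_from_vector(grid, rep(100L, nrow(grid)), sample_id)
  prof <- suppressWarnings(normalize_profile(cc, do_gc = FALSE))
  prof$log2 <- log2r
  attr(prof, "sigma_delta") <- sigma_delta(log2r, prof$chrom)
  prof
}

# called profile with explicit hard calls and one-hot posteriors
calls_from_vector <- function(grid, calls, sample_id = "s",
                              certainty = 1) {
  states <- c(-1L, 0L, 1L, 2L)
  post <- matrix((1 - certainty) / 3, length(calls), 4,
                 dimnames = list(NULL, c("p_loss", "p_neutral", "p_gain", "p_amp")))
  post[cbind(seq_along(calls), match(calls, states))] <- certainty
  out <- tibble::tibble(
    bin = grid$bin, chrom = grid$chrom, start = grid$start, end = grid$end,
    segment = cumsum(c(TRUE, diff(calls) != 0 | grid$chrom[-1] != grid$chrom[-nrow(grid)])),
    call = as.integer(calls)
  )
  out$p_loss <- post[, 1]; out$p_neutral <- post[, 2]
  out$p_gain <- post[, 3]; out$p_amp <- post[, 4]
  structure(out, class = c("cnv_calls", "tbl_df", "tbl", "data.frame"),
            sample_id = sample_id,
            states = NULL, priors = NULL, settings = list())
}

# hand-built cnv_segments object for direct caller/undo tests
segments_from_table <- function(seg_tbl, sigma, sample_id = "s") {
  bins <- purrr::map2_dfr(seg_tbl$segment, seq_len(nrow(seg_tbl)), function(id, k) {
    tibble::tibble(bin = seg_tbl$first_bin[k]:seg_tbl$last_bin[k], segment = id)
  })
  structure(list(segments = seg_tbl, bins = bins, sigma = sigma,
                 sample_id = sample_id,
                 settings = list(undo_sd = 4, min_width = 10)),
            class = "cnv_segments")
}

# brute-force CBS statistic oracle: full scan over all admissible (i, j)
oracle_max_stat <- function(x, min_width) {
  n <- length(x)
  best <- list(stat = -Inf, i = NA, j = NA)
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      k <- j - i
      if (k < min_width || (n - k) < min_width) next
      if (i != 0 && i < min_width) next
      if ((n - j) != 0 && (n - j) < min_width) next
      arc <- sum(x[(i + 1):j])
      stat <- abs(arc / k - (sum(x) - arc) / (n - k)) / sqrt(1 / k + 1 / (n - k))
      if (stat > best$stat + 1e-12) best <- list(stat = stat, i = i, j = j)
    }
  }
  best
}

# exact two-sided signed-rank p-value by full enumeration of sign vectors
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  total <- 2^n
  count <- 0
  for (m in 0:(total - 1)) {
    w <- sum(r[bitwAnd(m, 2^(seq_len(n) - 1)) > 0])
    if (abs(w - mu) >= abs(obs - mu) - 1e-9) count <- count + 1
  }
  count / total
}
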