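#' Default pipeline configuration
#'
#' Nested list of every tunable setting of the end-to-end pipeline, each
#' overridable via `...` using `section.key` names (unknown keys are an
#' error, so typos fail fast). The effective configuration is serialized
#' into every run's provenance manifest.
#'
#' Sections: `binning` (bin_size, min_mapq, dedup), `normalize` (do_gc,
#' do_mappability, loess_span, min_usable_bins), `panel`
#' (variance_threshold, autosomes_only), `segmentation` (alpha, nperm,
#' undo_sd, min_width, seed), `calling` (cellularity, relSDlong,
#' long_threshold, five_states, exclude_sex, male_x), `clustering`
#' (linkage, distance), `qc` (qc_pass_threshold, max_empty_fraction,
#' empty_mode, relative_multiple).
#'
#' @param ... Overrides, e.g. `pipeline_config(segmentation.alpha =
#'   0.05, calling.cellularity = 1)`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    binning = list(bin_size = 1e5, min_mapq = 20, dedup = TRUE),
    normalize = list(do_gc = TRUE, do_mappability = FALSE,
                     loess_span = 0.65, min_usable_bins = 100),
    panel = list(variance_threshold = 0.05, autosomes_only = TRUE),
    segmentation = list(alpha = 0.01, nperm = 1000, undo_sd = 4,
                        min_width = 10, seed = 1),
    calling = list(cellularity = 1, relSDlong = 2, long_threshold = 10,
                   five_states = FALSE, exclude_sex = TRUE, male_x = FALSE),
    clustering = list(linkage = "average", distance = "soft"),
    qc = list(qc_pass_threshold = 5, max_empty_fraction = 0.1,
              empty_mode = "relative", relative_multiple = 3)
  )
  dots <- list(...)
  for (key in names(dots)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || is.null(cfg[[parts[1]]]) ||
        !parts[2] %in% names(cfg[[parts[1]]])) {
      abort(sprintf("unknown configuration key '%s'", key))
    }
    cfg[[parts[1]]][[parts[2]]] <- dots[[key]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the end-to-end single-cell CNV pipeline
#'
#' Executes, in order: normalization of every sample and normal, panel
#' construction from the normals, dewaving, empty-bin QC, segmentation,
#' calling (shared priors across the cohort), condensing and clustering.
#' Samples failing a stage (normalization below the usable-bin minimum,
#' empty-bin outliers, a failing band-QC score when provided) are
#' quarantined with a reason and the run continues -- one bad cell never
#' aborts a cohort. Stage outputs are written as plain-text TSV/JSON so
#' any stage can be re-entered from its predecessor's files.
#'
#' @param samples Named list of `cnv_counts` for the cells of interest.
#' @param normals Named list of `cnv_counts` for the calibration panel.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to
#'   skip writing.
#' @param qc_scores Optional tibble from [qc_score()] rows (band QC);
#'   samples below the pass threshold are quarantined up front.
#' @return A `cnv_pipeline_result` list: `profiles`, `panel`, `segments`,
#'   `calls`, `regions`, `clustering`, `quarantine` tibble, `config` and
#'   `ok` (`TRUE` when at least 2 samples reached clustering).
#' @export
run_pipeline <- function(samples, normals, config = pipeline_config(),
                         out_dir = NULL, qc_scores = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(samples) < 1) abort("need at least one sample")
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  quarantine <- tibble(sample_id = character(0), stage = character(0),
                       reason = character(0))
  drop_sample <- function(id, stage, reason) {
    quarantine <<- bind_rows(quarantine,
                             tibble(sample_id = id, stage = stage, reason = reason))
    note("sample %s quarantined at %s: %s", id, stage, reason)
  }

  # band QC gate
  live <- names(samples)
  if (!is.null(qc_scores)) {
    for (i in seq_len(nrow(qc_scores))) {
      id <- qc_scores$sample_id[i]
      if (id %in% live && qc_scores$score[i] < config$qc$qc_pass_threshold) {
        drop_sample(id, "band_qc",
                    sprintf("QC-%d below threshold QC-%d", qc_scores$score[i],
                            config$qc$qc_pass_threshold))
        live <- setdiff(live, id)
      }
    }
  }

  norm_one <- function(counts, id) {
    prof <- withCallingHandlers(
      normalize_profile(counts,
                        do_gc = config$normalize$do_gc,
                        do_mappability = config$normalize$do_mappability,
                        loess_span = config$normalize$loess_span,
                        min_usable_bins = config$normalize$min_usable_bins),
      warning = function(w) invokeRestart("muffleWarning")
    )
    note("sample %s normalized: sigma_delta=%.4g empty=%d", id,
         attr(prof, "sigma_delta"), attr(prof, "empty_bin_count"))
    prof
  }

  normal_profiles <- purrr::imap(normals, norm_one)
  panel <- build_calibration_panel(
    normal_profiles,
    variance_threshold = config$panel$variance_threshold,
    autosomes_only = config$panel$autosomes_only
  )
  note("panel built: %d/%d member(s) retained", sum(panel$members$retained),
       nrow(panel$members))

  profiles <- list()
  for (id in live) {
    prof <- norm_one(samples[[id]], id)
    if (!attr(prof, "usable_profile")) {
      drop_sample(id, "normalize", "too few usable bins")
      next
    }
    profiles[[id]] <- dewave(prof, panel)
    note("sample %s dewaved", id)
  }

  if (length(profiles) > 1) {
    eb <- empty_bin_flag(profiles,
                         max_empty_fraction = config$qc$max_empty_fraction,
                         mode = config$qc$empty_mode,
                         relative_multiple = config$qc$relative_multiple)
    for (i in which(eb$flagged)) {
      drop_sample(eb$sample_id[i], "empty_bins",
                  sprintf("empty-bin fraction %.3g deviates from cohort",
                          eb$empty_fraction[i]))
      profiles[[eb$sample_id[i]]] <- NULL
    }
  }

  segs <- purrr::imap(profiles, function(p, id) {
    s <- segment_profile(p, alpha = config$segmentation$alpha,
                         n_permutations = config$segmentation$nperm,
                         undo_sd = config$segmentation$undo_sd,
                         min_width = config$segmentation$min_width,
                         seed = config$segmentation$seed)
    note("sample %s segmented into %d segment(s)", id, nrow(s$segments))
    s
  })
  calls <- call_cohort(segs, profiles,
                       cellularity = config$calling$cellularity,
                       relSDlong = config$calling$relSDlong,
                       long_threshold = config$calling$long_threshold,
                       five_states = config$calling$five_states,
                       exclude_sex = config$calling$exclude_sex,
                       male_x = config$calling$male_x)

  regions <- NULL
  clustering <- NULL
  if (length(calls) >= 2) {
    regions <- condense_calls(calls)
    clustering <- withCallingHandlers(
      cluster_samples(regions, linkage = config$clustering$linkage,
                      method = config$clustering$distance),
      warning = function(w) invokeRestart("muffleWarning")
    )
    note("clustered %d sample(s) over %d region(s)", length(calls),
         nrow(regions$regions))
  } else {
    note("fewer than 2 samples reached clustering; skipped")
  }

  result <- structure(
    list(profiles = profiles, panel = panel, segments = segs, calls = calls,
         regions = regions, clustering = clustering, quarantine = quarantine,
         config = config, log = log_lines, ok = length(calls) >= 2),
    class = "cnv_pipeline_result"
  )
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.cnv_pipeline_result <- function(x, ...) {
  cat(sprintf("<cnv_pipeline_result> %d profiled, %d quarantined, clustered: %s\n",
              length(x$profiles), nrow(x$quarantine),
              if (x$ok) "yes" else "no"))
  invisible(x)
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("profiles", "segments", "calls")) {
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)
  }
  for (id in names(result$profiles)) {
    write_profile_tsv(result$profiles[[id]],
                      file.path(out_dir, "profiles", paste0(id, ".tsv")))
    s <- result$segments[[id]]$segments
    utils::write.table(s, file.path(out_dir, "segments", paste0(id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cc <- result$calls[[id]]
    utils::write.table(as.data.frame(cc),
                       file.path(out_dir, "calls", paste0(id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(members = result$panel$members,
         variance_threshold = result$panel$variance_threshold),
    file.path(out_dir, "panel.json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(result$regions)) {
    utils::write.table(result$regions$regions,
                       file.path(out_dir, "regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(result$clustering$heatmap,
                       file.path(out_dir, "heatmap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(result$clustering$distance),
                       file.path(out_dir, "distance.tsv"),
                       sep = "\t", quote = FALSE, row.names = TRUE)
    if (requireNamespace("ape", quietly = TRUE)) {
      export_newick(result$clustering, file.path(out_dir, "dendrogram.nwk"))
    }
  }
  manifest <- list(
    config = unclass(result$config),
    quarantine = result$quarantine,
    samples = names(result$profiles),
    ok = result$ok
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(result$log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' Write a normalized profile as TSV plus JSON sidecar
#'
#' @param profile A `cnv_profile`.
#' @param path Output TSV path; the sidecar gets the same path with
#'   `.json` appended.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "cnv_profile"))
  utils::write.table(
    profile[, c("chrom", "start", "end", "usable", "count", "log2")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(
    list(sample_id = attr(profile, "sample_id"),
         total_mapped_reads = attr(profile, "total_mapped_reads"),
         sigma_delta = attr(profile, "sigma_delta"),
         empty_bin_count = attr(profile, "empty_bin_count"),
         corrections = attr(profile, "corrections")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a normalized profile written by [write_profile_tsv()]
#'
#' @param path TSV path (expects the `.json` sidecar next to it).
#' @param grid The `cnv_grid` the profile was computed on.
#' @return A `cnv_profile`.
#' @export
read_profile_tsv <- function(path, grid) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- as_tibble(grid)
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out$count <- as.integer(tab$count)
  out$log2 <- as.numeric(tab$log2)
  structure(out,
    class = c("cnv_profile", "tbl_df", "tbl", "data.frame"),
    sample_id = meta$sample_id,
    bin_size = attr(grid, "bin_size"),
    total_mapped_reads = meta$total_mapped_reads,
    sigma_delta = meta$sigma_delta,
    empty_bin_count = meta$empty_bin_count,
    usable_profile = TRUE,
    corrections = as.list(meta$corrections)
  )
}
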