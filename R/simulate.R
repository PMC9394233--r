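#' Toy bin grid for simulations and tests
#'
#' Four 50-Mb chromosomes of 500 bins at 100 kb, with a smooth synthetic
#' GC track (fraction 0.35-0.55). Small enough for fast tests while
#' keeping per-chromosome structure.
#'
#' @param n_chrom Number of chromosomes (default 4).
#' @param bins_per_chrom Bins per chromosome (default 500).
#' @param bin_size Bin width in bp (default 100 000).
#' @return An annotated `cnv_grid`.
#' @export
sim_grid <- function(n_chrom = 4, bins_per_chrom = 500, bin_size = 1e5) {
  lens <- setNames(rep(bins_per_chrom * bin_size, n_chrom),
                   paste0("chr", seq_len(n_chrom)))
  grid <- make_bin_grid(lens, bin_size)
  i <- seq_len(nrow(grid))
  chrom_idx <- match(grid$chrom, names(lens))
  grid$gc <- 0.45 + 0.08 * sin(2 * pi * (grid$start / lens[1]) * 3 + chrom_idx) *
    cos(2 * pi * i / nrow(grid))
  grid$mappability <- 1
  grid
}

#' Arm table for a simulated grid
#'
#' Splits each chromosome of a grid at its midpoint into p and q arms,
#' mirroring the chromosome-arm coordinate input used by the arm-level
#' QC.
#'
#' @param grid A `cnv_grid`.
#' @return Tibble with `chrom`, `start`, `end`, `arm`.
#' @export
sim_arms <- function(grid) {
  lens <- attr(grid, "chrom_lengths")
  short <- sub("^chr", "", names(lens))
  bind_rows(
    tibble(chrom = names(lens), start = 0, end = floor(unname(lens) / 2),
           arm = paste0(short, "p")),
    tibble(chrom = names(lens), start = floor(unname(lens) / 2),
           end = unname(lens), arm = paste0(short, "q"))
  ) %>%
    arrange(match(.data$chrom, names(lens)), .data$start)
}

#' Specify a single-cell sequencing simulation
#'
#' Bundles everything the generator needs: the grid, per-clone integral
#' copy numbers per bin, the cells (clone assignment and total reads),
#' and the artefact model — a GC-linked bias, a smooth "wave" bias shared
#' by all cells of the batch (sum of sinusoids with random phases, the
#' correlated low-frequency distortion that calibration-panel regression
#' removes), negative-binomial overdispersion of per-bin counts (WGA
#' noise), and random bin dropout. An optional `failed_wga` block
#' concentrates reads onto a few chromosome arms, emulating a failed
#' amplification.
#'
#' @param grid A `cnv_grid`.
#' @param clones Named list of integer copy-number vectors, one value per
#'   bin of the grid; e.g. `list(diploid = rep(2, nrow(grid)))`.
#' @param cells Tibble with `sample_id`, `clone`, `total_reads`.
#' @param gc_slope Linear GC bias slope on the log2 scale per unit GC
#'   (default 1; 0 disables).
#' @param wave_sd Standard deviation of the shared wave field on the
#'   log2 scale (default 0.35; 0 disables).
#' @param wave_components Number of sinusoids summed per chromosome
#'   (default 3).
#' @param wave_wavelength Fundamental wavelength in bins (default 160).
#' @param dispersion Negative-binomial size; smaller is noisier (default
#'   10, overdispersed WGA-like counts).
#' @param dropout Per-bin probability of dropping to zero (default 0.01).
#' @param failed_wga `NULL`, or `list(n_active_arms =, concentration =,
#'   background =)` for failed-WGA simulation.
#' @param seed RNG seed; identical spec + seed reproduces counts
#'   bit-for-bit.
#' @return A `sim_spec` list, validated.
#' @export
simulation_spec <- function(grid, clones, cells, gc_slope = 1,
                            wave_sd = 0.35, wave_components = 3,
                            wave_wavelength = 160, dispersion = 10,
                            dropout = 0.01, failed_wga = NULL, seed = 1) {
  stopifnot(inherits(grid, "cnv_grid"))
  if (!is.list(clones) || is.null(names(clones))) {
    abort("`clones` must be a named list of per-bin copy-number vectors")
  }
  for (nm in names(clones)) {
    cn <- clones[[nm]]
    if (length(cn) != nrow(grid)) {
      abort(sprintf("clone '%s' must have one copy number per bin", nm))
    }
    if (any(cn < 0) || any(cn != round(cn))) {
      abort(sprintf("clone '%s' has non-integral or negative copy numbers", nm))
    }
    if (all(cn == 0)) abort(sprintf("clone '%s' is all-zero", nm))
  }
  need <- c("sample_id", "clone", "total_reads")
  if (!is.data.frame(cells) || !all(need %in% names(cells))) {
    abort("`cells` needs columns sample_id, clone, total_reads")
  }
  if (!all(cells$clone %in% names(clones))) abort("unknown clone in `cells`")
  if (any(cells$total_reads <= 0)) abort("total_reads must be positive")
  structure(
    list(grid = grid, clones = clones, cells = as_tibble(cells),
         gc_slope = gc_slope, wave_sd = wave_sd,
         wave_components = wave_components, wave_wavelength = wave_wavelength,
         dispersion = dispersion, dropout = dropout,
         failed_wga = failed_wga, seed = seed),
    class = "sim_spec"
  )
}

# Smooth per-bin wave field (log2 scale), shared across the batch:
# per chromosome, a sum of sinusoids with random phases and harmonics of
# the fundamental wavelength, scaled to standard deviation `wave_sd`.
.wave_field <- function(grid, wave_sd, components, wavelength) {
  if (wave_sd <= 0) return(numeric(nrow(grid)))
  w <- numeric(nrow(grid))
  for (ch in unique(grid$chrom)) {
    idx <- which(grid$chrom == ch)
    t <- seq_along(idx)
    f <- numeric(length(idx))
    for (k in seq_len(components)) {
      f <- f + (1 / k) * sin(2 * pi * k * t / wavelength + runif(1, 0, 2 * pi))
    }
    w[idx] <- f
  }
  w * (wave_sd / stats::sd(w))
}

#' Simulate single-cell bin counts with exported truth
#'
#' The expected count of bin b in a cell of clone c is proportional to
#' `total_reads * (CN_cb / 2) * 2^(gc_slope * (gc_b - mean gc)) *
#' 2^(wave_b)`, normalized so expectations sum to the cell's total
#' reads. Counts are drawn negative-binomially with the requested
#' dispersion, then bins are zeroed with the dropout probability.
#'
#' @param spec A `sim_spec`.
#' @return List with `cells` (named list of `cnv_counts`) and `truth`
#'   (list: per-bin expected fields, per-clone copy numbers, cell
#'   table).
#' @export
simulate_cells <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  grid <- spec$grid
  gc <- grid$gc
  gc[is.na(gc)] <- mean(gc, na.rm = TRUE)
  gc_factor <- if (spec$gc_slope != 0) {
    2^(spec$gc_slope * (gc - mean(gc)))
  } else {
    rep(1, nrow(grid))
  }
  wave <- .wave_field(grid, spec$wave_sd, spec$wave_components,
                      spec$wave_wavelength)
  wave_factor <- 2^wave
  out <- vector("list", nrow(spec$cells))
  names(out) <- spec$cells$sample_id
  for (i in seq_len(nrow(spec$cells))) {
    cn <- spec$clones[[spec$cells$clone[i]]]
    mu <- (cn / 2) * gc_factor * wave_factor * grid$usable
    mu <- mu / sum(mu) * spec$cells$total_reads[i]
    counts <- rnbinom(length(mu), mu = mu, size = spec$dispersion)
    if (spec$dropout > 0) {
      counts[runif(length(mu)) < spec$dropout] <- 0L
    }
    out[[i]] <- assemble_bin_counts(
      grid, chrom = character(0), pos = numeric(0),
      sample_id = spec$cells$sample_id[i],
      filter_settings = list(source = "simulation")
    )
    out[[i]]$count <- as.integer(counts)
    attr(out[[i]], "total_mapped_reads") <- sum(counts)
  }
  list(
    cells = out,
    truth = list(
      cn = tibble(
        clone = rep(names(spec$clones), each = nrow(grid)),
        bin = rep(grid$bin, length(spec$clones)),
        cn = unlist(spec$clones, use.names = FALSE)
      ),
      cells = spec$cells,
      wave = wave,
      gc_factor = gc_factor
    )
  )
}

#' Simulate a failed whole-genome amplification
#'
#' Reads collapse onto `n_active_arms` randomly chosen arms: active arms
#' receive Dirichlet-distributed weights (gamma draws with shape
#' `concentration`, normalized), all arms share a small uniform
#' `background`, and bin expectations are scaled by their arm's weight
#' before negative-binomial noise. With every arm active and a large
#' concentration the draw degenerates to the uniform (successful-WGA)
#' case.
#'
#' @param spec A `sim_spec` whose `failed_wga` block is set.
#' @param arm_table Arm intervals for the grid (default:
#'   [sim_arms()] of the spec's grid).
#' @return Same shape as [simulate_cells()], plus `truth$arm_weights`;
#'   cells are labelled `status = "failed"` in `truth$cells`.
#' @export
simulate_failed_wga <- function(spec, arm_table = sim_arms(spec$grid)) {
  stopifnot(inherits(spec, "sim_spec"))
  fw <- spec$failed_wga
  if (is.null(fw)) abort("`spec$failed_wga` is not configured")
  n_active <- fw$n_active_arms
  if (is.null(n_active) || n_active < 1) abort("`n_active_arms` must be >= 1")
  concentration <- fw$concentration %||% 1
  background <- fw$background %||% 0.05
  set.seed(spec$seed)
  grid <- spec$grid
  arm_of_bin <- .assign_arms(grid, arm_table)
  arms <- unique(arm_table$arm)
  n_arms <- length(arms)
  n_active <- min(n_active, n_arms)

  out <- vector("list", nrow(spec$cells))
  names(out) <- spec$cells$sample_id
  weights_all <- matrix(NA_real_, n_arms, nrow(spec$cells),
                        dimnames = list(arms, spec$cells$sample_id))
  gc <- grid$gc
  gc[is.na(gc)] <- mean(gc, na.rm = TRUE)
  gc_factor <- if (spec$gc_slope != 0) 2^(spec$gc_slope * (gc - mean(gc))) else 1
  for (i in seq_len(nrow(spec$cells))) {
    active <- sample(arms, n_active)
    g <- rgamma(n_active, shape = concentration)
    w <- setNames(rep(0, n_arms), arms)
    w[active] <- g / sum(g)
    w <- (1 - background) * w + background / n_arms
    weights_all[, i] <- w
    cn <- spec$clones[[spec$cells$clone[i]]]
    mu <- (cn / 2) * gc_factor * unname(w[arm_of_bin]) * grid$usable
    mu <- mu / sum(mu) * spec$cells$total_reads[i]
    counts <- rnbinom(length(mu), mu = mu, size = spec$dispersion)
    if (spec$dropout > 0) counts[runif(length(mu)) < spec$dropout] <- 0L
    out[[i]] <- assemble_bin_counts(
      grid, chrom = character(0), pos = numeric(0),
      sample_id = spec$cells$sample_id[i],
      filter_settings = list(source = "simulation_failed_wga")
    )
    out[[i]]$count <- as.integer(counts)
    attr(out[[i]], "total_mapped_reads") <- sum(counts)
  }
  truth_cells <- spec$cells
  truth_cells$status <- "failed"
  list(cells = out,
       truth = list(cells = truth_cells, arm_weights = weights_all))
}

# arm label of each bin, keyed by the bin's start position; every bin
# must fall in exactly one arm interval
.assign_arms <- function(grid, arm_table) {
  .check_intervals(arm_table, "arm_table")
  arm <- rep(NA_character_, nrow(grid))
  for (k in seq_len(nrow(arm_table))) {
    hit <- grid$chrom == arm_table$chrom[k] &
      grid$start >= arm_table$start[k] & grid$start < arm_table$end[k]
    arm[hit] <- arm_table$arm[k]
  }
  if (anyNA(arm)) abort("arm intervals do not cover every bin of the grid")
  arm
}

#' Aggregate bin counts to chromosome arms
#'
#' Sums each cell's bin counts within arm intervals, producing the
#' per-arm count table consumed by [arm_ratios()].
#'
#' @param cells Named list of `cnv_counts` (e.g. from
#'   [simulate_cells()]).
#' @param arm_table Arm intervals covering the grid.
#' @return Tibble with `sample_id`, `arm`, `count`.
#' @export
simulate_arm_counts <- function(cells, arm_table) {
  if (length(cells) == 0) abort("no cells supplied")
  grid_arm <- .assign_arms(cells[[1]], arm_table)
  rows <- lapply(cells, function(cc) {
    tibble(sample_id = attr(cc, "sample_id"), arm = grid_arm,
           count = cc$count) %>%
      group_by(.data$sample_id, .data$arm) %>%
      summarise(count = sum(.data$count), .groups = "drop")
  })
  bind_rows(rows) %>%
    mutate(arm = factor(.data$arm, levels = unique(arm_table$arm))) %>%
    arrange(.data$sample_id, .data$arm) %>%
    mutate(arm = as.character(.data$arm))
}

#' Convenience clone constructors for simulations
#'
#' `clone_flat()` is copy-number neutral everywhere; `clone_events()`
#' applies whole- or part-chromosome copy-number events on top of the
#' diploid baseline.
#'
#' @param grid A `cnv_grid`.
#' @param events Tibble with `chrom`, `cn` and optional `from`, `to`
#'   (bin offsets within the chromosome, 1-based inclusive; defaults to
#'   the whole chromosome).
#' @return Integer vector of per-bin copy numbers.
#' @export
clone_flat <- function(grid) rep(2L, nrow(grid))

#' @rdname clone_flat
#' @export
clone_events <- function(grid, events) {
  cn <- clone_flat(grid)
  for (k in seq_len(nrow(events))) {
    idx <- which(grid$chrom == events$chrom[k])
    if (length(idx) == 0) abort(sprintf("chromosome '%s' not in grid", events$chrom[k]))
    from <- if ("from" %in% names(events) && !is.na(events$from[k])) events$from[k] else 1
    to <- if ("to" %in% names(events) && !is.na(events$to[k])) events$to[k] else length(idx)
    cn[idx[from:to]] <- as.integer(events$cn[k])
  }
  cn
}
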