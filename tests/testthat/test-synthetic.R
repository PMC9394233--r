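toy_spec <- function(grid, n_cells = 2, reads = 1e5, seed = 1, ...) {
  simulation_spec(
    grid, clones = list(flat = clone_flat(grid)),
    cells = tibble::tibble(sample_id = sprintf("c%02d", seq_len(n_cells)),
                           clone = "flat", total_reads = reads),
    seed = seed, ...
  )
}

test_that("the spec validates its inputs", {
  g <- sim_grid(1, 50)
  expect_error(simulation_spec(g, list(bad = rep(2L, 10)),
                               tibble::tibble(sample_id = "a", clone = "bad",
                                              total_reads = 1e4)),
               "per bin")
  expect_error(simulation_spec(g, list(z = rep(0L, 50)),
                               tibble::tibble(sample_id = "a", clone = "z",
                                              total_reads = 1e4)),
               "all-zero")
  expect_error(simulation_spec(g, list(f = rep(2.5, 50)),
                               tibble::tibble(sample_id = "a", clone = "f",
                                              total_reads = 1e4)),
               "non-integral")
  expect_error(simulate_failed_wga(toy_spec(g)), "not configured")
})

test_that("identical spec and seed reproduce counts bit-for-bit", {
  g <- sim_grid(2, 100)
  a <- simulate_cells(toy_spec(g, seed = 33))
  b <- simulate_cells(toy_spec(g, seed = 33))
  expect_identical(lapply(a$cells, `[[`, "count"), lapply(b$cells, `[[`, "count"))
  c3 <- simulate_cells(toy_spec(g, seed = 34))
  expect_false(identical(a$cells[[1]]$count, c3$cells[[1]]$count))

  fw <- toy_spec(g, seed = 35,
                 failed_wga = list(n_active_arms = 2, concentration = 1))
  expect_identical(simulate_failed_wga(fw)$cells[[1]]$count,
                   simulate_failed_wga(fw)$cells[[1]]$count)
})

test_that("near-Poisson flat cells have the expected small coefficient of variation", {
  g <- sim_grid(2, 500)  # 1000 bins
  spec <- toy_spec(g, n_cells = 1, reads = 1e5, seed = 36,
                   gc_slope = 0, wave_sd = 0, dispersion = 1e9, dropout = 0)
  cnt <- simulate_cells(spec)$cells[[1]]$count
  # mu = 100 per bin; Poisson CV = 10%, so the *mean* is what must be tight:
  expect_lt(abs(mean(cnt) - 100) / 100, 0.02)
  expect_lt(abs(sd(cnt) / mean(cnt) - 0.1), 0.02)  # no overdispersion left
})

test_that("per-bin means over replicate cells match the specified expectation", {
  g <- sim_grid(1, 500)
  spec <- simulation_spec(
    g, clones = list(t = clone_events(g, tibble::tibble(chrom = "chr1", cn = 3L,
                                                        from = 1, to = 100))),
    cells = tibble::tibble(sample_id = sprintf("r%03d", 1:500), clone = "t",
                           total_reads = 1e6),
    gc_slope = 0.5, wave_sd = 0.3, dispersion = 100, dropout = 0, seed = 37
  )
  sim <- simulate_cells(spec)
  cn <- spec$clones$t
  expected <- (cn / 2) * sim$truth$gc_factor * 2^sim$truth$wave
  expected <- expected / sum(expected) * 1e6
  acc <- Reduce(`+`, lapply(sim$cells, `[[`, "count")) / 500
  expect_lt(max(abs(acc - expected) / expected), 0.03)
})

test_that("failed WGA concentrates reads on the active arms", {
  g <- sim_grid(4, 200)
  arms <- sim_arms(g)
  spec <- toy_spec(g, n_cells = 10, reads = 2e5, seed = 38,
                   failed_wga = list(n_active_arms = 3, concentration = 1,
                                     background = 0.05))
  sim <- simulate_failed_wga(spec)
  ac <- simulate_arm_counts(sim$cells, arms)
  shares <- ac %>%
    dplyr::group_by(sample_id) %>%
    dplyr::summarise(top3 = sum(sort(count, decreasing = TRUE)[1:3]) / sum(count))
  expect_true(all(shares$top3 >= 0.8))
  # exported weights match: >= 95% - background on the three active arms
  w <- sim$truth$arm_weights
  expect_true(all(colSums(apply(w, 2, sort, decreasing = TRUE)[1:3, ]) > 0.9))
})

test_that("all-arms failed mode with high concentration is indistinguishable from uniform", {
  g <- sim_grid(4, 200)
  arms <- sim_arms(g)
  n_arms <- nrow(arms)
  spec_f <- toy_spec(g, n_cells = 1, reads = 5e5, seed = 39, dispersion = 50,
                     failed_wga = list(n_active_arms = n_arms,
                                       concentration = 1e6, background = 0))
  spec_u <- toy_spec(g, n_cells = 1, reads = 5e5, seed = 40, dispersion = 50)
  f_frac <- simulate_arm_counts(simulate_failed_wga(spec_f)$cells, arms)$count
  u_frac <- simulate_arm_counts(simulate_cells(spec_u)$cells, arms)$count
  ks <- suppressWarnings(ks.test(f_frac / sum(f_frac), u_frac / sum(u_frac)))
  expect_gt(ks$p.value, 0.01)
})

test_that("arm aggregation conserves totals and matches a brute-force sum", {
  g <- sim_grid(3, 120)
  set.seed(41)
  # random arm partition: split each chromosome at a random bin boundary
  lens <- attr(g, "chrom_lengths")
  arm_table <- dplyr::bind_rows(lapply(names(lens), function(ch) {
    cut <- sample(2:118, 1) * 1e5
    tibble::tibble(chrom = ch, start = c(0, cut), end = c(cut, unname(lens[ch])),
                   arm = paste0(sub("chr", "", ch), c("p", "q")))
  }))
  cells <- simulate_cells(toy_spec(g, n_cells = 3, reads = 5e4, seed = 42))$cells
  ac <- simulate_arm_counts(cells, arm_table)
  for (id in names(cells)) {
    expect_equal(sum(ac$count[ac$sample_id == id]), sum(cells[[id]]$count))
    # brute force: per-bin loop
    oracle <- sapply(arm_table$arm, function(a) {
      rows <- arm_table[arm_table$arm == a, ]
      sum(cells[[id]]$count[cells[[id]]$chrom == rows$chrom &
                              cells[[id]]$start >= rows$start &
                              cells[[id]]$start < rows$end])
    })
    got <- ac$count[ac$sample_id == id][match(arm_table$arm,
                                              ac$arm[ac$sample_id == id])]
    expect_equal(unname(got), unname(oracle))
  }

  bad_arms <- arm_table[-1, ]  # first chromosome's p arm missing
  expect_error(simulate_arm_counts(cells, bad_arms), "cover")
})

test_that("leukocyte-like simulated cells call almost entirely neutral after dewaving", {
  g <- sim_grid(2, 400)
  spec <- simulation_spec(
    g, clones = list(flat = clone_flat(g)),
    cells = tibble::tibble(sample_id = sprintf("L%02d", 1:8), clone = "flat",
                           total_reads = 1e6),
    gc_slope = 1, wave_sd = 0.3, dispersion = 60, dropout = 0.005, seed = 44
  )
  sim <- simulate_cells(spec)
  profs <- suppressWarnings(lapply(sim$cells, normalize_profile))
  panel <- suppressWarnings(build_calibration_panel(profs[1:6]))
  for (i in 7:8) {
    p <- dewave(profs[[i]], panel)
    seg <- segment_profile(p, n_permutations = 300, seed = 1)
    calls <- call_profile(seg, p)
    expect_lt(mean(calls$call != 0), 0.01)
  }
})
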