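test_that("condensing collapses all-constant chromosomes to single regions", {
  g <- sim_grid(2, 50)
  p1 <- calls_from_vector(g, rep(0L, 100), "a")
  p2 <- calls_from_vector(g, rep(0L, 100), "b")
  reg <- condense_calls(list(p1, p2))
  expect_equal(nrow(reg$regions), 2)  # one region per chromosome
  expect_equal(reg$regions$n_bins, c(50, 50))
})

test_that("a single sample's call switch places the region boundary exactly", {
  g <- sim_grid(1, 60)
  k <- 25
  p1 <- calls_from_vector(g, c(rep(0L, k - 1), rep(1L, 60 - k + 1)), "a")
  p2 <- calls_from_vector(g, rep(0L, 60), "b")
  reg <- condense_calls(list(p1, p2))
  expect_equal(nrow(reg$regions), 2)
  expect_equal(reg$regions$first_bin, c(1, k))
})

test_that("condensing matches a brute-force run-length oracle on random matrices", {
  g <- sim_grid(1, 300)
  set.seed(12)
  for (rep in 1:3) {
    # random piecewise structure per sample
    mat <- vapply(1:5, function(j) {
      br <- sort(sample(2:299, 8))
      rep(sample(c(-1L, 0L, 1L, 2L), 9, replace = TRUE),
          diff(c(1, br, 301)))
    }, integer(300))
    profs <- lapply(1:5, function(j) calls_from_vector(g, mat[, j], paste0("s", j)))
    reg <- condense_calls(profs)

    # oracle: scan bins, new region whenever any sample changes
    boundaries <- 1
    for (b in 2:300) {
      if (any(mat[b, ] != mat[b - 1, ])) boundaries <- c(boundaries, b)
    }
    expect_equal(reg$regions$first_bin, boundaries)
    expect_equal(sum(reg$regions$n_bins), 300)

    # expanding regions reproduces the call matrix exactly
    back <- expand_regions(reg)
    for (j in 1:5) expect_equal(back[[paste0("s", j)]], mat[, j])
  }
})

test_that("the concordance distance is a bounded semimetric with a manual oracle", {
  g <- sim_grid(1, 40)
  p <- list(
    calls_from_vector(g, rep(0L, 40), "a"),
    calls_from_vector(g, rep(0L, 40), "b"),
    calls_from_vector(g, c(rep(1L, 20), rep(0L, 20)), "c"),
    calls_from_vector(g, rep(-1L, 40), "d")
  )
  reg <- condense_calls(p)
  d <- region_distance(reg)
  expect_equal(d["a", "b"], 0)
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  # manual weighted concordance: regions are (1..20) and (21..40)
  expect_equal(d["a", "c"], 1 - (20 * 0 + 20 * 1) / 40)
  expect_equal(d["a", "d"], 1)
  expect_equal(d["c", "d"], 1)
  # hard distance agrees with certainty-1 posteriors
  expect_equal(region_distance(reg, "hard"), d)
})

test_that("identical samples merge first and the 4-sample dendrogram matches manual agglomeration", {
  g <- sim_grid(1, 40)
  p <- list(
    calls_from_vector(g, rep(0L, 40), "a"),
    calls_from_vector(g, rep(0L, 40), "b"),
    calls_from_vector(g, c(rep(1L, 20), rep(0L, 20)), "c"),
    calls_from_vector(g, rep(-1L, 40), "d")
  )
  cl <- cluster_samples(condense_calls(p))
  expect_equal(cl$tree$height[1], 0)
  first_pair <- sort(rownames(cl$distance)[-cl$tree$merge[1, ]])
  expect_equal(first_pair, c("a", "b"))
  # average linkage by hand: {a,b} at 0; c joins {a,b} at 0.5; d at 1
  expect_equal(cl$tree$height, c(0, 0.5, 1))
})

test_that("regions and distances are equivariant under sample reordering", {
  g <- sim_grid(1, 100)
  set.seed(14)
  mats <- lapply(1:4, function(j) {
    br <- sort(sample(2:99, 4))
    rep(sample(c(-1L, 0L, 1L), 5, replace = TRUE), diff(c(1, br, 101)))
  })
  profs <- lapply(1:4, function(j) calls_from_vector(g, mats[[j]], paste0("s", j)))
  reg1 <- condense_calls(profs)
  perm <- c(3, 1, 4, 2)
  reg2 <- condense_calls(profs[perm])
  expect_equal(nrow(reg1$regions), nrow(reg2$regions))
  d1 <- region_distance(reg1)
  d2 <- region_distance(reg2)
  expect_equal(d2, d1[perm, perm])
})

test_that("clustering separates patients and groups flat cells together", {
  g <- sim_grid(2, 100)
  set.seed(15)
  clone1 <- c(rep(1L, 100), rep(0L, 100))
  clone2 <- c(rep(0L, 100), rep(2L, 100))
  clone3 <- c(rep(-1L, 50), rep(0L, 150))
  flat <- rep(0L, 200)
  noisy <- function(base, id) {
    v <- base
    flip <- sample(200, 3)
    v[flip] <- pmin(pmax(v[flip] + sample(c(-1L, 1L), 3, TRUE), -1L), 2L)
    calls_from_vector(g, v, id)
  }
  profs <- c(
    lapply(1:3, function(i) noisy(clone1, paste0("p1_", i))),
    lapply(1:3, function(i) noisy(clone2, paste0("p2_", i))),
    lapply(1:3, function(i) noisy(clone3, paste0("p3_", i))),
    lapply(1:3, function(i) noisy(flat, paste0("wbc_", i)))
  )
  cl <- cluster_samples(condense_calls(profs))
  groups <- cutree(cl$tree, k = 4)
  labels <- sub("_[0-9]+$", "", names(groups))
  # every clone maps to exactly one cluster and clusters do not mix clones
  tab <- table(labels, groups)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("region queries aggregate calls with the any-amplification-then-majority rule", {
  g <- sim_grid(1, 30)
  p_neutral <- calls_from_vector(g, rep(0L, 30), "n")
  p_mixed <- calls_from_vector(g, c(rep(1L, 2), rep(0L, 28)), "m")
  p_amp <- calls_from_vector(g, c(0L, 2L, rep(0L, 28)), "amp")

  # interval covering bins 1..3 (0-based 0..300 kb)
  res <- query_region(list(p_neutral, p_mixed, p_amp), g,
                      list(chrom = "chr1", start = 0, end = 3e5))
  expect_equal(res$call, c(0L, 1L, 2L))   # majority {g,g,n} -> gain; any amp -> amp
  expect_equal(res$n_bins, rep(3L, 3))

  # tie {gain, loss} resolves to the higher state
  p_tie <- calls_from_vector(g, c(1L, -1L, rep(0L, 28)), "t")
  res_tie <- query_region(list(p_tie), g, list(chrom = "chr1", start = 0, end = 2e5))
  expect_equal(res_tie$call, 1L)

  # browser-style string interval
  res_str <- query_region(list(p_amp), g, "chr1:1-300000")
  expect_equal(res_str$call, 2L)

  # no usable called bins -> explicit no-resolution verdict
  p_na <- calls_from_vector(g, rep(0L, 30), "na")
  p_na$call[1:3] <- NA
  res_na <- query_region(list(p_na), g, list(chrom = "chr1", start = 0, end = 3e5))
  expect_equal(res_na$verdict, "no_resolution")

  expect_error(query_region(list(p_neutral), g,
                            list(chrom = "chr9", start = 0, end = 1e5)),
               "overlaps no bin")
})

test_that("newick export writes a tree on the sample ids", {
  skip_if_not_installed("ape")
  g <- sim_grid(1, 20)
  p <- lapply(1:3, function(i) {
    calls_from_vector(g, rep(c(-1L, 0L, 1L)[i], 20), paste0("s", i))
  })
  cl <- cluster_samples(condense_calls(p))
  path <- withr::local_tempfile(fileext = ".nwk")
  export_newick(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, c("s1", "s2", "s3"))
})
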