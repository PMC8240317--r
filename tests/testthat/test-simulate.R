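test_that("generation is deterministic and streams are independent", {
  a <- simulate_dataset(n = 15, m = 12, seed = 5)
  b <- simulate_dataset(n = 15, m = 12, seed = 5)
  expect_identical(a$Y_observed, b$Y_observed)
  expect_identical(a$truth_mask, b$truth_mask)
  expect_identical(a$newick, b$newick)

  # tree round-trip: emitted newick reproduces the distance matrix
  tr <- gen_tree_and_distances(7, seed = 3)
  D2 <- phylo_distances(tree = tr$newick, taxon_ids = rownames(tr$D))
  expect_equal(D2, tr$D)
  expect_identical(gen_tree_and_distances(7, seed = 3)$D, tr$D)
})

test_that("scheme gates control which signal sources are active", {
  cfg <- function(s) simulate_config(n = 200, m = 20, q = 2, scheme = s,
                                     seed = 9)
  co <- gen_complete(cfg("covariates"))
  expect_true(all(co$params$effects$sample == 0))
  expect_true(all(co$params$effects$taxon == 0))
  expect_false(all(co$params$effects$covariate == 0))

  sa <- gen_complete(cfg("samples"))
  expect_true(all(sa$params$effects$covariate == 0))
  expect_true(all(sa$params$effects$taxon == 0))
  # the sample effect is shared across taxa within a row
  expect_equal(max(apply(sa$params$effects$sample, 1, sd)), 0)

  ta <- gen_complete(cfg("taxa"))
  expect_true(all(ta$params$effects$sample == 0))
  expect_true(all(ta$params$effects$covariate == 0))
  # Y decomposes exactly into baseline + gated effects + noise (above floor)
  p <- ta$params
  recon <- rep(p$mu, each = 200) + p$effects$taxon + p$noise
  expect_equal(ta$Y_complete, pmax(recon, log10(1.01)), ignore_attr = TRUE)

  # same-tree-block taxa are more correlated than cross-block taxa
  blocks <- p$blocks
  same <- which(blocks == blocks[1])
  other <- which(blocks != blocks[1])
  r_same <- cor(ta$Y_complete[, same[1]], ta$Y_complete[, same[2]])
  r_diff <- cor(ta$Y_complete[, same[1]], ta$Y_complete[, other[1]])
  expect_gt(r_same, r_diff)
})

test_that("injected missingness matches its per-taxon target rates", {
  sim <- simulate_dataset(n = 500, m = 30, seed = 21, scheme = "covariates")
  frac <- colMeans(sim$truth_mask)
  p <- sim$p_missing
  binom_sd <- sqrt(p * (1 - p) / 500)
  expect_true(all(abs(frac - p) <= 3 * binom_sd))
  # observed differs from complete exactly on the mask
  expect_true(all((sim$Y_observed != sim$Y_complete) == sim$truth_mask))
  # injected values are low: below the 5th percentile of the taxon's
  # complete values
  for (j in which(colSums(sim$truth_mask) > 0)[1:10]) {
    inj <- sim$Y_observed[sim$truth_mask[, j], j]
    expect_true(all(inj < quantile(sim$Y_complete[, j], 0.05)))
  }
})

test_that("hard-zero mode writes exact zero counts", {
  sim <- simulate_dataset(n = 30, m = 10, seed = 2, hard_zero = TRUE)
  expect_true(all(sim$Y_observed[sim$truth_mask] == log10(1.01)))
  expect_true(all(sim$counts[sim$truth_mask] == 0))
})

test_that("proportional downsampling keeps high counts preferentially", {
  M <- matrix(c(10, 90, 50, 50), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  # keep_fraction = 1 is the identity
  ds1 <- downsample(M, 1, seed = 1)
  expect_identical(ds1$counts, M)
  expect_false(any(ds1$truth_mask))

  kept90 <- 0
  for (s in 1:1000) {
    ds <- downsample(M, 0.5, seed = s)
    # one of the two nonzero entries of row 1 survives
    expect_equal(sum(ds$counts[1, ] > 0), 1)
    expect_equal(sum(ds$truth_mask[1, ]), 1)
    if (ds$counts[1, "b"] > 0) kept90 <- kept90 + 1
  }
  expect_gte(kept90 / 1000, 0.85)
})

test_that("downsampling at 40% and 70% removal hits the advertised rates", {
  sim <- simulate_dataset(n = 20, m = 50, seed = 31)
  for (keep in c(0.6, 0.3)) {
    ds <- downsample(sim$counts_complete, keep, seed = 2)
    nz <- rowSums(sim$counts_complete > 0)
    removed <- rowSums(ds$truth_mask)
    expect_equal(removed, nz - ceiling(keep * nz), ignore_attr = TRUE)
  }
})

test_that("outlier samples are appended with the advertised structure", {
  sim <- simulate_dataset(n = 20, m = 15, seed = 4)
  expect_identical(gen_outlier_samples(sim, 0, 5), sim)  # no-op
  out <- gen_outlier_samples(sim, 2, 5, seed = 8)
  expect_equal(nrow(out$Y_observed), 22)
  expect_equal(out$outlier_samples, c("outlier1", "outlier2"))
  for (id in out$outlier_samples) {
    expect_equal(sum(out$Y_observed[id, ] > log10(1.01)), 5)
  }
  expect_false(any(out$truth_mask[out$outlier_samples, ]))
  expect_equal(nrow(out$covariates), 22)
})
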