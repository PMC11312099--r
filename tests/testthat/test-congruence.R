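random_rotation <- function(k) {
  qr_ <- qr(matrix(rnorm(k * k), k, k))
  Q <- qr.Q(qr_)
  Q
}

test_that("t0 = 1 exactly for rigid transforms of a configuration", {
  set.seed(61)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    k <- sample(2:3, 1)
    X <- matrix(rnorm(n * k), n, k)
    R <- random_rotation(k)
    Y <- 2.7 * X %*% R + matrix(rnorm(k), n, k, byrow = TRUE)
    fit <- procrustes_t0(X, Y)
    expect_equal(fit$t0, 1, tolerance = 1e-10)
    expect_equal(fit$m2, 0, tolerance = 1e-10)
    expect_equal(fit$t0, sqrt(1 - fit$m2), tolerance = 1e-10)
  }
})

test_that("t0 from the SVD matches the 2D rotation-grid oracle", {
  set.seed(67)
  for (rep in 1:10) {
    X <- matrix(rnorm(10), 5, 2)
    Y <- X
    Y[1, ] <- Y[1, ] + rnorm(2, sd = 0.5)
    fit <- procrustes_t0(X, Y)
    expect_equal(fit$t0, procrustes_grid_oracle(X, Y), tolerance = 1e-6)
  }
})

test_that("t0 agrees with vegan's symmetric Procrustes", {
  set.seed(71)
  X <- matrix(rnorm(16), 8, 2)
  Y <- matrix(rnorm(16), 8, 2)
  fit <- procrustes_t0(X, Y)
  vfit <- vegan::procrustes(X, Y, symmetric = TRUE)
  expect_equal(fit$m2, vfit$ss, tolerance = 1e-10)
  expect_equal(fit$t0, sqrt(1 - vfit$ss), tolerance = 1e-10)
})

test_that("t0 is symmetric and invariant under rigid transforms of either side", {
  set.seed(73)
  X <- matrix(rnorm(20), 10, 2)
  Y <- matrix(rnorm(20), 10, 2)
  t_xy <- procrustes_t0(X, Y)$t0
  expect_equal(procrustes_t0(Y, X)$t0, t_xy, tolerance = 1e-10)
  R <- random_rotation(2)
  expect_equal(procrustes_t0(X %*% R * 3 + 1, Y)$t0, t_xy, tolerance = 1e-10)
  expect_equal(procrustes_t0(X, Y %*% R / 5 - 2)$t0, t_xy, tolerance = 1e-10)
})

test_that("orthonormal column permutation gives t0 = 1 and padding works", {
  Q <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
  expect_equal(procrustes_t0(Q, Q[, 2:1])$t0, 1, tolerance = 1e-10)
  # narrower configuration is padded with zero columns
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(procrustes_t0(X, X[, 1:2, drop = FALSE])$t0,
               procrustes_t0(X, cbind(X[, 1:2], 0))$t0, tolerance = 1e-12)
})

test_that("procrustes input contracts are enforced", {
  X <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("s", 1:5), NULL))
  Y <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("t", 1:5), NULL))
  expect_error(procrustes_t0(X, Y), "different sample")
  expect_error(procrustes_t0(X[1:2, ], X[1:2, ]), "at least 3")
  expect_error(protest(X, X, n_permutations = 0), ">= 1")
})

test_that("protest is deterministic given a seed and minimal for t0 = 1", {
  set.seed(79)
  X <- matrix(rnorm(20), 10, 2)
  Y <- X %*% random_rotation(2) * 0.4 + 5
  fit <- protest(X, Y, n_permutations = 99, seed = 3)
  expect_equal(fit$p_value, 1 / 100)
  fit2 <- protest(X, Y, n_permutations = 99, seed = 3)
  expect_equal(fit, fit2)
})

test_that("protest p agrees in magnitude with vegan's PROTEST", {
  set.seed(83)
  sc <- simulate_scenario(scenario_config(n_taxa = 16, n_samples = 12,
                                          n_phyla = 3, seed = 12))
  xa <- pcoa(weighted_unifrac(sc$table_a, sc$tree))$vectors
  xb <- pcoa(weighted_unifrac(sc$table_b, sc$tree))$vectors
  ours <- protest(xa, xb, n_permutations = 999, seed = 4)
  vg <- vegan::protest(xa, xb, permutations = 999)
  expect_equal(ours$t0, vg$t0, tolerance = 1e-10)
  # both p estimates target the same permutation null
  expect_lt(abs(ours$p_value - vg$signif), 0.05)
})

test_that("leave-one-out recovers a zero delta_t for an absent group", {
  sc <- simulate_scenario(scenario_config(n_taxa = 12, n_samples = 8,
                                          n_phyla = 3, seed = 31))
  # add a taxon that exists in the taxonomy and tree scope but with zero
  # abundance everywhere: its group's removal must leave t0 unchanged
  tax <- sc$taxonomy
  tax$phylum[tax$taxon_id == "taxon_012"] <- "GhostPhylum"
  zero_a <- sc$table_a
  zero_a[zero_a$taxon_id == "taxon_012", -1] <- 0
  zero_b <- sc$table_b
  zero_b[zero_b$taxon_id == "taxon_012", -1] <- 0
  loo <- suppressWarnings(
    leave_one_out_delta_t(zero_a, zero_b, sc$tree, tax, rank = "phylum"))
  ghost <- loo[loo$group == "GhostPhylum", ]
  expect_false(ghost$skipped)
  expect_equal(ghost$delta_t, 0, tolerance = 1e-12)
  expect_equal(loo$delta_t, loo$t0_prime - attr(loo, "t0_baseline"),
               tolerance = 1e-12)
})

test_that("leave-one-out skips groups whose removal empties samples", {
  sc <- simulate_scenario(scenario_config(n_taxa = 8, n_samples = 6,
                                          n_phyla = 1, seed = 33))
  expect_warning(
    loo <- leave_one_out_delta_t(sc$table_a, sc$table_b, sc$tree, sc$taxonomy),
    "empties")
  expect_equal(nrow(loo), 1)
  expect_true(loo$skipped)
  expect_true(is.na(loo$delta_t))
})

test_that("leave-one-out flags mismatched sample structure", {
  sc <- simulate_scenario(scenario_config(n_taxa = 8, n_samples = 6,
                                          n_phyla = 2, seed = 35))
  short_b <- sc$table_b[, 1:5]
  expect_error(leave_one_out_delta_t(sc$table_a, short_b, sc$tree, sc$taxonomy),
               "same number of samples")
})

test_that("one-sided removal leaves community B untouched", {
  sc <- simulate_scenario(scenario_config(n_taxa = 12, n_samples = 8,
                                          n_phyla = 3, seed = 37))
  loo_one <- suppressWarnings(
    leave_one_out_delta_t(sc$table_a, sc$table_b, sc$tree, sc$taxonomy,
                          side = "one"))
  loo_both <- suppressWarnings(
    leave_one_out_delta_t(sc$table_a, sc$table_b, sc$tree, sc$taxonomy))
  expect_equal(attr(loo_one, "t0_baseline"), attr(loo_both, "t0_baseline"))
  expect_false(isTRUE(all.equal(loo_one$t0_prime, loo_both$t0_prime)))
})
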