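test_that("signature distances vanish on orbits and separate off them", {
  G <- cyclic_permutation_group(6)
  bank <- orbit_bank(G, unit_vec(6, seed = 1))
  x <- sample_base_points(1, 6, seed = 2)[, 1]

  grids <- list(random_threshold_grid(10, c(-1, 1), seed = 3),
                full_threshold_grid(bank, matrix(x)),
                threshold_grid(c(-0.3, 0, 0.4)))
  for (g in G$elements) {
    gx <- as.numeric(g %*% x)
    for (grid in grids) {
      expect_identical(signature_distance(x, gx, bank, grid, "l1"), 0)
      expect_identical(signature_distance(x, gx, bank, grid, "l2"), 0)
    }
  }
  expect_identical(signature_distance(x, x, bank, grids[[1]]), 0)

  # cross-orbit pairs separate at full grid resolution
  y <- sample_base_points(1, 6, seed = 4)[, 1]
  gxy <- full_threshold_grid(bank, cbind(x, y))
  expect_gt(signature_distance(x, y, bank, gxy), 0)
  # the collapsed scalar variant is available
  expect_gte(signature_distance(x, y, bank, gxy, collapsed = TRUE), 0)
})

test_that("the full threshold grid is the midpoint construction", {
  bank <- simple_cell_bank(matrix(c(1, 2, 3), 1, 3), heaviside(0))
  g <- full_threshold_grid(bank, matrix(1))
  expect_equal(g$thresholds, c(0.5, 1.5, 2.5, 3.5))

  # all responses equal: two flanking thresholds
  bank1 <- simple_cell_bank(matrix(c(1, 1), 1, 2), heaviside(0))
  g1 <- full_threshold_grid(bank1, matrix(2))
  expect_equal(length(g1$thresholds), 2L)
  expect_true(g1$thresholds[1] < 2 && g1$thresholds[2] > 2)
})

test_that("full-grid distance is zero iff sorted responses coincide", {
  G <- cyclic_permutation_group(6)
  bank <- orbit_bank(G, unit_vec(6, seed = 5))
  n_same <- 0
  for (s in 1:500) {
    x <- sample_base_points(1, 6, seed = 6000 + s)[, 1]
    y <- if (s %% 2 == 0) {
      gi <- (s %% 6) + 1
      as.numeric(G$elements[[gi]] %*% x) # same orbit
    } else {
      sample_base_points(1, 6, seed = 9000 + s)[, 1]
    }
    grid <- full_threshold_grid(bank, cbind(x, y))
    dist0 <- signature_distance(x, y, bank, grid) == 0
    # sorting oracle on the raw response multisets
    rx <- sort(as.numeric(crossprod(bank$W, x)))
    ry <- sort(as.numeric(crossprod(bank$W, y)))
    same_multiset <- max(abs(rx - ry)) <= 1e-9
    expect_identical(dist0, same_multiset)
    n_same <- n_same + same_multiset
  }
  expect_gt(n_same, 0) # both branches exercised
})

test_that("l2 signature distances satisfy the metric axioms", {
  G <- dihedral_permutation_group(4)
  bank <- orbit_bank(G, unit_vec(4, seed = 7))
  grid <- random_threshold_grid(12, c(-1, 1), seed = 8)
  for (s in 1:25) {
    x <- sample_base_points(1, 4, seed = 300 + s)[, 1]
    y <- sample_base_points(1, 4, seed = 400 + s)[, 1]
    z <- sample_base_points(1, 4, seed = 500 + s)[, 1]
    dxy <- signature_distance(x, y, bank, grid, "l2")
    dyx <- signature_distance(y, x, bank, grid, "l2")
    expect_gte(dxy, 0)
    expect_identical(dxy, dyx)
    expect_lte(signature_distance(x, z, bank, grid, "l2"),
               dxy + signature_distance(y, z, bank, grid, "l2") + 1e-12)
  }
})

test_that("distance reports separate intra from inter at full grid", {
  G <- cyclic_permutation_group(6)
  ds <- make_orbit_dataset(G, 20, seed = 9)
  bank <- orbit_bank(G, unit_vec(6, seed = 10))

  rep <- distance_report(ds, bank, grid = "full", n_pairs = 100, seed = 11)
  expect_true(all(rep$intra == 0))
  expect_true(all(rep$inter > 0))
  expect_identical(overlap_fraction(rep), 0)

  # deterministic given the seed
  rep2 <- distance_report(ds, bank, grid = "full", n_pairs = 100, seed = 11)
  expect_identical(rep$inter, rep2$inter)

  # small fixed grids lose selectivity but never invariance
  g10 <- random_threshold_grid(10, response_range(bank, ds$S), seed = 12)
  repk <- distance_report(ds, bank, grid = g10, n_pairs = 100, seed = 13)
  expect_true(all(repk$intra == 0))

  empty <- distance_report(ds, bank, n_pairs = 0, seed = 1)
  expect_length(empty$intra, 0)
  expect_true(is.na(overlap_fraction(empty)))

  one_orbit <- build_orbit_dataset(G, sample_base_points(1, 6, seed = 14))
  expect_error(distance_report(one_orbit, bank, n_pairs = 5), "2 orbits")
})

test_that("identical distance distributions give full histogram overlap", {
  G <- cyclic_permutation_group(6)
  ds <- make_orbit_dataset(G, 10, seed = 15)
  bank <- orbit_bank(G, unit_vec(6, seed = 16))
  rep <- distance_report(ds, bank, grid = "full", n_pairs = 50, seed = 17)
  fake <- rep
  fake$intra <- fake$inter
  expect_equal(overlap_fraction(fake), 1)
})

test_that("cosine similarity is 1 for identical stimuli and the averaged
           curve rises to a plateau on toy data", {
  G <- cyclic_permutation_group(6)
  bank <- orbit_bank(G, unit_vec(6, seed = 18))
  x <- sample_base_points(1, 6, seed = 19)[, 1]

  cv_same <- cosine_similarity_curve(x, x, bank, K_list = c(2, 5, 10),
                                     reps = 30, seed = 20,
                                     zero_handling = "missing")
  expect_equal(cv_same$mean_cosine, rep(1, 3), tolerance = 1e-12)

  ds <- make_orbit_dataset(G, 40, seed = 21)
  cv <- cosine_curve_report(ds, bank, n_pairs = 20, reps = 30, seed = 22)
  expect_gt(attr(cv, "spearman"), 0)
  expect_lt(attr(cv, "plateau_gap"), 0.02)
})

test_that("the Hoeffding bound has the stated algebra and limits", {
  expect_equal(hoeffding_bound(10, 1e-9, 1), 2, tolerance = 1e-6)
  # doubling Q squares the exponential factor
  for (Q in c(10, 50)) {
    for (eps in c(0.05, 0.2)) {
      expect_equal(hoeffding_bound(2 * Q, eps, 1),
                   hoeffding_bound(Q, eps, 1)^2 / 2, tolerance = 1e-12)
    }
  }
  expect_true(hoeffding_bound(200, 0.1, 1) < hoeffding_bound(50, 0.1, 1))
  expect_error(hoeffding_bound(-1, 0.1, 1), "positive")
})

test_that("the exact expected distance matches Monte Carlo and the bound
           covers the estimator", {
  G <- cyclic_permutation_group(6)
  bank <- orbit_bank(G, unit_vec(6, seed = 23))
  x <- sample_base_points(1, 6, seed = 24)[, 1]
  y <- sample_base_points(1, 6, seed = 25)[, 1]

  cov <- hoeffding_coverage(x, y, bank, Q_values = c(10, 50),
                            eps_values = c(0.05, 0.1), n_draws = 2000,
                            seed = 26)
  expect_true(all(cov$empirical <= cov$bound))

  # independent check of the closed-form expectation by brute Monte Carlo
  rx <- sort(as.numeric(crossprod(bank$W, x)))
  ry <- sort(as.numeric(crossprod(bank$W, y)))
  b <- range(c(rx, ry))
  z <- with_local_seed(27, stats::runif(2e5, b[1], b[2]))
  d_mc <- mean(abs((6 - findInterval(z, rx, left.open = TRUE)) -
                     (6 - findInterval(z, ry, left.open = TRUE))) / 6)
  expect_equal(attr(cov, "dist_exact"), d_mc, tolerance = 0.01)
})
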