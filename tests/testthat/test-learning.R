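test_that("elementwise loss equals the Frobenius form for the square loss", {
  for (s in 1:100) {
    W <- rand_W(5, 3, seed = s)
    S <- rand_W(5, 8, seed = 1000 + s)
    nl <- logistic_surrogate(0, 10)
    spec <- loss_spec("square", nonlinearity = nl)
    l_sum <- unsup_loss(W, S, spec)
    l_frob <- frobenius_response_norm(W, S, nl)
    expect_lt(abs(l_sum - l_frob), 1e-12 * max(1, abs(l_sum)))
    # and both agree with the double-loop oracle
    expect_equal(l_sum, loss_oracle(W, S, function(u) u^2, nl),
                 tolerance = 1e-12)
  }
})

test_that("a big negative Heaviside threshold saturates the loss", {
  W <- rand_W(6, 4, seed = 3)
  S <- sample_base_points(20, 6, seed = 4)
  bank <- simple_cell_bank(W, heaviside(0))
  z <- big_negative_threshold(bank, S)
  spec <- loss_spec("square", nonlinearity = heaviside(z))
  expect_identical(unsup_loss(W, S, spec), 4 * 20) # every sigma = 1
})

test_that("the loss is invariant under W -> gW on orbit-complete stimuli", {
  for (G in list(cyclic_permutation_group(6),
                 dihedral_permutation_group(6))) {
    ds <- make_orbit_dataset(G, 5, seed = 7)
    W <- rand_W(6, 4, seed = 8)
    spec <- loss_spec("square")
    l0 <- unsup_loss(W, ds$S, spec)
    for (g in G$elements) {
      expect_lt(abs(unsup_loss(g %*% W, ds$S, spec) - l0),
                1e-10 * max(1, l0))
    }
  }
})

test_that("gradients match central finite differences", {
  W <- rand_W(4, 3, seed = 11) * 0.3
  S <- rand_W(4, 6, seed = 12)
  for (f in c("square", "abs", "huber")) {
    spec <- loss_spec(f, nonlinearity = logistic_surrogate(0, 5))
    G <- unsup_grad(W, S, spec)
    h <- 1e-6
    for (idx in list(c(1, 1), c(3, 2), c(4, 3))) {
      Wp <- W; Wm <- W
      Wp[idx[1], idx[2]] <- Wp[idx[1], idx[2]] + h
      Wm[idx[1], idx[2]] <- Wm[idx[1], idx[2]] - h
      fd <- (unsup_loss(Wp, S, spec) - unsup_loss(Wm, S, spec)) / (2 * h)
      expect_lt(abs(G[idx[1], idx[2]] - fd) / max(1e-8, abs(fd)), 1e-5)
    }
  }
  expect_error(unsup_grad(W, S, loss_spec(nonlinearity = heaviside(0))),
               "surrogate")
})

test_that("the gradient at W = 0 is the stimulus sum replicated per cell", {
  S <- rand_W(5, 9, seed = 13)
  nl <- logistic_surrogate(-0.5, 4)
  spec <- loss_spec("square", nonlinearity = nl)
  G <- unsup_grad(matrix(0, 5, 3), S, spec)
  sig0 <- stats::plogis(4 * 0.5)
  coef <- 2 * sig0 * 4 * sig0 * (1 - sig0)  # f'(sigma(0)) * sigma'(0)
  expected <- coef * rowSums(S)
  for (i in 1:3) expect_equal(G[, i], expected, tolerance = 1e-12)
})

test_that("gradient equivariance holds on full orbits and degrades on
           truncated ones", {
  for (G in list(cyclic_permutation_group(6),
                 dihedral_permutation_group(6))) {
    ds <- make_orbit_dataset(G, 10, seed = 17)
    W <- rand_W(6, 4, seed = 18)
    res <- gradient_equivariance_residual(W, ds, G)
    expect_true(res$orbit_complete)
    expect_lt(res$residual, 1e-10)

    half <- subsample_orbits(ds, 0.5, seed = 19)
    expect_warning(
      res_half <- gradient_equivariance_residual(W, half, G),
      "complete")
    expect_false(res_half$orbit_complete)
    expect_gt(res_half$residual, res$residual)
  }

  # trivial group: residual identically zero
  G1 <- planar_rotation_group(1)
  S1 <- sample_base_points(5, 2, seed = 20)
  expect_identical(
    gradient_equivariance_residual(rand_W(2, 2, seed = 21), S1,
                                   G1)$residual, 0)
})

test_that("training is monotone, deterministic and checkpoint-equivariant", {
  G <- cyclic_permutation_group(6)
  ds <- make_orbit_dataset(G, 10, seed = 23)
  st <- train_simple_cells(ds, alpha = 1e-3, epochs = 6, seed = 1)
  expect_true(all(diff(st$loss_trace) >= 0))
  expect_equal(st$t, 6 * 60) # epochs * |G| * Q presentations
  # solution-space equivariance at every epoch checkpoint
  expect_true(all(st$equivariance_trace < 1e-8))

  st2 <- train_simple_cells(ds, alpha = 1e-3, epochs = 6, seed = 1)
  expect_identical(st$W, st2$W)

  st0 <- train_simple_cells(ds, alpha = 1e-3, epochs = 2, init = "zero")
  expect_true(is.finite(st0$loss_trace[3]))
})

test_that("constrained maximization stays on the Stiefel manifold", {
  G <- cyclic_permutation_group(6)
  S <- make_orbit_dataset(G, 20, seed = 29)
  S_new <- make_orbit_dataset(G, 2, seed = 30)
  fit <- constrained_maximize(S, S_new, lambda = 1, n_cells = 6, seed = 2,
                              max_iter = 60)
  expect_lt(fit$ortho_residual, 1e-8)
  expect_true(all(diff(fit$objective) >= 0))

  fit2 <- constrained_maximize(S, S_new, lambda = 1, n_cells = 6, seed = 2,
                               max_iter = 60)
  expect_identical(fit$U, fit2$U)

  expect_error(constrained_maximize(S, S_new, n_cells = 7),
               "orthonormal frame")
})
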