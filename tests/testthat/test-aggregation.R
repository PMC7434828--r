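# Constructed candidate pool with a guaranteed pooled-response gap: the
# target orbit of a unit template responds ~1 on its own orbit (the
# identity-aligned stimulus clears the z = 0.5 surrogate threshold), while
# a scaled-down distractor's responses stay below it by Cauchy-Schwarz, so
# its pooled response is ~0.
gap_instance <- function(seed, G) {
  wbar <- unit_vec(G$d, seed = seed)
  v <- 0.05 * unit_vec(G$d, seed = seed + 5000)
  list(wbar = wbar,
       candidates = cbind(orbit(G, wbar), orbit(G, v)),
       S_new = orbit(G, wbar),
       spec = loss_spec("square",
                        nonlinearity = logistic_surrogate(0.5, 20)))
}

test_that("select_max_cell returns the argmax of the pooled response", {
  # aligned beats orthogonal in the surrogate-linear regime
  s <- c(1, 0, 0)
  cands <- cbind(c(1, 0, 0), c(0, 1, 0))
  spec <- loss_spec("square", nonlinearity = logistic_surrogate(0, 2))
  expect_equal(select_max_cell(cands, matrix(s), spec), 1L)

  # exhaustive oracle agreement on 100 random instances
  for (r in 1:100) {
    cands <- rand_W(4, 7, seed = r)
    S_new <- rand_W(4, 5, seed = 3000 + r)
    got <- select_max_cell(cands, S_new, spec)
    oracle <- which.max(vapply(seq_len(7), function(i) {
      sum(stats::plogis(2 * as.numeric(cands[, i] %*% S_new))^2)
    }, numeric(1)))
    expect_equal(got, oracle)
  }

  # exact duplicates tie; the lowest index wins
  dup <- cbind(c(1, 0, 0), c(1, 0, 0))
  expect_equal(select_max_cell(dup, matrix(s), spec), 1L)
  expect_error(pooled_response(matrix(numeric(0), 3, 0), matrix(s), spec),
               "nonempty")
})

test_that("pooled responses are constant on weight orbits over
           orbit-complete stimuli", {
  G <- cyclic_permutation_group(6)
  inst <- gap_instance(1, G)
  p <- pooled_response(orbit(G, inst$wbar), inst$S_new, inst$spec)
  expect_lt(max(p) - min(p), 1e-12 * max(1, max(p)))
})

test_that("aggregation recovers the target orbit from a gapped pool", {
  G <- cyclic_permutation_group(6)
  for (s in 1:10) {
    inst <- gap_instance(s, G)
    # verify the constructed gap: every target beats every distractor
    p <- pooled_response(inst$candidates, inst$S_new, inst$spec)
    expect_gt(min(p[1:6]), max(p[7:12]))

    agg <- aggregate_orbit(inst$candidates, inst$S_new, group_size = 6,
                           spec = inst$spec, group = G)
    expect_setequal(agg$selected_indices, 1:6)
    expect_true(agg$is_orbit)
    expect_lt(max(agg$matching$residual), 1e-12)
  }
})

test_that("duplicate candidates are skipped without affecting selection", {
  G <- cyclic_permutation_group(6)
  inst <- gap_instance(3, G)
  orb <- orbit(G, inst$wbar)
  doubled <- cbind(orb, orb)
  agg <- aggregate_orbit(doubled, inst$S_new, group_size = 6,
                         spec = inst$spec, group = G)
  expect_equal(agg$dedup_count, 6L)
  expect_true(agg$is_orbit)

  # group_size = 1 returns just the maximal cell
  one <- aggregate_orbit(orb, inst$S_new, group_size = 1, spec = inst$spec)
  expect_equal(ncol(one$selected_weights), 1L)

  # pool exhaustion raises with the achieved count
  expect_error(aggregate_orbit(cbind(orb[, 1], orb[, 1]), inst$S_new,
                               group_size = 2, spec = inst$spec),
               "exhausted")
})

test_that("is_weight_orbit matches shuffled orbits and rejects outliers", {
  G <- dihedral_permutation_group(5)
  wbar <- unit_vec(5, seed = 31)
  orb <- orbit(G, wbar)
  shuffle <- with_local_seed(32, sample(G$N))
  shuffle <- c(1L, setdiff(shuffle, 1L)) # template stays first
  chk <- is_weight_orbit(orb[, shuffle], G)
  expect_true(chk$is_orbit)
  expect_equal(chk$matching$element, shuffle)
  expect_false(chk$degenerate)

  bad <- orb[, shuffle]
  bad[, 4] <- unit_vec(5, seed = 33)
  expect_false(is_weight_orbit(bad, G)$is_orbit)

  zero <- is_weight_orbit(matrix(0, 5, G$N), G)
  expect_true(zero$is_orbit)
  expect_true(zero$degenerate)

  expect_error(is_weight_orbit(orb[, 1:3], G), "columns")
})

test_that("orbit banks give exactly invariant complex cells;
           broken orbits do not", {
  G <- cyclic_permutation_group(6)
  wbar <- unit_vec(6, seed = 41)
  X <- sample_base_points(20, 6, seed = 42)

  bank <- orbit_bank(G, wbar, heaviside(0.2))
  expect_identical(invariance_residual(bank, G, X), 0)

  # rotation group: residual at float round-off level
  R12 <- planar_rotation_group(12)
  bank2 <- orbit_bank(R12, c(0.8, 0.1), heaviside(0.15))
  X2 <- sample_base_points(20, 2, seed = 43)
  expect_lt(invariance_residual(bank2, R12, X2), 1e-10)

  # perturbing one weight column breaks invariance for generic points
  Wb <- orbit(G, wbar)
  Wb[, 3] <- unit_vec(6, seed = 44)
  bank3 <- simple_cell_bank(Wb, heaviside(0.2))
  expect_gt(invariance_residual(bank3, G, X), 0)
})
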