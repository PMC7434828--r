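test_that("cyclic permutation groups enumerate exactly the cyclic shifts", {
  # identity case
  G1 <- cyclic_permutation_group(1)
  expect_equal(G1$N, 1L)
  expect_identical(G1$elements[[1]], diag(1))

  # d = 3: brute-force enumeration of the cyclic permutations of (1,2,3)
  G3 <- cyclic_permutation_group(3)
  shifts <- lapply(0:2, function(k) ((0:2 + k) %% 3) + 1)
  expected <- lapply(shifts, function(p) {
    m <- matrix(0, 3, 3)
    m[cbind(p, 1:3)] <- 1
    m
  })
  for (i in 1:3) expect_identical(G3$elements[[i]], expected[[i]])

  # d = 6: all axioms pass with residual exactly 0 (permutation matrices)
  rep6 <- verify_group_axioms(cyclic_permutation_group(6), tol = 1e-12)
  expect_true(rep6$all_pass)
  expect_identical(rep6$closure_residual, 0)
  expect_identical(rep6$orthogonal_residual, 0)

  expect_error(cyclic_permutation_group(0), "integer")
})

test_that("dihedral groups are the symmetries of a labeled cycle", {
  G <- dihedral_permutation_group(3)
  expect_equal(G$N, 6L)
  # brute force: all 6 permutations of 3 symbols preserve the 3-cycle,
  # so the group must contain every 3x3 permutation matrix exactly once
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  found <- apply(perms, 1, function(p) {
    m <- matrix(0, 3, 3)
    m[cbind(p, 1:3)] <- 1
    any(vapply(G$elements, function(g) identical(g, m), logical(1)))
  })
  expect_true(all(found))
  expect_true(verify_group_axioms(G, tol = 1e-12)$all_pass)

  # product of two distinct reflections is an index rotation in the set
  refl <- G$elements[4:6]
  prod_rr <- refl[[1]] %*% refl[[2]]
  in_rotations <- any(vapply(G$elements[1:3],
                             function(g) identical(g, prod_rr), logical(1)))
  expect_true(in_rotations)

  # n = 6: order 12 and non-abelian (brute-force commutator check)
  G6 <- dihedral_permutation_group(6)
  expect_equal(G6$N, 12L)
  noncomm <- FALSE
  for (i in seq_len(G6$N)) {
    for (j in seq_len(G6$N)) {
      if (!identical(G6$elements[[i]] %*% G6$elements[[j]],
                     G6$elements[[j]] %*% G6$elements[[i]])) {
        noncomm <- TRUE
      }
    }
  }
  expect_true(noncomm)
  expect_error(dihedral_permutation_group(2), "integer")
})

test_that("planar rotation groups follow the stated sign convention", {
  expect_identical(planar_rotation_group(1)$elements[[1]], diag(2))

  # N = 4, theta = pi/2: rows (0, 1) and (-1, 0)
  R4 <- planar_rotation_group(4)
  expect_equal(R4$elements[[2]], matrix(c(0, -1, 1, 0), 2, 2),
               tolerance = 1e-15)

  # cyclicity: the 2*pi/6 element composed 6 times is the identity
  R6 <- planar_rotation_group(6)
  acc <- diag(2)
  for (k in 1:6) acc <- acc %*% R6$elements[[2]]
  expect_equal(acc, diag(2), tolerance = 1e-12)

  expect_true(verify_group_axioms(planar_rotation_group(12),
                                  tol = 1e-8)$all_pass)
})

test_that("patch rotation groups are exact permutations on the polar grid", {
  G <- patch_rotation_group(10, 6)
  expect_equal(G$d, 61L)     # 10 rings x 6 sectors + 1 center pixel
  expect_equal(G$N, 6L)
  rep <- verify_group_axioms(G, tol = 1e-12)
  expect_true(rep$all_pass)
  expect_identical(rep$closure_residual, 0)

  expect_equal(patch_rotation_group(3, 1)$N, 1L)

  # applying the shift-3 element twice equals shift 6 = identity (N = 6)
  sq <- G$elements[[4]] %*% G$elements[[4]]
  expect_identical(sq, G$elements[[1]])

  # the center pixel is fixed by every element
  for (g in G$elements) expect_identical(g[61, 61], 1)
})

test_that("axiom verification flags a set missing the identity", {
  G <- cyclic_permutation_group(4)
  broken <- finite_group(G$elements[2:4], kind = "custom")
  rep <- verify_group_axioms(broken)
  expect_false(rep$identity)
  expect_false(rep$all_pass)
})

test_that("orbits are computed column-wise in element order", {
  G3 <- cyclic_permutation_group(3)
  O <- orbit(G3, c(1, 0, 0))
  expect_identical(O, diag(3)[, c(1, 2, 3)])
  expect_true(all(colSums(O) == 1))

  # planar rotations of (1, 0): apply the printed matrix formula by hand
  R4 <- planar_rotation_group(4)
  O2 <- orbit(R4, c(1, 0))
  expect_equal(O2, cbind(c(1, 0), c(0, -1), c(-1, 0), c(0, 1)),
               tolerance = 1e-12)

  expect_identical(orbit(G3, c(0, 0, 0)), matrix(0, 3, 3))
  expect_error(orbit(G3, c(1, 0)), "length")
})

test_that("orbit of a transformed point is a column permutation", {
  G <- dihedral_permutation_group(5)
  x <- sample_base_points(1, 5, seed = 4)[, 1]
  O1 <- orbit(G, x)
  for (gi in c(2L, 7L)) {
    O2 <- orbit(G, G$elements[[gi]] %*% x)
    # greedy matching of columns within 1e-10
    used <- logical(G$N)
    for (j in seq_len(G$N)) {
      dists <- sqrt(colSums((O1 - O2[, j])^2))
      dists[used] <- Inf
      k <- which.min(dists)
      expect_lt(dists[k], 1e-10)
      used[k] <- TRUE
    }
  }
})

test_that("same_orbit is an equivalence relation with witnesses", {
  G <- cyclic_permutation_group(6)
  x <- sample_base_points(1, 6, seed = 11)[, 1]

  res <- same_orbit(G, x, x)
  expect_true(res$same)
  expect_equal(res$witness, 1L) # identity

  # y = g x: witness recovers g (x -> g y means g maps y to x; here
  # x = g4 %*% y has witness 4 when asking same_orbit(x, y))
  y <- as.numeric(G$elements[[4]] %*% x)
  res2 <- same_orbit(G, y, x)
  expect_true(res2$same)
  expect_equal(res2$witness, 4L)

  # independent unit-ball vectors are in different orbits a.s.
  z <- sample_base_points(1, 6, seed = 12)[, 1]
  expect_false(same_orbit(G, x, z)$same)

  # symmetry and transitivity inside one orbit
  a <- as.numeric(G$elements[[2]] %*% x)
  b <- as.numeric(G$elements[[5]] %*% x)
  expect_true(same_orbit(G, a, b)$same)
  expect_true(same_orbit(G, b, a)$same)
  expect_true(same_orbit(G, a, x)$same && same_orbit(G, x, b)$same &&
                same_orbit(G, a, b)$same)
})
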