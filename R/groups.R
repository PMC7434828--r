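#' Finite orthogonal groups of d x d matrices
#'
#' A `finite_group` is an ordered set of `N` orthogonal `d x d` matrices
#' closed under matrix multiplication, containing the identity, and closed
#' under inversion (for orthogonal matrices `g^-1 = t(g)`). Element 1 is
#' always the identity. Permutation-matrix groups satisfy all axioms with
#' residual exactly 0; rotation groups satisfy them up to trigonometric
#' round-off.
#'
#' @param elements list of `d x d` orthogonal matrices; element 1 must be
#'   the identity.
#' @param kind label: one of `"cyclic_perm"`, `"dihedral_perm"`,
#'   `"planar_rotation"`, `"patch_rotation"`, `"custom"`.
#' @param layout optional list of extra structural metadata (used by the
#'   patch-rotation constructor to record the polar-grid layout).
#' @return an object of class `finite_group` with fields `elements`,
#'   `kind`, `d` (ambient dimension) and `N` (group order).
#' @seealso [cyclic_permutation_group()], [dihedral_permutation_group()],
#'   [planar_rotation_group()], [patch_rotation_group()],
#'   [verify_group_axioms()]
#' @export
finite_group <- function(elements, kind = "custom", layout = NULL) {
  if (!is.list(elements) || length(elements) == 0L) {
    stop("`elements` must be a nonempty list of matrices", call. = FALSE)
  }
  d <- nrow(elements[[1L]])
  ok <- vapply(elements, function(m) {
    is.matrix(m) && all(dim(m) == c(d, d)) && all(is.finite(m))
  }, logical(1))
  if (!all(ok)) {
    stop("all elements must be finite square matrices of equal side",
         call. = FALSE)
  }
  structure(
    list(elements = elements, kind = kind, d = d, N = length(elements),
         layout = layout),
    class = "finite_group"
  )
}

#' @export
print.finite_group <- function(x, ...) {
  cat(sprintf("<finite_group> kind=%s  d=%d  N=%d\n", x$kind, x$d, x$N))
  invisible(x)
}

# Permutation matrix sending e_j to e_{p[j]}.
perm_matrix <- function(p) {
  d <- length(p)
  m <- matrix(0, d, d)
  m[cbind(p, seq_len(d))] <- 1
  m
}

#' Cyclic permutation group on R^d
#'
#' The `d` cyclic index-shift permutation matrices acting on `R^d`, in
#' increasing shift order; element 1 is the identity (shift 0).
#'
#' @param d ambient dimension (and group order), a positive integer.
#' @return a [finite_group()] of order `d`.
#' @examples
#' G <- cyclic_permutation_group(6)
#' verify_group_axioms(G)$all_pass
#' @export
cyclic_permutation_group <- function(d) {
  stop_if_not_count(d, "d", 1L)
  elements <- lapply(seq_len(d) - 1L, function(k) {
    perm_matrix(((seq_len(d) - 1L + k) %% d) + 1L)
  })
  finite_group(elements, kind = "cyclic_perm")
}

#' Dihedral permutation group on R^n
#'
#' The `2n` symmetries of a cycle of `n` labeled positions, as permutation
#' matrices on `R^n`: the `n` index rotations first (element 1 = identity),
#' then the `n` index reflections. Non-abelian for `n >= 3`.
#'
#' @param n number of cycle positions (ambient dimension); integer `>= 3`.
#' @return a [finite_group()] of order `2n`.
#' @examples
#' G <- dihedral_permutation_group(3)
#' G$N # 6: the symmetries of a labeled triangle
#' @export
dihedral_permutation_group <- function(n) {
  stop_if_not_count(n, "n", 3L)
  idx <- seq_len(n) - 1L
  rot <- lapply(idx, function(k) perm_matrix(((idx + k) %% n) + 1L))
  ref <- lapply(idx, function(k) perm_matrix(((k - idx) %% n) + 1L))
  finite_group(c(rot, ref), kind = "dihedral_perm")
}

#' Finite planar rotation group R_N
#'
#' The `N` rotations of the plane by angles `theta_i = i * 2*pi/N`,
#' `i = 0, ..., N-1`, as 2 x 2 matrices with row 1 `(cos, sin)` and row 2
#' `(-sin, cos)`. Element 1 (`i = 0`) is the identity.
#'
#' @param N number of rotations, a positive integer.
#' @return a [finite_group()] of order `N` with `d = 2`.
#' @examples
#' planar_rotation_group(4)$elements[[2]] # rows (0, 1), (-1, 0)
#' @export
planar_rotation_group <- function(N) {
  stop_if_not_count(N, "N", 1L)
  elements <- lapply(seq_len(N) - 1L, function(i) {
    th <- i * 2 * pi / N
    matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L)
  })
  finite_group(elements, kind = "planar_rotation")
}

#' Exact rotation group for disk-shaped patches on a polar grid
#'
#' Pixels of a disk of radius `radius` are arranged on a polar grid of
#' `radius` concentric rings with `n_angles` angular sectors each, plus one
#' fixed center pixel (ambient dimension `radius * n_angles + 1`). Rotation
#' by `i * 2*pi/n_angles` cycles the sector index within every ring and
#' fixes the center, so every group element is an exact permutation matrix
#' and the finite-orthogonal-group assumption holds with zero residual (a
#' raster grid would need interpolation, which breaks orthogonality).
#'
#' @param radius number of rings, a positive integer.
#' @param n_angles number of equally spaced rotation angles (group order).
#' @return a [finite_group()] of order `n_angles` acting on
#'   `R^(radius * n_angles + 1)`, with a `layout` field recording
#'   `radius`, `n_angles` and the center-pixel index.
#' @examples
#' G <- patch_rotation_group(10, 6) # paper-scale patches: d = 61
#' G$d
#' @export
patch_rotation_group <- function(radius, n_angles) {
  stop_if_not_count(radius, "radius", 1L)
  stop_if_not_count(n_angles, "n_angles", 1L)
  d <- radius * n_angles + 1L
  center <- d
  elements <- lapply(seq_len(n_angles) - 1L, function(k) {
    p <- integer(d)
    for (r in seq_len(radius)) {
      a <- seq_len(n_angles)
      p[(r - 1L) * n_angles + a] <- (r - 1L) * n_angles +
        (((a - 1L + k) %% n_angles) + 1L)
    }
    p[center] <- center
    perm_matrix(p)
  })
  finite_group(elements, kind = "patch_rotation",
               layout = list(radius = as.integer(radius),
                             n_angles = as.integer(n_angles),
                             center = center))
}

# Index of the element of `group` matching matrix `m` within `tol`
# (max-abs residual), or NA_integer_. Also returns the residual.
match_element <- function(group, m, tol = 1e-8) {
  res <- vapply(group$elements, function(g) max(abs(g - m)), numeric(1))
  i <- which.min(res)
  list(index = if (res[i] <= tol) i else NA_integer_, residual = res[i])
}

#' Numerically verify the group axioms
#'
#' Checks orthogonality, identity membership, closure, inversion
#' (`t(g)` is in the group) and associativity, reporting per-axiom pass
#' flags and worst-case max-abs matrix residuals. Associativity is checked
#' exhaustively for `N <= 16` and on 1000 deterministic random triples
#' otherwise.
#'
#' @param group a [finite_group()].
#' @param tol residual tolerance for each axiom check.
#' @return a list of class `axiom_report`: logical flags `orthogonal`,
#'   `identity`, `closure`, `inverse`, `associativity`, `all_pass`, and the
#'   matching residuals.
#' @export
verify_group_axioms <- function(group, tol = 1e-8) {
  stopifnot(inherits(group, "finite_group"))
  els <- group$elements
  N <- group$N
  d <- group$d
  I <- diag(d)

  orth_res <- max(vapply(els, function(g) max(abs(crossprod(g) - I)),
                         numeric(1)))
  id_res <- min(vapply(els, function(g) max(abs(g - I)), numeric(1)))

  closure_res <- 0
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      closure_res <- max(closure_res,
                         match_element(group, els[[i]] %*% els[[j]],
                                       tol = Inf)$residual)
    }
  }
  inverse_res <- max(vapply(els, function(g) {
    match_element(group, t(g), tol = Inf)$residual
  }, numeric(1)))

  if (N <= 16L) {
    triples <- as.matrix(expand.grid(i = seq_len(N), j = seq_len(N),
                                     k = seq_len(N)))
  } else {
    triples <- with_seed(N, matrix(sample.int(N, 3L * 1000L, replace = TRUE),
                                   ncol = 3L))
  }
  assoc_res <- 0
  for (r in seq_len(nrow(triples))) {
    a <- els[[triples[r, 1L]]]
    b <- els[[triples[r, 2L]]]
    cc <- els[[triples[r, 3L]]]
    assoc_res <- max(assoc_res, max(abs((a %*% b) %*% cc - a %*% (b %*% cc))))
  }

  rep <- list(
    orthogonal = orth_res <= tol, orthogonal_residual = orth_res,
    identity = id_res <= tol, identity_residual = id_res,
    closure = closure_res <= tol, closure_residual = closure_res,
    inverse = inverse_res <= tol, inverse_residual = inverse_res,
    associativity = assoc_res <= tol, associativity_residual = assoc_res,
    tol = tol
  )
  rep$all_pass <- rep$orthogonal && rep$identity && rep$closure &&
    rep$inverse && rep$associativity
  class(rep) <- "axiom_report"
  rep
}

#' @export
print.axiom_report <- function(x, ...) {
  cat(sprintf(
    paste0("<axiom_report> all_pass=%s (tol=%g)\n",
           "  orthogonal=%s (%.2e)  identity=%s (%.2e)  closure=%s (%.2e)\n",
           "  inverse=%s (%.2e)  associativity=%s (%.2e)\n"),
    x$all_pass, x$tol,
    x$orthogonal, x$orthogonal_residual, x$identity, x$identity_residual,
    x$closure, x$closure_residual, x$inverse, x$inverse_residual,
    x$associativity, x$associativity_residual))
  invisible(x)
}

#' Orbit of a point under a finite group
#'
#' @param group a [finite_group()].
#' @param x numeric vector of length `group$d`.
#' @return a `d x N` matrix whose column `i` is `elements[[i]] %*% x`;
#'   the identity column (column 1) equals `x`.
#' @examples
#' orbit(cyclic_permutation_group(3), c(1, 0, 0)) # the 3 one-hot vectors
#' @export
orbit <- function(group, x) {
  stopifnot(inherits(group, "finite_group"))
  x <- as.numeric(x)
  if (length(x) != group$d) {
    stop(sprintf("`x` must have length %d (got %d)", group$d, length(x)),
         call. = FALSE)
  }
  vapply(group$elements, function(g) as.numeric(g %*% x), numeric(group$d))
}

#' Are two points in the same group orbit?
#'
#' Tests the orbit equivalence relation: `x ~ y` iff some group element
#' maps `y` onto `x` within `tol` (Euclidean norm).
#'
#' @param group a [finite_group()].
#' @param x,y numeric vectors of length `group$d`.
#' @param tol match tolerance on `||x - g y||_2`.
#' @return list with `same` (logical), `witness` (index of the minimizing
#'   element; the recovering `g` when `same` is `TRUE`) and `residual`
#'   (the minimal distance).
#' @export
same_orbit <- function(group, x, y, tol = 1e-8) {
  stopifnot(inherits(group, "finite_group"))
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != group$d || length(y) != group$d) {
    stop("`x` and `y` must both have length `group$d`", call. = FALSE)
  }
  dn <- sqrt(colSums((orbit(group, y) - x)^2))
  i <- which.min(dn)
  list(same = dn[i] <= tol, witness = i, residual = dn[i])
}
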