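#' Sample base points uniformly from the unit ball
#'
#' Draws `Q` i.i.d. points uniformly from the closed unit l2-ball of `R^d`
#' by normalizing a Gaussian vector to the sphere and scaling by
#' `U^(1/d)`, which is exact and fully seedable.
#'
#' @param Q number of points.
#' @param d ambient dimension.
#' @param seed integer RNG seed; identical seeds give bit-identical draws.
#' @return a `d x Q` matrix, one point per column, each with norm `<= 1`.
#' @examples
#' X <- sample_base_points(100, 6, seed = 1)
#' max(sqrt(colSums(X^2))) # <= 1
#' @export
sample_base_points <- function(Q, d, seed = NULL) {
  stop_if_not_count(Q, "Q", 1L)
  stop_if_not_count(d, "d", 1L)
  with_seed(seed, {
    g <- matrix(stats::rnorm(d * Q), d, Q)
    nrm <- sqrt(colSums(g^2))
    nrm[nrm == 0] <- 1
    r <- stats::runif(Q)^(1 / d)
    sweep(g, 2L, r / nrm, `*`)
  })
}

#' Assemble an orbit-structured stimulus dataset
#'
#' Expands `Q` base points into their full group orbits: the stimulus
#' matrix `S` has `Q * N` columns; the block for base point `q` contains
#' `elements[[i]] %*% x_q` in group-element order.
#'
#' Base points falling in the same orbit (a probability-zero event for
#' continuous sampling) violate the distinct-base-set assumption; when
#' `check_distinct` is `TRUE` they raise an error.
#'
#' @param group a [finite_group()].
#' @param base_points `d x Q` matrix (or length-`d` vector) of base points.
#' @param seed optional seed recorded for provenance (not used for
#'   randomness here).
#' @param check_distinct verify pairwise orbit-distinctness of the base
#'   points (default: only when `Q <= 200`, to bound the O(Q^2 N) cost).
#' @return an object of class `orbit_dataset`: list with `group`,
#'   `base_points`, `S` (`d x (Q*N)`), `orbit_label` (base-point index per
#'   column), `element_index` (group-element index per column), `Q`, `N`,
#'   `complete` (TRUE when every orbit is full) and `seed`.
#' @export
build_orbit_dataset <- function(group, base_points, seed = NULL,
                                check_distinct = NULL) {
  stopifnot(inherits(group, "finite_group"))
  base_points <- as_stimulus_matrix(base_points)
  if (nrow(base_points) != group$d) {
    stop(sprintf("base points have dimension %d but the group acts on R^%d",
                 nrow(base_points), group$d), call. = FALSE)
  }
  Q <- ncol(base_points)
  N <- group$N
  if (is.null(check_distinct)) check_distinct <- Q <= 200L
  if (check_distinct && Q >= 2L) {
    n2 <- colSums(base_points^2)
    for (g in group$elements) {
      D2 <- outer(n2, n2, `+`) - 2 * crossprod(base_points, g %*% base_points)
      D2[lower.tri(D2, diag = TRUE)] <- Inf
      if (any(D2 < (1e-8)^2)) {
        stop("two base points lie in the same orbit; resample them",
             call. = FALSE)
      }
    }
  }
  S <- matrix(0, group$d, Q * N)
  for (q in seq_len(Q)) {
    S[, (q - 1L) * N + seq_len(N)] <- orbit(group, base_points[, q])
  }
  structure(
    list(group = group, base_points = base_points, S = S,
         orbit_label = rep(seq_len(Q), each = N),
         element_index = rep(seq_len(N), times = Q),
         Q = Q, N = N, complete = TRUE, seed = seed),
    class = "orbit_dataset"
  )
}

#' @export
print.orbit_dataset <- function(x, ...) {
  cat(sprintf(
    "<orbit_dataset> %d orbits x %d elements = %d stimuli in R^%d (%s%s)\n",
    x$Q, x$N, ncol(x$S), nrow(x$S), x$group$kind,
    if (x$complete) "" else ", partial orbits"))
  invisible(x)
}

#' Sample an orbit dataset of unit-ball base points
#'
#' Convenience wrapper: draws `Q` base points uniformly from the unit ball
#' ([sample_base_points()]), resampling any point that collides with an
#' existing orbit, then expands them with [build_orbit_dataset()].
#'
#' @inheritParams build_orbit_dataset
#' @param Q number of orbits.
#' @param seed integer RNG seed.
#' @return an `orbit_dataset`.
#' @export
make_orbit_dataset <- function(group, Q, seed = NULL) {
  stop_if_not_count(Q, "Q", 1L)
  X <- sample_base_points(Q, group$d, seed = seed)
  if (Q >= 2L && Q <= 200L) {
    with_seed(if (is.null(seed)) NULL else seed + 1L, {
      for (q in seq(2L, Q)) {
        tries <- 0L
        while (any(vapply(seq_len(q - 1L), function(p) {
          same_orbit(group, X[, q], X[, p])$same
        }, logical(1)))) {
          X[, q] <- sample_base_points(1L, group$d)
          tries <- tries + 1L
          if (tries > 100L) stop("could not sample distinct base points")
        }
      }
    })
  }
  build_orbit_dataset(group, X, seed = seed, check_distinct = FALSE)
}

# Circular Gaussian smoothing of a length-n vector (angular direction).
smooth_circular <- function(v, sd) {
  if (sd <= 1e-8) return(v)
  n <- length(v)
  h <- max(1L, ceiling(3 * sd))
  w <- stats::dnorm(seq(-h, h), sd = sd)
  w <- w / sum(w)
  out <- numeric(n)
  for (k in seq(-h, h)) {
    out <- out + w[k + h + 1L] * v[((seq_len(n) - 1L + k) %% n) + 1L]
  }
  out
}

# Truncated-Gaussian smoothing along a non-circular axis (radial direction).
smooth_linear <- function(v, sd) {
  if (sd <= 1e-8) return(v)
  n <- length(v)
  h <- max(1L, ceiling(3 * sd))
  w <- stats::dnorm(seq(-h, h), sd = sd)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- seq(max(1L, i - h), min(n, i + h))
    ww <- w[k - i + h + 1L]
    out[i] <- sum(ww * v[k]) / sum(ww)
  }
  out
}

#' Synthetic rotated-patch dataset on a polar grid
#'
#' Generates `Q` base "image patches" as smoothed Gaussian random fields on
#' the polar grid of [patch_rotation_group()] (rings x angular sectors plus
#' a center pixel), then expands each into its full rotation orbit. The
#' angular/radial Gaussian smoothing (`smoothness`, in grid-cell units)
#' emulates the spatial correlation of natural image patches;
#' `smoothness = 0` gives i.i.d. pixel noise. Each base patch is scaled to
#' unit l2 norm so response ranges are comparable with unit-ball toy data.
#'
#' @param Q number of base patches (orbits).
#' @param radius number of rings (paper-scale default 10).
#' @param n_angles number of rotation angles (paper-scale default 6).
#' @param smoothness Gaussian correlation length in grid cells; `0` =
#'   white noise.
#' @param seed integer RNG seed.
#' @return an `orbit_dataset` over the exact patch-rotation group, with
#'   `d = radius * n_angles + 1` and `Q * n_angles` stimulus columns.
#' @examples
#' ds <- make_toy_patches(10, radius = 10, n_angles = 6, seed = 1)
#' ncol(ds$S) # 60
#' @export
make_toy_patches <- function(Q, radius = 10, n_angles = 6, smoothness = 1,
                             seed = NULL) {
  stop_if_not_count(Q, "Q", 1L)
  stop_if_not_count(radius, "radius", 1L)
  stop_if_not_count(n_angles, "n_angles", 1L)
  if (!is.numeric(smoothness) || length(smoothness) != 1L ||
      !is.finite(smoothness) || smoothness < 0) {
    stop("`smoothness` must be a single nonnegative number", call. = FALSE)
  }
  group <- patch_rotation_group(radius, n_angles)
  d <- group$d
  base <- with_seed(seed, {
    vapply(seq_len(Q), function(q) {
      f <- matrix(stats::rnorm(radius * n_angles), radius, n_angles)
      if (smoothness > 0) {
        f <- t(apply(f, 1L, smooth_circular, sd = smoothness))
        f <- apply(f, 2L, smooth_linear, sd = smoothness)
        f <- matrix(f, radius, n_angles)
      }
      v <- c(as.numeric(t(f)), stats::rnorm(1L)) # ring-major pixels + center
      v / sqrt(sum(v^2))
    }, numeric(d))
  })
  build_orbit_dataset(group, base, seed = seed, check_distinct = FALSE)
}

#' Subsample orbits to emulate incomplete transformation sampling
#'
#' Keeps `ceiling(fraction * N)` stimuli per orbit, sampled without
#' replacement (in group-element order), modeling datasets where the
#' complete set of input orbits is not available. The resulting dataset is
#' flagged `complete = FALSE` unless `fraction = 1` (returned unchanged).
#'
#' @param dataset an `orbit_dataset`.
#' @param fraction fraction of each orbit to keep, in `(0, 1]`.
#' @param seed integer RNG seed for the per-orbit subsampling.
#' @return an `orbit_dataset` with partial orbits.
#' @export
subsample_orbits <- function(dataset, fraction, seed = NULL) {
  stopifnot(inherits(dataset, "orbit_dataset"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      !is.finite(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must be a single number in (0, 1]", call. = FALSE)
  }
  N <- dataset$N
  keep_n <- as.integer(ceiling(fraction * N))
  if (keep_n == N) return(dataset)
  keep <- with_seed(seed, {
    unlist(lapply(seq_len(dataset$Q), function(q) {
      (q - 1L) * N + sort(sample.int(N, keep_n))
    }))
  })
  out <- dataset
  out$S <- dataset$S[, keep, drop = FALSE]
  out$orbit_label <- dataset$orbit_label[keep]
  out$element_index <- dataset$element_index[keep]
  out$complete <- FALSE
  out
}
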