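#' Pointwise nonlinearities for simple cells
#'
#' `heaviside(z)` is the hard threshold `H(t - z)` with the closed-at-zero
#' convention `H(0) = 1`; it is the nonlinearity used for all evaluation
#' (signatures, distances, invariance checks). `logistic_surrogate(z, beta)`
#' is the smooth surrogate `1 / (1 + exp(-beta (t - z)))` used wherever a
#' derivative is required (learning); it converges pointwise to the
#' Heaviside as `beta -> Inf` away from the threshold.
#'
#' @param z threshold (offset) of the nonlinearity.
#' @param beta steepness of the logistic surrogate; positive.
#' @return an object of class `nonlinearity`.
#' @export
heaviside <- function(z = 0) {
  stopifnot(is.numeric(z), length(z) == 1L, is.finite(z))
  structure(list(kind = "heaviside", z = z), class = "nonlinearity")
}

#' @rdname heaviside
#' @export
logistic_surrogate <- function(z = 0, beta = 10) {
  stopifnot(is.numeric(z), length(z) == 1L, is.finite(z))
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0) {
    stop("`beta` must be a single positive number", call. = FALSE)
  }
  structure(list(kind = "logistic_surrogate", z = z, beta = beta),
            class = "nonlinearity")
}

nl_apply <- function(nl, t) {
  switch(nl$kind,
         heaviside = (t >= nl$z) + 0,
         logistic_surrogate = stats::plogis(nl$beta * (t - nl$z)),
         stop("unknown nonlinearity kind: ", nl$kind))
}

nl_deriv <- function(nl, t) {
  if (nl$kind == "heaviside") {
    stop(paste("the Heaviside nonlinearity has a degenerate derivative;",
               "use logistic_surrogate() for gradient computations"),
         call. = FALSE)
  }
  p <- stats::plogis(nl$beta * (t - nl$z))
  nl$beta * p * (1 - p)
}

#' Bank of simple cells
#'
#' A simple cell computes `sigma(w' x)`; a bank stacks the weights of
#' `N_cells` cells as the columns of `W` and shares one nonlinearity.
#'
#' @param W `d x N_cells` weight matrix (column `i` = weights of cell `i`).
#' @param nonlinearity a [heaviside()] or [logistic_surrogate()] spec.
#' @return an object of class `simple_cell_bank`.
#' @seealso [orbit_bank()] for a bank whose weights form a group orbit.
#' @export
simple_cell_bank <- function(W, nonlinearity = heaviside(0)) {
  W <- as_stimulus_matrix(W)
  if (!all(is.finite(W))) stop("`W` must be finite", call. = FALSE)
  stopifnot(inherits(nonlinearity, "nonlinearity"), ncol(W) >= 1L)
  structure(list(W = W, nonlinearity = nonlinearity),
            class = "simple_cell_bank")
}

#' @export
print.simple_cell_bank <- function(x, ...) {
  cat(sprintf("<simple_cell_bank> %d cells in R^%d, %s(z=%g%s)\n",
              ncol(x$W), nrow(x$W), x$nonlinearity$kind, x$nonlinearity$z,
              if (!is.null(x$nonlinearity$beta))
                sprintf(", beta=%g", x$nonlinearity$beta) else ""))
  invisible(x)
}

#' Bank whose weights are the group orbit of one template
#'
#' Builds the `|G|`-cell bank with weights `{g w : g in G}` — the
#' configuration under which the pooled complex cell is exactly invariant
#' to the group action.
#'
#' @param group a [finite_group()].
#' @param w template weight vector of length `group$d`.
#' @inheritParams simple_cell_bank
#' @return a [simple_cell_bank()] with `N_cells = group$N`.
#' @export
orbit_bank <- function(group, w, nonlinearity = heaviside(0)) {
  simple_cell_bank(orbit(group, w), nonlinearity)
}

check_dim <- function(bank, x) {
  x <- as_stimulus_matrix(x)
  if (nrow(x) != nrow(bank$W)) {
    stop(sprintf("stimulus dimension %d does not match weight dimension %d",
                 nrow(x), nrow(bank$W)), call. = FALSE)
  }
  x
}

#' Simple-cell responses
#'
#' `sigma(W' x)` for each cell: the bank's nonlinearity applied to the
#' scalar products between each stimulus and each cell's weights.
#'
#' @param bank a [simple_cell_bank()].
#' @param x stimulus vector, or matrix with one stimulus per column.
#' @return a vector of length `N_cells` (vector input) or an
#'   `N_cells x ncol(x)` matrix.
#' @export
simple_response <- function(bank, x) {
  xm <- check_dim(bank, x)
  r <- nl_apply(bank$nonlinearity, crossprod(bank$W, xm))
  if (!is.matrix(x)) as.numeric(r) else r
}

#' Complex-cell response
#'
#' The linear aggregation `c(x) = sum_i sigma(w_i' x)` over the bank. When
#' the bank's weights form a group orbit and the group consists of
#' permutation matrices, `c(g x) = c(x)` exactly.
#'
#' @inheritParams simple_response
#' @return a scalar (vector input) or a vector with one response per
#'   stimulus column.
#' @export
complex_response <- function(bank, x) {
  xm <- check_dim(bank, x)
  r <- colSums(nl_apply(bank$nonlinearity, crossprod(bank$W, xm)))
  if (!is.matrix(x)) r[[1L]] else r
}

#' Threshold grids for complex-cell signatures
#'
#' A strictly increasing sequence of Heaviside thresholds `z_1 < ... < z_K`
#' indexing the signature `c_z(x)`. `random_threshold_grid()` draws `K`
#' thresholds uniformly at random in a given response range (the sampled
#' regime of the finite-threshold analysis).
#'
#' @param thresholds numeric vector, strictly increasing.
#' @param mode provenance label, `"uniform_random_in_range"` or
#'   `"full_grid_of_observed_responses"` or `"manual"`.
#' @return an object of class `threshold_grid`.
#' @export
threshold_grid <- function(thresholds, mode = "manual") {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || any(!is.finite(thresholds))) {
    stop("`thresholds` must be a nonempty finite numeric vector",
         call. = FALSE)
  }
  if (length(thresholds) > 1L && any(diff(thresholds) <= 0)) {
    stop("`thresholds` must be strictly increasing", call. = FALSE)
  }
  structure(list(thresholds = thresholds, K = length(thresholds),
                 mode = mode),
            class = "threshold_grid")
}

#' @rdname threshold_grid
#' @param K number of thresholds to draw.
#' @param range length-2 numeric range to draw from (e.g.
#'   [response_range()]).
#' @param seed integer RNG seed.
#' @export
random_threshold_grid <- function(K, range, seed = NULL) {
  stop_if_not_count(K, "K", 1L)
  stopifnot(length(range) == 2L, all(is.finite(range)), range[1] <= range[2])
  z <- with_seed(seed, sort(stats::runif(K, range[1], range[2])))
  z <- unique(z) # ties have probability zero
  threshold_grid(z, mode = "uniform_random_in_range")
}

#' Threshold-indexed complex-cell signature
#'
#' For each grid threshold `z_k`, counts the simple cells whose raw
#' response exceeds it: `values[k] = sum_i H(w_i' x - z_k)`. This equals
#' `N_cells * (1 - ecdf)` of the response set evaluated at `z_k` (with the
#' closed-at-zero Heaviside), i.e. the complemented, scaled empirical CDF
#' — the statistic that is invariant on orbits and, at full grid
#' resolution, a maximal invariant (see [full_threshold_grid()]).
#'
#' @param bank a [simple_cell_bank()] (the grid overrides the bank's own
#'   threshold; Heaviside semantics are always used here).
#' @param x a single stimulus vector.
#' @param grid a [threshold_grid()].
#' @return an object of class `complex_cell_signature`: list with
#'   `values` (length `K`, nonincreasing, integers in `[0, N_cells]`) and
#'   `thresholds`.
#' @export
signature <- function(bank, x, grid) {
  stopifnot(inherits(grid, "threshold_grid"))
  xm <- check_dim(bank, x)
  if (ncol(xm) != 1L) stop("`x` must be a single stimulus", call. = FALSE)
  r <- sort(as.numeric(crossprod(bank$W, xm)))
  structure(list(values = as.numeric(count_ge(r, grid$thresholds)),
                 thresholds = grid$thresholds),
            class = "complex_cell_signature")
}

#' @export
print.complex_cell_signature <- function(x, ...) {
  cat(sprintf("<complex_cell_signature> K=%d thresholds, values in [%g, %g]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Range of raw simple-cell responses over a stimulus set
#'
#' @param bank a [simple_cell_bank()].
#' @param S stimulus matrix (one stimulus per column) or vector.
#' @return numeric `c(min, max)` of `w_i' x_j` over all cells and stimuli.
#' @export
response_range <- function(bank, S) {
  Sm <- check_dim(bank, S)
  if (ncol(Sm) == 0L) stop("`S` must be nonempty", call. = FALSE)
  range(crossprod(bank$W, Sm))
}

#' "Big fixed negative threshold" for full-range activation
#'
#' Returns `-(1 + max |w_i' x_j|)` over the training set: a Heaviside
#' threshold below every activation, so that all training activations pass
#' and the full range of activations is used.
#'
#' @inheritParams response_range
#' @return a single negative number.
#' @export
big_negative_threshold <- function(bank, S) {
  Sm <- check_dim(bank, S)
  -(1 + max(abs(crossprod(bank$W, Sm))))
}
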