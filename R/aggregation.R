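#' Pooled response of candidate weights to a stimulus set
#'
#' For each candidate weight column `w`, the total nonlinear response
#' `sum_j f(sigma(w' s_j))` over the stimulus set — the quantity the
#' complex-cell wiring rule maximizes. On a stimulus set that is a union
#' of complete orbits, the pooled response is constant on weight orbits.
#'
#' @param candidates `d x n` matrix of candidate weight columns.
#' @param S_new stimulus matrix (`d x M`) or `orbit_dataset`.
#' @param spec a [loss_spec()].
#' @return numeric vector of length `n`.
#' @export
pooled_response <- function(candidates, S_new, spec = loss_spec()) {
  if (inherits(S_new, "orbit_dataset")) S_new <- S_new$S
  m <- check_shapes(candidates, S_new)
  if (ncol(m$W) == 0L || ncol(m$S) == 0L) {
    stop("`candidates` and `S_new` must be nonempty", call. = FALSE)
  }
  rowSums(spec$f_fun(nl_apply(spec$nonlinearity, crossprod(m$W, m$S))))
}

#' Index of the maximally responding candidate
#'
#' The argmax of [pooled_response()] over the candidate pool; ties are
#' broken by the lowest index.
#'
#' @inheritParams pooled_response
#' @return integer index into the candidate columns.
#' @export
select_max_cell <- function(candidates, S_new, spec = loss_spec()) {
  which.max(pooled_response(candidates, S_new, spec))
}

#' Wire a complex cell by iterated maximal-response selection
#'
#' Repeats [select_max_cell()] `group_size` times, each time excluding the
#' already selected candidates and any candidate that is a near duplicate
#' of a selected one (cosine similarity `> 1 - dedup_tol`; elements of the
#' same orbit can be repeatedly sampled without affecting the result, so
#' duplicates are simply skipped). When the stimulus set is a union of
#' complete orbits, the pooled response is constant on weight orbits, so
#' the selection walks through the orbit of the maximally responding
#' template.
#'
#' @inheritParams pooled_response
#' @param group_size number of simple cells to wire (the orbit size `N`).
#' @param dedup_tol cosine-similarity tolerance for duplicate candidates.
#' @param group optional [finite_group()]; when given, the selected
#'   weights are checked with [is_weight_orbit()] at `orbit_tol`.
#' @param orbit_tol tolerance for the orbit check.
#' @return an object of class `aggregation_result`: `selected_weights`
#'   (`d x group_size`, selection order, maximal cell first),
#'   `selected_indices`, `pooled` (their pooled responses), `dedup_count`,
#'   and — when `group` is given — `is_orbit` and `matching` from
#'   [is_weight_orbit()].
#' @export
aggregate_orbit <- function(candidates, S_new, group_size,
                            spec = loss_spec(), dedup_tol = 1e-8,
                            group = NULL, orbit_tol = 1e-8) {
  if (inherits(S_new, "orbit_dataset")) S_new <- S_new$S
  m <- check_shapes(candidates, S_new)
  candidates <- m$W
  stop_if_not_count(group_size, "group_size", 1L)
  n <- ncol(candidates)
  pooled <- pooled_response(candidates, S_new, spec)
  norms <- sqrt(colSums(candidates^2))
  available <- rep(TRUE, n)
  selected <- integer(0)
  dedup_count <- 0L
  for (s in seq_len(group_size)) {
    if (!any(available)) {
      stop(sprintf(
        "candidate pool exhausted after %d selections (need %d distinct)",
        length(selected), group_size), call. = FALSE)
    }
    p <- pooled
    p[!available] <- -Inf
    i <- which.max(p)
    selected <- c(selected, i)
    available[i] <- FALSE
    # drop near-duplicates of the freshly selected weight
    if (norms[i] > 0 && any(available)) {
      cs <- as.numeric(crossprod(candidates, candidates[, i])) /
        (norms * norms[i])
      dup <- available & is.finite(cs) & cs > 1 - dedup_tol
      dedup_count <- dedup_count + sum(dup)
      available[dup] <- FALSE
    }
  }
  out <- list(selected_weights = candidates[, selected, drop = FALSE],
              selected_indices = selected,
              pooled = pooled[selected],
              dedup_count = dedup_count,
              is_orbit = NA, matching = NULL)
  if (!is.null(group) && group_size == group$N) {
    chk <- is_weight_orbit(out$selected_weights, group, tol = orbit_tol)
    out$is_orbit <- chk$is_orbit
    out$matching <- chk$matching
    out$degenerate <- chk$degenerate
  }
  class(out) <- "aggregation_result"
  out
}

#' @export
print.aggregation_result <- function(x, ...) {
  cat(sprintf(
    "<aggregation_result> %d cells selected, dedup_count=%d, is_orbit=%s\n",
    ncol(x$selected_weights), x$dedup_count, x$is_orbit))
  invisible(x)
}

#' Do a set of weights form a group orbit?
#'
#' Takes the first column as the template `w_bar`, computes its orbit, and
#' greedily matches weight columns to orbit columns (globally smallest
#' residual first, each row/column used once). `TRUE` iff the matching is
#' a bijection with every residual `<= tol`. A zero template is flagged
#' `degenerate` (any zero set trivially matches).
#'
#' @param weights `d x N` matrix with exactly `N = group$N` columns.
#' @param group a [finite_group()].
#' @param tol per-column Euclidean residual tolerance.
#' @return list with `is_orbit` (logical), `matching` (data frame:
#'   `column`, `element`, `residual`) and `degenerate`.
#' @export
is_weight_orbit <- function(weights, group, tol = 1e-8) {
  stopifnot(inherits(group, "finite_group"))
  weights <- as_stimulus_matrix(weights)
  N <- group$N
  if (ncol(weights) != N) {
    stop(sprintf("`weights` must have exactly %d columns (got %d)",
                 N, ncol(weights)), call. = FALSE)
  }
  if (nrow(weights) != group$d) {
    stop("weight dimension does not match the group", call. = FALSE)
  }
  wbar <- weights[, 1L]
  orb <- orbit(group, wbar)
  D <- sqrt(pmax(outer(colSums(weights^2), colSums(orb^2), `+`) -
                   2 * crossprod(weights, orb), 0))
  col_used <- logical(N)
  row_used <- logical(N)
  match_el <- integer(N)
  match_res <- numeric(N)
  for (s in seq_len(N)) {
    Dm <- D
    Dm[row_used, ] <- Inf
    Dm[, col_used] <- Inf
    i <- which.min(Dm)
    rc <- arrayInd(i, dim(Dm))
    row_used[rc[1L]] <- TRUE
    col_used[rc[2L]] <- TRUE
    match_el[rc[1L]] <- rc[2L]
    # recompute the residual from the column difference: the expanded
    # quadratic form loses half the digits to cancellation near zero
    match_res[rc[1L]] <- sqrt(sum((weights[, rc[1L]] - orb[, rc[2L]])^2))
  }
  list(is_orbit = all(match_res <= tol),
       matching = data.frame(column = seq_len(N), element = match_el,
                             residual = match_res),
       degenerate = sqrt(sum(wbar^2)) <= tol)
}

#' Invariance residual of a complex cell
#'
#' `max_{g, x} |c(g x) - c(x)|` over the group elements and a set of test
#' points, where `c` is the complex-cell response of the bank. For a bank
#' whose weights form an orbit of a permutation group with a Heaviside
#' nonlinearity the residual is exactly 0 for generic thresholds; for
#' rotation groups it is bounded by trigonometric round-off.
#'
#' @param bank a [simple_cell_bank()] or an `aggregation_result` (whose
#'   selected weights are then used with `nonlinearity`).
#' @param group a [finite_group()].
#' @param test_points `d x n` matrix of test stimuli.
#' @param nonlinearity nonlinearity to use when `bank` is an
#'   `aggregation_result` (default [heaviside()] at 0).
#' @return the worst-case absolute response difference (scalar).
#' @export
invariance_residual <- function(bank, group, test_points,
                                nonlinearity = heaviside(0)) {
  if (inherits(bank, "aggregation_result")) {
    bank <- simple_cell_bank(bank$selected_weights, nonlinearity)
  }
  stopifnot(inherits(bank, "simple_cell_bank"),
            inherits(group, "finite_group"))
  test_points <- as_stimulus_matrix(test_points)
  c0 <- complex_response(bank, test_points)
  max(vapply(group$elements, function(g) {
    max(abs(complex_response(bank, g %*% test_points) - c0))
  }, numeric(1)))
}
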