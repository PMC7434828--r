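#' Specification of the unsupervised response loss
#'
#' The loss class is `L(W, S) = sum_{i,j} f(sigma(w_i' x_j))` for a
#' nonnegative Lipschitz map `f` applied to the nonlinear response of every
#' cell to every stimulus. `f = square` recovers the squared Frobenius norm
#' `||sigma(W'S)||_F^2` (see [frobenius_response_norm()]); Hebbian, Oja,
#' Foldiak and ICA-style rules are members of this class.
#'
#' @param f scalar map: `"square"` (default), `"abs"`, or `"huber"`.
#' @param delta Huber transition point (only for `f = "huber"`).
#' @param nonlinearity a nonlinearity spec; gradients require the
#'   [logistic_surrogate()].
#' @return an object of class `loss_spec` with fields `f`, `f_fun`,
#'   `f_grad`, `nonlinearity`.
#' @export
loss_spec <- function(f = c("square", "abs", "huber"), delta = 1,
                      nonlinearity = logistic_surrogate()) {
  f <- match.arg(f)
  stopifnot(inherits(nonlinearity, "nonlinearity"))
  if (f == "huber" && (!is.numeric(delta) || delta <= 0)) {
    stop("`delta` must be positive for the Huber loss", call. = FALSE)
  }
  fns <- switch(f,
    square = list(fun = function(u) u^2, grad = function(u) 2 * u),
    abs = list(fun = function(u) abs(u), grad = function(u) sign(u)),
    huber = list(
      fun = function(u) ifelse(abs(u) <= delta, 0.5 * u^2,
                               delta * (abs(u) - 0.5 * delta)),
      grad = function(u) ifelse(abs(u) <= delta, u, delta * sign(u))
    )
  )
  structure(list(f = f, delta = delta, f_fun = fns$fun, f_grad = fns$grad,
                 nonlinearity = nonlinearity),
            class = "loss_spec")
}

check_shapes <- function(W, S) {
  W <- as_stimulus_matrix(W)
  S <- as_stimulus_matrix(S)
  if (nrow(W) != nrow(S)) {
    stop(sprintf("weights (d=%d) and stimuli (d=%d) dimension mismatch",
                 nrow(W), nrow(S)), call. = FALSE)
  }
  list(W = W, S = S)
}

#' Unsupervised response loss
#'
#' `L(W, S) = sum_{i,j} f(sigma(w_i' x_j))`, a nonnegative scalar.
#'
#' @param W `d x N_cells` weight matrix.
#' @param S `d x R` stimulus matrix.
#' @param spec a [loss_spec()].
#' @return a nonnegative scalar.
#' @export
unsup_loss <- function(W, S, spec = loss_spec()) {
  m <- check_shapes(W, S)
  sum(spec$f_fun(nl_apply(spec$nonlinearity, crossprod(m$W, m$S))))
}

#' Squared Frobenius norm of the nonlinear response matrix
#'
#' `||sigma(W'S)||_F^2` — the matrix form of the square-loss member of the
#' loss class, computed via `norm(, "F")` as an algebraically independent
#' route to the same number as [unsup_loss()] with `f = "square"`.
#'
#' @inheritParams unsup_loss
#' @param nonlinearity nonlinearity applied entrywise to `W'S`.
#' @return a nonnegative scalar.
#' @export
frobenius_response_norm <- function(W, S, nonlinearity = logistic_surrogate()) {
  m <- check_shapes(W, S)
  norm(nl_apply(nonlinearity, crossprod(m$W, m$S)), type = "F")^2
}

#' Gradient of the unsupervised loss
#'
#' Column `i` is `sum_j f'(sigma(w_i' x_j)) sigma'(w_i' x_j) x_j` — the
#' Hebbian-family update direction for cell `i`. Requires a differentiable
#' (surrogate) nonlinearity.
#'
#' @inheritParams unsup_loss
#' @return a matrix of the same shape as `W`.
#' @export
unsup_grad <- function(W, S, spec = loss_spec()) {
  m <- check_shapes(W, S)
  A <- crossprod(m$W, m$S)                      # N_cells x R raw responses
  P <- nl_apply(spec$nonlinearity, A)
  M <- spec$f_grad(P) * nl_deriv(spec$nonlinearity, A)
  m$S %*% t(M)
}

#' Is a stimulus set a union of complete group orbits?
#'
#' Checks that for every group element `g`, the columns of `g S` match the
#' columns of `S` as a multiset (greedy nearest matching within `tol`).
#' This is the hypothesis under which the solution-space equivariance of
#' the learning dynamics holds.
#'
#' @param S `d x R` stimulus matrix or an `orbit_dataset`.
#' @param group a [finite_group()].
#' @param tol per-column Euclidean matching tolerance.
#' @return logical.
#' @export
is_orbit_complete <- function(S, group, tol = 1e-8) {
  if (inherits(S, "orbit_dataset")) S <- S$S
  S <- as_stimulus_matrix(S)
  stopifnot(inherits(group, "finite_group"), nrow(S) == group$d)
  R <- ncol(S)
  n2 <- colSums(S^2)
  for (g in group$elements) {
    M <- g %*% S
    D2 <- outer(colSums(M^2), n2, `+`) - 2 * crossprod(M, S)
    used <- logical(R)
    for (j in seq_len(R)) {
      row <- D2[j, ]
      row[used] <- Inf
      i <- which.min(row)
      # exact recheck on the matched column: the expanded quadratic form
      # has cancellation error ~sqrt(eps) near zero
      if (sqrt(sum((M[, j] - S[, i])^2)) > tol) return(FALSE)
      used[i] <- TRUE
    }
  }
  TRUE
}

#' Equivariance residual of the learning dynamics
#'
#' On a stimulus set that is a union of complete orbits, the loss gradient
#' is equivariant: `grad(gW, S) = g grad(W, S)` for every group element,
#' so the orbit of any solution of the weight dynamics is itself a set of
#' solutions. This function measures the worst-case violation,
#' `max_{g,i} || grad(gW,S)[,i] - g grad(W,S)[,i] ||_2`.
#'
#' @param W `d x N_cells` weight matrix.
#' @param S stimulus matrix or `orbit_dataset`.
#' @param group a [finite_group()].
#' @param spec a [loss_spec()] with a differentiable nonlinearity.
#' @param check_complete verify the orbit-completeness hypothesis; when
#'   violated the result carries `orbit_complete = FALSE` (the theorem's
#'   hypothesis does not hold and the residual is typically large).
#' @return list with `residual` (max over elements and cells),
#'   `per_element` (residual per group element) and `orbit_complete`.
#' @export
gradient_equivariance_residual <- function(W, S, group, spec = loss_spec(),
                                           check_complete = TRUE) {
  if (inherits(S, "orbit_dataset")) S <- S$S
  m <- check_shapes(W, S)
  stopifnot(inherits(group, "finite_group"), nrow(m$W) == group$d)
  complete <- if (check_complete) is_orbit_complete(m$S, group) else NA
  G0 <- unsup_grad(m$W, m$S, spec)
  per <- vapply(group$elements, function(g) {
    G1 <- unsup_grad(g %*% m$W, m$S, spec)
    max(sqrt(colSums((G1 - g %*% G0)^2)))
  }, numeric(1))
  if (isFALSE(complete)) {
    warning("stimulus set is not a union of complete orbits; ",
            "the equivariance hypothesis is violated", call. = FALSE)
  }
  list(residual = max(per), per_element = per, orbit_complete = complete)
}

#' Train a bank of simple cells by unsupervised gradient ascent
#'
#' Full-batch gradient ascent on [unsup_loss()] with backtracking step
#' halving, so the loss trace is nondecreasing. Each epoch visits the
#' whole stimulus set once; with an orbit-complete stimulus set of `Q`
#' orbits every epoch checkpoint therefore lands after a multiple of
#' `|G| * Q` stimulus presentations, the schedule under which the
#' solution-space equivariance holds. Ascent (Hebbian potentiation) is
#' used because the experimental protocol maximizes the same response
#' objective.
#'
#' @param S stimulus matrix (`d x R`) or an `orbit_dataset`.
#' @param n_cells number of simple cells (defaults to the orbit size when
#'   `S` is an `orbit_dataset`).
#' @param spec a [loss_spec()] with a differentiable nonlinearity.
#' @param alpha base learning rate (halved within an epoch until the loss
#'   does not decrease).
#' @param epochs number of full passes.
#' @param seed RNG seed for the weight initialization.
#' @param init `"gaussian"` (sd `1e-2/sqrt(d)`, the default) or `"zero"`.
#' @param group optional [finite_group()]; when given, the equivariance
#'   residual is logged at every epoch checkpoint.
#' @return an object of class `train_state`: `W` (final weights), `t`
#'   (stimulus presentations performed), `alpha`, `loss_trace` (length
#'   `epochs + 1`, including the initial loss), `equivariance_trace`
#'   (when `group` is given) and `seed`.
#' @export
train_simple_cells <- function(S, n_cells = NULL, spec = loss_spec(),
                               alpha = 0.01, epochs = 10, seed = NULL,
                               init = c("gaussian", "zero"), group = NULL) {
  init <- match.arg(init)
  if (inherits(S, "orbit_dataset")) {
    if (is.null(group)) group <- S$group
    if (is.null(n_cells)) n_cells <- S$N
    S <- S$S
  }
  S <- as_stimulus_matrix(S)
  stop_if_not_count(epochs, "epochs", 1L)
  if (is.null(n_cells)) stop("`n_cells` must be given for a plain matrix",
                             call. = FALSE)
  stop_if_not_count(n_cells, "n_cells", 1L)
  if (!is.numeric(alpha) || alpha <= 0) {
    stop("`alpha` must be positive", call. = FALSE)
  }
  d <- nrow(S)
  W <- if (init == "zero") {
    matrix(0, d, n_cells)
  } else {
    with_seed(seed, matrix(stats::rnorm(d * n_cells, sd = 1e-2 / sqrt(d)),
                           d, n_cells))
  }
  cur <- unsup_loss(W, S, spec)
  loss_trace <- numeric(epochs + 1L)
  loss_trace[1L] <- cur
  eq_trace <- if (!is.null(group)) numeric(epochs) else NULL
  for (ep in seq_len(epochs)) {
    G <- unsup_grad(W, S, spec)
    step <- alpha
    repeat {
      W2 <- W + step * G
      nxt <- unsup_loss(W2, S, spec)
      if (!is.finite(nxt)) {
        stop(sprintf("training diverged at epoch %d", ep), call. = FALSE)
      }
      if (nxt >= cur) break
      step <- step / 2
      if (step < 1e-14) { W2 <- W; nxt <- cur; break }
    }
    W <- W2
    cur <- nxt
    loss_trace[ep + 1L] <- cur
    if (!is.null(group)) {
      eq_trace[ep] <- gradient_equivariance_residual(
        W, S, group, spec, check_complete = FALSE)$residual
    }
  }
  structure(
    list(W = W, t = epochs * ncol(S), alpha = alpha,
         loss_trace = loss_trace, equivariance_trace = eq_trace,
         seed = seed),
    class = "train_state"
  )
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf(
    "<train_state> %d cells in R^%d, %d presentations, loss %.4g -> %.4g\n",
    ncol(x$W), nrow(x$W), x$t, x$loss_trace[1L],
    x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

# QR retraction onto the orthonormal frame, with the sign of diag(R) fixed
# so the retraction is deterministic and continuous.
qr_retract <- function(M) {
  qd <- qr(M)
  Q <- qr.Q(qd)
  s <- sign(diag(qr.R(qd)))
  s[s == 0] <- 1
  Q * rep(s, each = nrow(Q))
}

#' Orthogonality-constrained response maximization
#'
#' Solves the two-term response-energy problem
#' `max_U  ||sigma(U'S)||_F^2 + lambda ||sigma(U'S_new)||_F^2` subject to
#' the Stiefel constraint `U'U = Id`, by projected gradient ascent with a
#' QR retraction and backtracking step halving (objective nondecreasing by
#' construction). `n_cells <= d` is required — no orthonormal frame with
#' more columns than rows exists.
#'
#' @param S training stimulus matrix (`d x R`) or `orbit_dataset`.
#' @param S_new new-stimulus matrix or `orbit_dataset` (second phase);
#'   `NULL` drops the second term.
#' @param lambda nonnegative weight of the `S_new` term.
#' @param n_cells number of orthonormal columns to learn.
#' @param spec a [loss_spec()] with a differentiable nonlinearity.
#' @param alpha base step size.
#' @param max_iter iteration cap.
#' @param tol relative-improvement stopping tolerance.
#' @param seed RNG seed for the random orthonormal initialization.
#' @param init optional `d x n_cells` starting matrix (retracted before
#'   use).
#' @return an object of class `stiefel_fit`: `U` (with
#'   `max |U'U - I| <= 1e-8`), `objective` (trace, nondecreasing),
#'   `ortho_residual`, `iterations`, `converged`.
#' @export
constrained_maximize <- function(S, S_new = NULL, lambda = 1, n_cells,
                                 spec = loss_spec(), alpha = 0.05,
                                 max_iter = 300, tol = 1e-9, seed = NULL,
                                 init = NULL) {
  if (inherits(S, "orbit_dataset")) S <- S$S
  if (inherits(S_new, "orbit_dataset")) S_new <- S_new$S
  S <- as_stimulus_matrix(S)
  d <- nrow(S)
  stop_if_not_count(n_cells, "n_cells", 1L)
  if (n_cells > d) {
    stop(sprintf(
      "n_cells = %d exceeds d = %d: no orthonormal frame exists",
      n_cells, d), call. = FALSE)
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("`lambda` must be a single nonnegative number", call. = FALSE)
  }
  objective <- function(U) {
    o <- unsup_loss(U, S, spec)
    if (!is.null(S_new) && lambda > 0) {
      o <- o + lambda * unsup_loss(U, S_new, spec)
    }
    o
  }
  gradient <- function(U) {
    G <- unsup_grad(U, S, spec)
    if (!is.null(S_new) && lambda > 0) {
      G <- G + lambda * unsup_grad(U, S_new, spec)
    }
    G
  }
  U <- if (is.null(init)) {
    with_seed(seed, matrix(stats::rnorm(d * n_cells), d, n_cells))
  } else {
    as_stimulus_matrix(init)
  }
  U <- qr_retract(U)
  cur <- objective(U)
  trace <- cur
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    G <- gradient(U)
    step <- alpha
    accepted <- FALSE
    repeat {
      U2 <- qr_retract(U + step * G)
      nxt <- objective(U2)
      if (!is.finite(nxt)) {
        stop(sprintf("maximization diverged at iteration %d", it),
             call. = FALSE)
      }
      if (nxt >= cur) { accepted <- TRUE; break }
      step <- step / 2
      if (step < 1e-14) break
    }
    if (!accepted) { converged <- TRUE; break }
    improved <- nxt - cur
    U <- U2
    cur <- nxt
    trace <- c(trace, cur)
    if (improved <= tol * max(1, abs(cur))) { converged <- TRUE; break }
  }
  structure(
    list(U = U, objective = trace,
         ortho_residual = max(abs(crossprod(U) - diag(n_cells))),
         iterations = length(trace) - 1L, converged = converged,
         seed = seed),
    class = "stiefel_fit"
  )
}

#' @export
print.stiefel_fit <- function(x, ...) {
  cat(sprintf(
    "<stiefel_fit> %d x %d frame, %d iterations, objective %.6g, ortho %.1e\n",
    nrow(x$U), ncol(x$U), x$iterations, x$objective[length(x$objective)],
    x$ortho_residual))
  invisible(x)
}
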