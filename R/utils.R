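`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds it with `seed`, evaluates `code`,
#' and restores the previous state on exit. `seed = NULL` leaves the RNG
#' untouched.
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  code
}

# Coerce a vector or matrix of stimuli to a d x n matrix (columns = stimuli).
as_stimulus_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Number of sorted responses >= z, with a closed-at-zero Heaviside
# convention H(t) = 1 iff t >= 0. `r_sorted` must be ascending.
count_ge <- function(r_sorted, z) {
  length(r_sorted) - findInterval(z, r_sorted, left.open = TRUE)
}
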