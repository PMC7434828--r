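# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so the suite is deterministic.

unit_vec <- function(d, seed) {
  v <- sample_base_points(1, d, seed = seed)[, 1]
  v / sqrt(sum(v^2))
}

rand_W <- function(d, n, seed) {
  with_local_seed(seed, matrix(stats::rnorm(d * n), d, n))
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Brute-force double-loop oracle for the elementwise response loss.
loss_oracle <- function(W, S, f, nl) {
  total <- 0
  for (i in seq_len(ncol(W))) {
    for (j in seq_len(ncol(S))) {
      a <- sum(W[, i] * S[, j])
      u <- if (nl$kind == "heaviside") {
        as.numeric(a - nl$z >= 0)
      } else {
        stats::plogis(nl$beta * (a - nl$z))
      }
      total <- total + f(u)
    }
  }
  total
}

# Brute-force counting oracle for the threshold signature.
signature_oracle <- function(W, x, thresholds) {
  r <- as.numeric(t(W) %*% x)
  vapply(thresholds, function(z) sum(r - z >= 0), numeric(1))
}
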