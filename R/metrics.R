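#' Distance between threshold signatures of two stimuli
#'
#' `|| c(x) - c(y) ||` over a shared threshold grid, in the l1 form
#' `sum_z |c_z(x) - c_z(y)|` or the l2 form. The distance is zero for any
#' shared grid whenever `x` and `y` lie in the same orbit of a permutation
#' group and the bank's weights form an orbit; at full grid resolution
#' (see [full_threshold_grid()]) it is zero only then.
#'
#' @param x,y stimulus vectors.
#' @param bank a [simple_cell_bank()].
#' @param grid a shared [threshold_grid()].
#' @param norm `"l1"` (default, the experimental form) or `"l2"`.
#' @param collapsed if `TRUE`, collapse each signature to the scalar
#'   `sum_z c_z` before differencing (the scalar variant of the
#'   finite-threshold code), and return its absolute difference.
#' @return a nonnegative scalar.
#' @export
signature_distance <- function(x, y, bank, grid, norm = c("l1", "l2"),
                               collapsed = FALSE) {
  norm <- match.arg(norm)
  s1 <- signature(bank, x, grid)$values
  s2 <- signature(bank, y, grid)$values
  if (collapsed) return(abs(sum(s1) - sum(s2)))
  if (norm == "l1") sum(abs(s1 - s2)) else sqrt(sum((s1 - s2)^2))
}

#' Full (maximally selective) threshold grid
#'
#' Midpoints between consecutive distinct observed raw responses of the
#' bank over `points`, plus one flanking threshold below the minimum and
#' one above the maximum. Signatures over this grid determine the response
#' multisets exactly, so [signature_distance()] over it is zero iff the
#' sorted response vectors of the two stimuli coincide — the finite
#' realization of the continuous-threshold maximal invariant.
#'
#' @param bank a [simple_cell_bank()].
#' @param points stimulus matrix (typically the stimuli to be compared).
#' @param collapse_tol responses closer than this are treated as one
#'   observed value.
#' @return a [threshold_grid()] with mode
#'   `"full_grid_of_observed_responses"`.
#' @export
full_threshold_grid <- function(bank, points, collapse_tol = 1e-9) {
  pm <- check_dim(bank, points)
  if (ncol(pm) == 0L) stop("`points` must be nonempty", call. = FALSE)
  r <- sort(as.numeric(crossprod(bank$W, pm)))
  r <- r[c(TRUE, diff(r) > collapse_tol)]
  m <- length(r)
  if (m == 1L) {
    z <- c(r - 0.5, r + 0.5)
  } else {
    flank <- mean(diff(r)) / 2
    z <- c(r[1L] - flank, (r[-m] + r[-1L]) / 2, r[m] + flank)
  }
  threshold_grid(z, mode = "full_grid_of_observed_responses")
}

#' Intra- vs inter-orbit signature distance report
#'
#' Samples `n_pairs` same-orbit pairs and `n_pairs` cross-orbit pairs of
#' stimuli from the dataset and computes their signature distances. With
#' `grid = "full"` each pair uses its own full midpoint grid (maximal
#' selectivity, the Lemma regime); a fixed [threshold_grid()] — e.g. 10
#' random thresholds — reproduces the finite-threshold experimental
#' regime.
#'
#' @param dataset an `orbit_dataset` with at least 2 orbits.
#' @param bank a [simple_cell_bank()].
#' @param grid `"full"` or a shared [threshold_grid()].
#' @param n_pairs pairs per class; `0` gives an empty report.
#' @param seed integer RNG seed for the pair sampling.
#' @param norm distance norm, `"l1"` or `"l2"`.
#' @return an object of class `distance_report`: numeric vectors `intra`
#'   and `inter`, plus `n_pairs`, `norm`, `grid_mode`, `seed`.
#' @export
distance_report <- function(dataset, bank, grid = "full", n_pairs = 200,
                            seed = NULL, norm = c("l1", "l2")) {
  norm <- match.arg(norm)
  stopifnot(inherits(dataset, "orbit_dataset"))
  stop_if_not_count(n_pairs + 1L, "n_pairs + 1", 1L) # n_pairs >= 0
  if (dataset$Q < 2L) {
    stop("the dataset must contain at least 2 orbits", call. = FALSE)
  }
  per_orbit <- split(seq_along(dataset$orbit_label), dataset$orbit_label)
  multi <- which(lengths(per_orbit) >= 2L)
  if (n_pairs > 0L && length(multi) == 0L) {
    stop("no orbit has >= 2 stimuli; cannot sample intra-orbit pairs",
         call. = FALSE)
  }
  grid_mode <- if (identical(grid, "full")) "full" else "fixed"
  if (grid_mode == "fixed") stopifnot(inherits(grid, "threshold_grid"))
  pair_dist <- function(i, j) {
    x <- dataset$S[, i]
    y <- dataset$S[, j]
    g <- if (grid_mode == "full") {
      full_threshold_grid(bank, cbind(x, y))
    } else {
      grid
    }
    signature_distance(x, y, bank, g, norm = norm)
  }
  res <- with_seed(seed, {
    intra <- vapply(seq_len(n_pairs), function(k) {
      q <- multi[[sample.int(length(multi), 1L)]]
      ij <- sample(per_orbit[[q]], 2L)
      pair_dist(ij[1L], ij[2L])
    }, numeric(1))
    inter <- vapply(seq_len(n_pairs), function(k) {
      qq <- sample.int(dataset$Q, 2L)
      i <- per_orbit[[qq[1L]]][sample.int(length(per_orbit[[qq[1L]]]), 1L)]
      j <- per_orbit[[qq[2L]]][sample.int(length(per_orbit[[qq[2L]]]), 1L)]
      pair_dist(i, j)
    }, numeric(1))
    list(intra = intra, inter = inter)
  })
  structure(
    list(intra = res$intra, inter = res$inter, n_pairs = n_pairs,
         norm = norm, grid_mode = grid_mode, seed = seed),
    class = "distance_report"
  )
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf(
    paste0("<distance_report> %d pairs/class (%s norm, %s grid)\n",
           "  intra: median %.4g  max %.4g\n",
           "  inter: median %.4g  min %.4g\n  overlap: %.3f\n"),
    x$n_pairs, x$norm, x$grid_mode,
    stats::median(x$intra), max(x$intra),
    stats::median(x$inter), min(x$inter), overlap_fraction(x)))
  invisible(x)
}

#' Histogram overlap of intra- and inter-orbit log distances
#'
#' The overlap coefficient `sum_b min(p_intra(b), p_inter(b))` of the two
#' log10-distance histograms over a common set of bins, with a floor of
#' `1e-12` applied before taking logs (intra distances are exactly zero in
#' the ideal setting). 0 = perfectly separated distributions, 1 =
#' identical.
#'
#' @param report a [distance_report()].
#' @param n_bins number of common histogram bins.
#' @param floor additive-free lower clamp applied before `log10`.
#' @return a scalar in `[0, 1]` (`NA` for empty reports).
#' @export
overlap_fraction <- function(report, n_bins = 30, floor = 1e-12) {
  stopifnot(inherits(report, "distance_report"))
  if (length(report$intra) == 0L || length(report$inter) == 0L) {
    return(NA_real_)
  }
  li <- log10(pmax(report$intra, floor))
  le <- log10(pmax(report$inter, floor))
  rng <- range(c(li, le))
  if (diff(rng) == 0) return(1)
  breaks <- seq(rng[1L] - 1e-9, rng[2L] + 1e-9, length.out = n_bins + 1L)
  pi_ <- tabulate(findInterval(li, breaks, all.inside = TRUE), n_bins) /
    length(li)
  pe_ <- tabulate(findInterval(le, breaks, all.inside = TRUE), n_bins) /
    length(le)
  sum(pmin(pi_, pe_))
}

#' Cosine similarity of signatures vs number of random thresholds
#'
#' For each `K` in `K_list`, draws `reps` random threshold grids of size
#' `K` (uniform in `range`, by default the shared response range of `x`
#' and `y`), computes the cosine similarity between the two signatures,
#' and averages. A draw under which one stimulus has an all-zero code (no
#' cell fires at any sampled threshold) conveys no agreement: with
#' `zero_handling = "zero"` (default) it contributes similarity 0, which
#' is what makes the mean similarity grow with `K` toward its plateau
#' (the empty-code probability vanishes as the grid fills in);
#' `"missing"` drops such draws instead. `K = 1` is degenerate (the
#' cosine of two positive scalar counts is identically 1) and is excluded
#' from the default grid.
#'
#' @param x,y stimulus vectors (generically from different orbits).
#' @param bank a [simple_cell_bank()].
#' @param K_list increasing vector of threshold counts.
#' @param reps random grids per `K`.
#' @param seed integer RNG seed.
#' @param range length-2 threshold sampling range; `NULL` (default) uses
#'   the shared response range of the pair. Experiment evaluations pass
#'   the response range over the whole stimulus ensemble.
#' @param zero_handling treatment of draws with an all-zero code:
#'   `"zero"` (similarity 0) or `"missing"` (dropped).
#' @return a data frame (class `cosine_curve`) with columns `K`,
#'   `mean_cosine`, `n_valid` (draws with both codes nonzero); attributes
#'   `spearman` (rank correlation of `mean_cosine` with `K`) and
#'   `plateau_gap` (`|mean(K_max) - mean(K closest to K_max/2)|`).
#' @export
cosine_similarity_curve <- function(x, y, bank,
                                    K_list = c(2, 3, 5, 10, 25, 50, 100, 200),
                                    reps = 100, seed = NULL, range = NULL,
                                    zero_handling = c("zero", "missing")) {
  zero_handling <- match.arg(zero_handling)
  K_list <- as.integer(K_list)
  stopifnot(length(K_list) >= 2L, all(K_list >= 1L), !is.unsorted(K_list))
  rng <- if (is.null(range)) {
    response_range(bank, cbind(as.numeric(x), as.numeric(y)))
  } else {
    stopifnot(length(range) == 2L, range[1L] <= range[2L])
    range
  }
  rx <- sort(as.numeric(crossprod(bank$W, as.numeric(x))))
  ry <- sort(as.numeric(crossprod(bank$W, as.numeric(y))))
  out <- with_seed(seed, {
    do.call(rbind, lapply(K_list, function(K) {
      sims <- vapply(seq_len(reps), function(r) {
        z <- stats::runif(K, rng[1L], rng[2L])
        s1 <- count_ge(rx, sort(z))
        s2 <- count_ge(ry, sort(z))
        n1 <- sqrt(sum(s1^2))
        n2 <- sqrt(sum(s2^2))
        if (n1 == 0 || n2 == 0) return(NA_real_)
        sum(s1 * s2) / (n1 * n2)
      }, numeric(1))
      mc <- if (zero_handling == "zero") {
        mean(ifelse(is.na(sims), 0, sims))
      } else {
        mean(sims, na.rm = TRUE)
      }
      data.frame(K = K, mean_cosine = mc, n_valid = sum(!is.na(sims)))
    }))
  })
  ok <- is.finite(out$mean_cosine)
  attr(out, "spearman") <- if (sum(ok) >= 2L) {
    stats::cor(out$K[ok], out$mean_cosine[ok], method = "spearman")
  } else {
    NA_real_
  }
  k_max <- max(K_list)
  k_half <- K_list[which.min(abs(K_list - k_max / 2))]
  attr(out, "plateau_gap") <- abs(
    out$mean_cosine[out$K == k_max] - out$mean_cosine[out$K == k_half])
  class(out) <- c("cosine_curve", "data.frame")
  out
}

#' Pair-averaged cosine-similarity curve over a dataset
#'
#' [cosine_similarity_curve()] for a single stimulus pair is dominated by
#' sampling noise (the curve is nearly flat); the trend the experiments
#' measure emerges after averaging over many cross-orbit pairs, as in the
#' large-test-set protocol. This samples `n_pairs` cross-orbit pairs from
#' the dataset, averages their per-K mean cosine similarities, and
#' reports the trend statistics of the averaged curve.
#'
#' @param dataset an `orbit_dataset` with at least 2 orbits.
#' @param bank a [simple_cell_bank()].
#' @param K_list increasing vector of threshold counts (`K >= 2`; very
#'   small `K` is dominated by the positive-cone bias of count vectors).
#' @param n_pairs number of cross-orbit pairs to average over.
#' @param reps random grids per `K` per pair.
#' @param seed integer RNG seed.
#' @param zero_handling see [cosine_similarity_curve()].
#' @return a data frame (class `cosine_curve`) with columns `K`,
#'   `mean_cosine`, `n_valid`, and attributes `spearman` and
#'   `plateau_gap` as in [cosine_similarity_curve()].
#' @export
cosine_curve_report <- function(dataset, bank,
                                K_list = c(5, 10, 25, 50, 100, 200),
                                n_pairs = 30, reps = 50, seed = NULL,
                                zero_handling = c("zero", "missing")) {
  zero_handling <- match.arg(zero_handling)
  stopifnot(inherits(dataset, "orbit_dataset"), dataset$Q >= 2L)
  stop_if_not_count(n_pairs, "n_pairs", 1L)
  rng <- response_range(bank, dataset$S) # ensemble-wide threshold range
  per_orbit <- split(seq_along(dataset$orbit_label), dataset$orbit_label)
  curves <- with_seed(seed, {
    lapply(seq_len(n_pairs), function(p) {
      qq <- sample.int(dataset$Q, 2L)
      i <- per_orbit[[qq[1L]]][sample.int(length(per_orbit[[qq[1L]]]), 1L)]
      j <- per_orbit[[qq[2L]]][sample.int(length(per_orbit[[qq[2L]]]), 1L)]
      pair_seed <- sample.int(.Machine$integer.max, 1L)
      cosine_similarity_curve(dataset$S[, i], dataset$S[, j], bank,
                              K_list = K_list, reps = reps,
                              seed = pair_seed, range = rng,
                              zero_handling = zero_handling)
    })
  })
  mc <- rowMeans(vapply(curves, function(cv) cv$mean_cosine,
                        numeric(length(K_list))), na.rm = TRUE)
  out <- data.frame(K = as.integer(K_list), mean_cosine = mc,
                    n_valid = rowSums(vapply(curves, function(cv) cv$n_valid,
                                             numeric(length(K_list)))))
  ok <- is.finite(out$mean_cosine)
  attr(out, "spearman") <- if (sum(ok) >= 2L) {
    stats::cor(out$K[ok], out$mean_cosine[ok], method = "spearman")
  } else {
    NA_real_
  }
  k_max <- max(K_list)
  k_half <- K_list[which.min(abs(K_list - k_max / 2))]
  attr(out, "plateau_gap") <- abs(
    out$mean_cosine[out$K == k_max] - out$mean_cosine[out$K == k_half])
  class(out) <- c("cosine_curve", "data.frame")
  out
}

#' Hoeffding bound for the finite-threshold distance estimate
#'
#' The concentration bound `2 exp(-Q eps^2 / (2 p))` with the range
#' constant `p = range_width^2 / 4`, bounding the probability that a mean
#' of `Q` i.i.d. threshold draws of a `[0, range_width]`-valued summand
#' deviates from its expectation by more than `eps`.
#'
#' @param Q number of sampled thresholds.
#' @param eps deviation.
#' @param range_width width of the summand's range (1 for the normalized
#'   per-threshold distance).
#' @return a value in `(0, 2]`, decreasing in `Q` and `eps`.
#' @export
hoeffding_bound <- function(Q, eps, range_width = 1) {
  if (any(c(Q, eps, range_width) <= 0) ||
      any(!is.finite(c(Q, eps, range_width)))) {
    stop("`Q`, `eps` and `range_width` must be positive and finite",
         call. = FALSE)
  }
  2 * exp(-Q * eps^2 / (2 * (range_width^2 / 4)))
}

#' Monte-Carlo coverage of the Hoeffding bound
#'
#' For a fixed stimulus pair, the per-threshold summand is the normalized
#' signature difference `d(z) = |c_z(x) - c_z(y)| / N_cells` in `[0, 1]`,
#' with `z` uniform in the shared response range. The exact distance
#' `dist = E_z d(z)` is computed in closed form (d is piecewise constant
#' between observed responses), and the `Q`-threshold estimate
#' `dist_hat = mean_q d(z_q)` is simulated `n_draws` times; the empirical
#' frequency of `|dist_hat - dist| > eps` is compared with
#' [hoeffding_bound()].
#'
#' @param x,y stimulus vectors.
#' @param bank a [simple_cell_bank()].
#' @param Q_values vector of threshold counts.
#' @param eps_values vector of deviations.
#' @param n_draws Monte-Carlo replicates per configuration.
#' @param seed integer RNG seed.
#' @return data frame with columns `Q`, `eps`, `empirical` (violation
#'   frequency), `bound`, and `dist_exact` as an attribute.
#' @export
hoeffding_coverage <- function(x, y, bank, Q_values = c(10, 50, 200),
                               eps_values = c(0.05, 0.1), n_draws = 10000,
                               seed = NULL) {
  stop_if_not_count(n_draws, "n_draws", 1L)
  nc <- ncol(bank$W)
  rx <- sort(as.numeric(crossprod(bank$W, as.numeric(x))))
  ry <- sort(as.numeric(crossprod(bank$W, as.numeric(y))))
  b <- sort(unique(c(rx, ry)))
  lo <- b[1L]
  hi <- b[length(b)]
  if (hi <= lo) {
    stop("degenerate response range; cannot sample thresholds",
         call. = FALSE)
  }
  d_of_z <- function(z) {
    abs(count_ge(rx, z) - count_ge(ry, z)) / nc
  }
  # d(z) is constant on each interval (b_k, b_{k+1}]; integrate exactly.
  mids <- (b[-length(b)] + b[-1L]) / 2
  seg <- diff(b)
  dist_exact <- sum(d_of_z(mids) * seg) / (hi - lo)
  rows <- with_seed(seed, {
    do.call(rbind, lapply(Q_values, function(Q) {
      z <- matrix(stats::runif(n_draws * Q, lo, hi), n_draws, Q)
      dv <- matrix(d_of_z(as.numeric(z)), n_draws, Q)
      dist_hat <- rowMeans(dv)
      do.call(rbind, lapply(eps_values, function(eps) {
        data.frame(Q = Q, eps = eps,
                   empirical = mean(abs(dist_hat - dist_exact) > eps),
                   bound = hoeffding_bound(Q, eps, range_width = 1))
      }))
    }))
  })
  attr(rows, "dist_exact") <- dist_exact
  rows
}
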