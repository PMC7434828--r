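#' Configuration for a scripted orbit-pooling experiment
#'
#' Bundles the protocol sizes and learning settings of the three scripted
#' experiments: `"cyclic"` (cyclic permutation group on `R^6`),
#' `"dihedral"` (dihedral group of order 12 on `R^6`), and `"patch"`
#' (synthetic rotated patches of radius 10 with 6 rotation angles on a
#' polar grid). Protocol defaults: 100 training orbits, 2 new orbits for
#' the aggregation phase, a 1000-orbit test set, 10 random thresholds for
#' the finite-threshold code.
#'
#' @param kind `"cyclic"`, `"dihedral"` or `"patch"`.
#' @param seed root RNG seed; every stage derives its own stream from it.
#' @param Q_train,Q_new,Q_test orbit counts for the training, new-input
#'   and test sets.
#' @param d ambient dimension for the toy groups.
#' @param radius,n_angles,smoothness patch-generator settings (see
#'   [make_toy_patches()]).
#' @param n_thresholds random thresholds for the finite-threshold code.
#' @param n_threshold_draws independent threshold draws over which the
#'   finite-threshold overlap statistic is averaged.
#' @param n_pairs sampled pairs per class in distance reports.
#' @param lambda,beta,alpha,max_iter learning settings for
#'   [constrained_maximize()] (logistic surrogate steepness `beta`,
#'   training threshold 0).
#' @param curve_K,curve_reps,curve_pairs settings for
#'   [cosine_curve_report()].
#' @param hoeffding_draws Monte-Carlo draws for [hoeffding_coverage()].
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(kind = c("cyclic", "dihedral", "patch"),
                              seed = 1, Q_train = 100, Q_new = 2,
                              Q_test = 1000, d = 6, radius = 10,
                              n_angles = 6, smoothness = 1,
                              n_thresholds = 10, n_threshold_draws = 10,
                              n_pairs = 200,
                              lambda = 1, beta = 10, alpha = 0.05,
                              max_iter = 200,
                              curve_K = c(5, 10, 25, 50, 100, 200),
                              curve_reps = 50, curve_pairs = 30,
                              hoeffding_draws = 2000) {
  kind <- match.arg(kind)
  for (nm in c("Q_train", "Q_new", "Q_test", "d", "radius", "n_angles",
               "n_thresholds", "max_iter", "curve_reps", "curve_pairs",
               "hoeffding_draws")) {
    stop_if_not_count(get(nm), nm, 1L)
  }
  structure(
    list(kind = kind, seed = as.integer(seed), Q_train = Q_train,
         Q_new = Q_new, Q_test = Q_test, d = d, radius = radius,
         n_angles = n_angles, smoothness = smoothness,
         n_thresholds = n_thresholds,
         n_threshold_draws = n_threshold_draws,
         n_pairs = n_pairs, lambda = lambda,
         beta = beta, alpha = alpha, max_iter = max_iter,
         curve_K = curve_K, curve_reps = curve_reps,
         curve_pairs = curve_pairs, hoeffding_draws = hoeffding_draws),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from JSON or YAML
#'
#' Keys matching the arguments of [experiment_config()] override its
#' defaults.
#'
#' @param path a `.json`, `.yaml` or `.yml` file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the `yaml` package is required to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  keep <- intersect(names(cfg), names(formals(experiment_config)))
  do.call(experiment_config, cfg[keep])
}

config_group <- function(config) {
  switch(config$kind,
         cyclic = cyclic_permutation_group(config$d),
         dihedral = dihedral_permutation_group(config$d),
         patch = patch_rotation_group(config$radius, config$n_angles))
}

config_spec <- function(config) {
  loss_spec("square",
            nonlinearity = logistic_surrogate(z = 0, beta = config$beta))
}

config_dataset <- function(config, Q, seed) {
  if (config$kind == "patch") {
    make_toy_patches(Q, radius = config$radius, n_angles = config$n_angles,
                     smoothness = config$smoothness, seed = seed)
  } else {
    make_orbit_dataset(config_group(config), Q, seed = seed)
  }
}

log_jsonl <- function(path, record) {
  if (is.null(path)) return(invisible(NULL))
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA), con)
  invisible(NULL)
}

#' Simulate the stimulus sets of an experiment
#'
#' Generates the training set `S` (`Q_train` orbits), the new-input set
#' `S_new` (`Q_new` orbits) and the test set `S_test` (`Q_test` orbits)
#' for the configured group, optionally writing them (plus a JSON-lines
#' run log) under `out_dir`. Reruns with the same config are
#' bit-identical.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return invisibly, a list with `group`, `S`, `S_new`, `S_test`.
#' @export
cmd_simulate <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  s <- config$seed
  data <- list(group = config_group(config),
               S = config_dataset(config, config$Q_train, s + 1L),
               S_new = config_dataset(config, config$Q_new, s + 2L),
               S_test = config_dataset(config, config$Q_test, s + 3L))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_group(data$group, file.path(out_dir, "group"))
    write_orbit_dataset(data$S, file.path(out_dir, "S"))
    write_orbit_dataset(data$S_new, file.path(out_dir, "S_new"))
    write_orbit_dataset(data$S_test, file.path(out_dir, "S_test"))
    log_jsonl(file.path(out_dir, "run_log.jsonl"),
              list(stage = "simulate", kind = config$kind,
                   seed = config$seed,
                   sizes = list(S = ncol(data$S$S),
                                S_new = ncol(data$S_new$S),
                                S_test = ncol(data$S_test$S))))
  }
  invisible(data)
}

#' Learn simple-cell weights for an experiment
#'
#' Runs the Stiefel-constrained response maximization on `S` and `S_new`
#' with `n_cells = min(d, |G|)` orthonormal columns (an orthonormal frame
#' cannot have more columns than rows; the full `|G|`-cell complex bank is
#' restored afterwards by orbit closure in [cmd_aggregate()]).
#'
#' @param config an [experiment_config()].
#' @param data the list returned by [cmd_simulate()].
#' @param out_dir output directory, or `NULL`.
#' @return invisibly, a list with the `stiefel_fit` and the learned
#'   `simple_cell_bank` (Heaviside evaluation nonlinearity, threshold 0).
#' @export
cmd_train <- function(config, data, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  n_cells <- min(data$group$d, data$group$N)
  fit <- constrained_maximize(
    data$S, data$S_new, lambda = config$lambda, n_cells = n_cells,
    spec = config_spec(config), alpha = config$alpha,
    max_iter = config$max_iter, seed = config$seed + 4L)
  bank <- simple_cell_bank(fit$U, heaviside(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bank(bank, file.path(out_dir, "bank"))
    utils::write.csv(
      data.frame(iteration = seq_along(fit$objective) - 1L,
                 objective = fit$objective),
      file.path(out_dir, "training_log.csv"), row.names = FALSE)
    log_jsonl(file.path(out_dir, "run_log.jsonl"),
              list(stage = "train", kind = config$kind, seed = config$seed,
                   iterations = fit$iterations,
                   objective = fit$objective[length(fit$objective)],
                   ortho_residual = fit$ortho_residual))
  }
  invisible(list(fit = fit, bank = bank))
}

#' Wire the complex cell for an experiment
#'
#' Builds the candidate pool as the group-orbit closure of the learned
#' columns (each learned weight is one representative of its solution
#' orbit), then runs the iterated maximal-response selection on `S_new`
#' to pick the `|G|` simple cells of the complex cell.
#'
#' @param config an [experiment_config()].
#' @param data the list returned by [cmd_simulate()].
#' @param trained the list returned by [cmd_train()].
#' @param out_dir output directory, or `NULL`.
#' @return invisibly, the `aggregation_result`.
#' @export
cmd_aggregate <- function(config, data, trained, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  U <- trained$fit$U
  pool <- do.call(cbind, lapply(seq_len(ncol(U)), function(i) {
    orbit(data$group, U[, i])
  }))
  agg <- aggregate_orbit(pool, data$S_new, group_size = data$group$N,
                         spec = config_spec(config), group = data$group)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix_txt(agg$selected_weights,
                     file.path(out_dir, "complex_weights.tsv"))
    jsonlite::write_json(
      list(selected_indices = agg$selected_indices,
           pooled = agg$pooled, dedup_count = agg$dedup_count,
           is_orbit = agg$is_orbit, matching = agg$matching),
      file.path(out_dir, "aggregation.json"), auto_unbox = TRUE,
      digits = NA)
    log_jsonl(file.path(out_dir, "run_log.jsonl"),
              list(stage = "aggregate", kind = config$kind,
                   seed = config$seed, is_orbit = agg$is_orbit,
                   dedup_count = agg$dedup_count))
  }
  invisible(agg)
}

#' Evaluate invariance and selectivity of the wired complex cell
#'
#' Produces the distance statistics of the scripted experiments: a
#' full-grid distance report (maximal selectivity regime), a
#' finite-threshold report with `n_thresholds` shared random thresholds,
#' the cosine-similarity-vs-threshold-count curve for one cross-orbit test
#' pair, the Hoeffding coverage table for the same pair, and the
#' worst-case complex-response invariance residual over test stimuli.
#'
#' @param config an [experiment_config()].
#' @param data the list returned by [cmd_simulate()].
#' @param agg the `aggregation_result` from [cmd_aggregate()].
#' @param out_dir output directory, or `NULL`.
#' @return invisibly, a list of class `evaluation_report` with fields
#'   `report_full`, `report_k`, `curve`, `hoeffding`, `inv_residual` and
#'   `summary` (named scalars).
#' @export
cmd_evaluate <- function(config, data, agg, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  bank <- simple_cell_bank(agg$selected_weights, heaviside(0))
  s <- config$seed
  report_full <- distance_report(data$S_test, bank, grid = "full",
                                 n_pairs = config$n_pairs, seed = s + 5L)
  rng <- response_range(bank, data$S_test$S)
  # the finite-threshold overlap is a collision statistic with high
  # variance across threshold draws: average it over independent grids
  reports_k <- lapply(seq_len(config$n_threshold_draws), function(i) {
    grid_k <- random_threshold_grid(config$n_thresholds, rng,
                                    seed = s + 6L + 10L * i)
    distance_report(data$S_test, bank, grid = grid_k,
                    n_pairs = config$n_pairs, seed = s + 7L + 10L * i)
  })
  report_k <- reports_k[[1L]]
  overlap_k_mean <- mean(vapply(reports_k, overlap_fraction, numeric(1)))
  curve <- cosine_curve_report(data$S_test, bank, K_list = config$curve_K,
                               n_pairs = config$curve_pairs,
                               reps = config$curve_reps, seed = s + 8L)
  # one fixed cross-orbit pair for the Hoeffding coverage experiment
  x <- data$S_test$S[, data$S_test$orbit_label == 1L][, 1L]
  y <- data$S_test$S[, data$S_test$orbit_label == 2L][, 1L]
  hoeff <- hoeffding_coverage(x, y, bank,
                              n_draws = config$hoeffding_draws,
                              seed = s + 9L)
  n_inv <- min(50L, ncol(data$S_test$S))
  inv_res <- invariance_residual(agg, data$group,
                                 data$S_test$S[, seq_len(n_inv)])
  summary <- c(
    intra_median_full = stats::median(report_full$intra),
    intra_max_full = max(report_full$intra),
    inter_median_full = stats::median(report_full$inter),
    inter_min_full = min(report_full$inter),
    overlap_full = overlap_fraction(report_full),
    overlap_k = overlap_k_mean,
    spearman = attr(curve, "spearman"),
    plateau_gap = attr(curve, "plateau_gap"),
    hoeffding_max_excess = max(hoeff$empirical - hoeff$bound),
    invariance_residual = inv_res,
    is_orbit = as.numeric(isTRUE(agg$is_orbit))
  )
  out <- structure(
    list(report_full = report_full, report_k = report_k, curve = curve,
         hoeffding = hoeff, inv_residual = inv_res, summary = summary),
    class = "evaluation_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(
      data.frame(
        pair_id = seq_len(length(report_full$intra) +
                            length(report_full$inter)),
        type = rep(c("intra", "inter"),
                   c(length(report_full$intra),
                     length(report_full$inter))),
        distance_full = c(report_full$intra, report_full$inter),
        distance_k = c(report_k$intra, report_k$inter)),
      file.path(out_dir, "distances.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(curve),
                     file.path(out_dir, "cosine_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(hoeff, file.path(out_dir, "hoeffding.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(summary),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    log_jsonl(file.path(out_dir, "run_log.jsonl"),
              c(list(stage = "evaluate", kind = config$kind,
                     seed = config$seed), as.list(summary)))
  }
  invisible(out)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(round(x$summary, 6))
  invisible(x)
}

#' Run the three scripted experiments end to end
#'
#' Chains simulate, train, aggregate and evaluate for the cyclic,
#' dihedral and synthetic-patch presets and collects their summary
#' statistics. Defaults are scaled to desk size (200 test orbits, 200
#' sampled pairs per class) so the full chain runs in a few minutes on
#' one CPU; pass `Q_test = 1000` for the full protocol.
#'
#' @param seed root seed; each preset derives its own stream.
#' @param out_dir output directory (one subdirectory per preset), or
#'   `NULL`.
#' @param Q_train,Q_test,n_pairs protocol sizes passed to every preset.
#' @param ... further overrides for [experiment_config()].
#' @return a list with one `evaluation_report` per preset (`cyclic`,
#'   `dihedral`, `patch`) and `comparison`, a data frame of their summary
#'   rows.
#' @export
run_figure1 <- function(seed = 1, out_dir = NULL, Q_train = 100,
                        Q_test = 200, n_pairs = 200, ...) {
  kinds <- c("cyclic", "dihedral", "patch")
  offsets <- c(cyclic = 100L, dihedral = 200L, patch = 300L)
  reports <- lapply(kinds, function(k) {
    cfg <- experiment_config(kind = k, seed = seed + offsets[[k]],
                             Q_train = Q_train, Q_test = Q_test,
                             n_pairs = n_pairs, ...)
    dir_k <- if (is.null(out_dir)) NULL else file.path(out_dir, k)
    data <- cmd_simulate(cfg, dir_k)
    trained <- cmd_train(cfg, data, dir_k)
    agg <- cmd_aggregate(cfg, data, trained, dir_k)
    cmd_evaluate(cfg, data, agg, dir_k)
  })
  names(reports) <- kinds
  comparison <- do.call(rbind, lapply(kinds, function(k) {
    data.frame(kind = k, t(reports[[k]]$summary))
  }))
  reports$comparison <- comparison
  if (!is.null(out_dir)) {
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  }
  reports
}
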