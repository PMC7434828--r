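# Serialization: delimited numeric matrices + JSON metadata sidecars.
# Matrices are written in full double precision (17 significant digits),
# tab-delimited, no headers, so round trips preserve 1e-8-level residuals.

write_matrix_txt <- function(m, path) {
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

read_matrix_txt <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                              colClasses = "numeric"))
}

#' Write / read a finite group
#'
#' A group is stored as `<prefix>.json` (kind, d, N, layout) plus
#' `<prefix>_elements.tsv` holding the `N` stacked `d x d` element
#' matrices (element `i` occupies rows `(i-1)*d + 1 ... i*d`).
#'
#' @param group a [finite_group()].
#' @param prefix file path prefix (no extension).
#' @return `write_group()` the prefix, invisibly; `read_group()` the
#'   reconstructed [finite_group()].
#' @export
write_group <- function(group, prefix) {
  stopifnot(inherits(group, "finite_group"))
  meta <- list(kind = group$kind, d = group$d, N = group$N,
               layout = group$layout)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  write_matrix_txt(do.call(rbind, group$elements),
                   paste0(prefix, "_elements.tsv"))
  invisible(prefix)
}

#' @rdname write_group
#' @export
read_group <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  stacked <- read_matrix_txt(paste0(prefix, "_elements.tsv"))
  d <- meta$d
  elements <- lapply(seq_len(meta$N), function(i) {
    unname(stacked[(i - 1L) * d + seq_len(d), , drop = FALSE])
  })
  finite_group(elements, kind = meta$kind,
               layout = if (length(meta$layout)) meta$layout else NULL)
}

#' Write / read an orbit dataset
#'
#' Stored as `<prefix>_S.tsv` (stimulus matrix, columns = stimuli),
#' `<prefix>_base.tsv` (base points), a JSON sidecar with Q, N, labels and
#' seed, and the group files under `<prefix>_group*`.
#'
#' @param dataset an `orbit_dataset`.
#' @param prefix file path prefix.
#' @return `write_orbit_dataset()` the prefix, invisibly;
#'   `read_orbit_dataset()` the reconstructed `orbit_dataset`.
#' @export
write_orbit_dataset <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "orbit_dataset"))
  write_group(dataset$group, paste0(prefix, "_group"))
  write_matrix_txt(dataset$S, paste0(prefix, "_S.tsv"))
  write_matrix_txt(dataset$base_points, paste0(prefix, "_base.tsv"))
  meta <- list(Q = dataset$Q, N = dataset$N,
               orbit_label = dataset$orbit_label,
               element_index = dataset$element_index,
               complete = dataset$complete,
               seed = dataset$seed)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_orbit_dataset
#' @export
read_orbit_dataset <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  structure(
    list(group = read_group(paste0(prefix, "_group")),
         base_points = unname(read_matrix_txt(paste0(prefix, "_base.tsv"))),
         S = unname(read_matrix_txt(paste0(prefix, "_S.tsv"))),
         orbit_label = as.integer(meta$orbit_label),
         element_index = as.integer(meta$element_index),
         Q = as.integer(meta$Q), N = as.integer(meta$N),
         complete = isTRUE(meta$complete),
         seed = if (is.null(meta$seed)) NULL else as.integer(meta$seed)),
    class = "orbit_dataset"
  )
}

#' Write / read a simple-cell bank
#'
#' Stored as `<prefix>_W.tsv` (weight matrix) plus a JSON nonlinearity
#' spec.
#'
#' @param bank a [simple_cell_bank()].
#' @param prefix file path prefix.
#' @return `write_bank()` the prefix, invisibly; `read_bank()` the
#'   reconstructed [simple_cell_bank()].
#' @export
write_bank <- function(bank, prefix) {
  stopifnot(inherits(bank, "simple_cell_bank"))
  write_matrix_txt(bank$W, paste0(prefix, "_W.tsv"))
  jsonlite::write_json(bank$nonlinearity[c("kind", "z", "beta")],
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_bank
#' @export
read_bank <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  nl <- if (meta$kind == "heaviside") {
    heaviside(meta$z)
  } else {
    logistic_surrogate(meta$z, meta$beta)
  }
  simple_cell_bank(unname(read_matrix_txt(paste0(prefix, "_W.tsv"))), nl)
}

#' Export a signature as CSV
#'
#' Two columns, `threshold` and `value`.
#'
#' @param sig a `complex_cell_signature`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_signature_csv <- function(sig, path) {
  stopifnot(inherits(sig, "complex_cell_signature"))
  utils::write.csv(data.frame(threshold = sig$thresholds,
                              value = sig$values),
                   path, row.names = FALSE)
  invisible(path)
}
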