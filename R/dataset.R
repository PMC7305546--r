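## Training corpus generation: enumeration of layered fat/muscle/rest
## conductivity specifications, mapping specifications to per-element
## fields, and batch simulation of (target, normalized-voltage) pairs.

#' Enumerate fat/muscle layer partitions
#'
#' All pairs `(l_f, l_m)` with `1 <= l_f < l_m <= L - 1` in lexicographic
#' order: at least one layer each for fat, muscle and the rest. For
#' `L = 15` there are `C(14, 2) = 91` partitions.
#'
#' @param L layer count (>= 3).
#' @return data.frame with columns `l_f`, `l_m`.
#' @export
enumerate_partitions <- function(L = 15L) {
  L <- as.integer(L)
  if (L < 3L) stop_eit("need L >= 3 for fat, muscle and rest",
                       class = "eit_validation_error")
  p <- t(utils::combn(L - 1L, 2L))
  data.frame(l_f = p[, 1], l_m = p[, 2])
}

#' Enumerate conductivity triples
#'
#' Cartesian product of the muscle and rest conductivity grids at fixed fat
#' conductivity (relative units, fat = 1). Defaults follow the reference
#' training design: 17 muscle values 2.0, 2.5, ..., 10.0 and 9 rest values
#' 1.5, 2.5, ..., 9.5. The physical ordering `gamma_f < gamma_r < gamma_m`
#' can optionally be enforced; by default it is not, so the full product
#' (17 x 9 per partition) is generated.
#'
#' @param gamma_f fat conductivity (fixed, default 1).
#' @param gamma_m muscle conductivity grid; must satisfy
#'   `gamma_f < gamma_m <= 10 * gamma_f`.
#' @param gamma_r rest (interior tissue) conductivity grid.
#' @param enforce_order keep only triples with
#'   `gamma_f < gamma_r < gamma_m`.
#' @return data.frame with columns `gamma_f`, `gamma_m`, `gamma_r`.
#' @export
enumerate_conductivities <- function(gamma_f = 1,
                                     gamma_m = seq(2, 10, by = 0.5),
                                     gamma_r = seq(1.5, 9.5, by = 1),
                                     enforce_order = FALSE) {
  if (!length(gamma_m) || !length(gamma_r)) {
    stop_eit("conductivity grids must be non-empty",
             class = "eit_validation_error")
  }
  if (any(gamma_m <= gamma_f) || any(gamma_m > 10 * gamma_f)) {
    stop_eit("muscle grid must satisfy gamma_f < gamma_m <= 10*gamma_f",
             class = "eit_validation_error")
  }
  g <- expand.grid(gamma_r = gamma_r, gamma_m = gamma_m,
                   KEEP.OUT.ATTRS = FALSE)
  if (enforce_order) g <- g[g$gamma_r > gamma_f & g$gamma_r < g$gamma_m, ]
  data.frame(gamma_f = gamma_f, gamma_m = g$gamma_m, gamma_r = g$gamma_r,
             row.names = NULL)
}

#' Layered conductivity specification
#'
#' A layered abdomen model: layers `1..l_f` are subcutaneous fat, layers
#' `l_f+1..l_m` are muscle, the remaining layers are other interior tissue.
#' The implied fat thickness is `d0 * l_f` and the muscle thickness
#' `d0 * (l_m - l_f)`.
#'
#' @param l_f,l_m fat and muscle boundary layer indices,
#'   `1 <= l_f < l_m <= L - 1`.
#' @param gamma_f,gamma_m,gamma_r region conductivities with
#'   `gamma_f < gamma_m <= 10 * gamma_f`.
#' @param L total layer count.
#' @return object of class `eit_spec`.
#' @export
layered_conductivity <- function(l_f, l_m, gamma_f = 1, gamma_m = 5,
                                 gamma_r = 2.5, L = 15L) {
  l_f <- as.integer(l_f); l_m <- as.integer(l_m); L <- as.integer(L)
  if (!(1L <= l_f && l_f < l_m && l_m <= L - 1L)) {
    stop_eit("need 1 <= l_f < l_m <= L-1", class = "eit_validation_error")
  }
  if (!(gamma_f < gamma_m && gamma_m <= 10 * gamma_f)) {
    stop_eit("need gamma_f < gamma_m <= 10*gamma_f",
             class = "eit_validation_error")
  }
  if (gamma_r <= 0) stop_eit("gamma_r must be positive",
                             class = "eit_validation_error")
  structure(list(l_f = l_f, l_m = l_m, gamma_f = gamma_f,
                 gamma_m = gamma_m, gamma_r = gamma_r, L = L),
            class = "eit_spec")
}

#' @exportS3Method base::print
print.eit_spec <- function(x, ...) {
  cat(sprintf("Layered conductivity: fat 1..%d (%.2g), muscle %d..%d (%.2g), rest (%.2g), L = %d\n",
              x$l_f, x$gamma_f, x$l_f + 1L, x$l_m, x$gamma_m, x$gamma_r, x$L))
  invisible(x)
}

#' Map a layered specification to a per-element conductivity field
#'
#' @param spec an [layered_conductivity()] specification.
#' @param layers an [compute_layers()] partition with matching `L`.
#' @return list with `field` (per-element conductivity) and `target`
#'   (per-layer conductivity vector of length `L`).
#' @export
spec_to_field <- function(spec, layers) {
  stopifnot(inherits(spec, "eit_spec"), inherits(layers, "eit_layers"))
  if (spec$L != layers$L) {
    stop_eit("specification and partition disagree on L",
             class = "eit_validation_error")
  }
  L <- layers$L
  target <- c(rep(spec$gamma_f, spec$l_f),
              rep(spec$gamma_m, spec$l_m - spec$l_f),
              rep(spec$gamma_r, L - spec$l_m))
  list(field = target[layers$layer], target = target)
}

#' Generate a training dataset of (conductivity, normalized voltage) pairs
#'
#' For every specification: build the per-element field, solve all drives,
#' measure the ordered voltage vector, optionally add multiplicative noise,
#' normalize against the homogeneous reference, and store the pair. Raw
#' voltages are stored alongside the normalized ones (the geometry-transfer
#' ablation trains on both).
#'
#' @param mesh an [build_mesh()] mesh.
#' @param layers an [compute_layers()] partition.
#' @param protocol the measurement protocol.
#' @param specs data.frame with columns `l_f`, `l_m`, `gamma_f`, `gamma_m`,
#'   `gamma_r` (see [enumerate_partitions()] / [enumerate_conductivities()]),
#'   or a list of `eit_spec` objects.
#' @param ref a [reference_set()]; computed if missing.
#' @param noise relative multiplicative noise level on raw voltages
#'   (default 0).
#' @param seed integer seed for the noise stream.
#' @param progress_every print progress every this many specifications
#'   (0 = silent).
#' @return object of class `eit_dataset` with matrices `inputs`
#'   (normalized, N x M*), `raw` (N x M*), `targets` (N x L), the spec
#'   table and provenance.
#' @export
generate_dataset <- function(mesh, layers, protocol, specs, ref = NULL,
                             noise = 0, seed = NULL, progress_every = 0L) {
  stopifnot(inherits(mesh, "eit_mesh"), inherits(layers, "eit_layers"),
            inherits(protocol, "eit_protocol"))
  if (is.list(specs) && !is.data.frame(specs)) {
    specs <- do.call(rbind, lapply(specs, function(s) {
      data.frame(l_f = s$l_f, l_m = s$l_m, gamma_f = s$gamma_f,
                 gamma_m = s$gamma_m, gamma_r = s$gamma_r)
    }))
  }
  need <- c("l_f", "l_m", "gamma_f", "gamma_m", "gamma_r")
  if (!all(need %in% names(specs))) {
    stop_eit("specs must have columns ", paste(need, collapse = ", "),
             class = "eit_validation_error")
  }
  if (anyDuplicated(specs)) {
    stop_eit("duplicate specifications in the training set",
             class = "eit_validation_error")
  }
  if (is.null(ref)) ref <- reference_set(mesh, protocol)
  N <- nrow(specs)
  L <- layers$L
  inputs <- matrix(NA_real_, N, protocol$M_star)
  raw <- matrix(NA_real_, N, protocol$M_star)
  targets <- matrix(NA_real_, N, L)
  noise_seeds <- if (noise > 0) {
    with_seed(seed, sample.int(.Machine$integer.max - 1L, N))
  } else rep(NA_integer_, N)
  failed <- integer(0)
  t0 <- Sys.time()
  for (k in seq_len(N)) {
    sp <- layered_conductivity(specs$l_f[k], specs$l_m[k], specs$gamma_f[k],
                               specs$gamma_m[k], specs$gamma_r[k], L)
    sf <- spec_to_field(sp, layers)
    ok <- tryCatch({
      fields <- solve_forward(mesh, sf$field, protocol)
      V <- measure_voltages(fields, protocol)
      if (noise > 0) V <- add_noise(V, noise, noise_seeds[k])
      vhat <- normalize_voltages(V, ref)
      raw[k, ] <- V$V
      inputs[k, ] <- vhat$V
      targets[k, ] <- sf$target
      TRUE
    }, eit_error = function(e) {
      warning(sprintf("spec %d failed and was skipped: %s", k,
                      conditionMessage(e)), call. = FALSE)
      FALSE
    })
    if (!ok) failed <- c(failed, k)
    if (progress_every > 0 && k %% progress_every == 0) {
      el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      message(sprintf("  simulated %d/%d specs (%.1f s elapsed)", k, N, el))
    }
  }
  if (length(failed)) {
    keep <- setdiff(seq_len(N), failed)
    inputs <- inputs[keep, , drop = FALSE]
    raw <- raw[keep, , drop = FALSE]
    targets <- targets[keep, , drop = FALSE]
    specs <- specs[keep, , drop = FALSE]
  }
  ds <- structure(list(
    inputs = inputs, raw = raw, targets = targets, specs = specs,
    L = L, d0 = layers$d0, M_star = protocol$M_star,
    n_failed = length(failed),
    provenance = list(mesh_hash = mesh$hash, protocol_hash = protocol$hash,
                      layers_roi = layers$roi, noise = noise, seed = seed)
  ), class = "eit_dataset")
  ds$hash <- content_hash(list(inputs, targets, ds$provenance))
  ds
}

#' @exportS3Method base::print
print.eit_dataset <- function(x, ...) {
  cat(sprintf("EIT training dataset: %d pairs, inputs %d, targets %d layers (d0 = %.2f cm)\n",
              nrow(x$inputs), x$M_star, x$L, x$d0))
  if (x$n_failed) cat(sprintf("  %d specifications failed and were skipped\n",
                              x$n_failed))
  invisible(x)
}

#' Write a dataset container to disk
#'
#' RDS array container holding the input/target matrices, the spec table
#' and provenance; a small CSV slice (`file` with extension replaced by
#' `_head.csv`) is written alongside for quick inspection.
#'
#' @param dataset an `eit_dataset`.
#' @param file output `.rds` path.
#' @param csv_head rows to export to the CSV slice (0 = none).
#' @export
write_dataset <- function(dataset, file, csv_head = 0L) {
  stopifnot(inherits(dataset, "eit_dataset"))
  saveRDS(dataset, file)
  if (csv_head > 0) {
    k <- min(csv_head, nrow(dataset$inputs))
    slice <- cbind(dataset$specs[seq_len(k), ],
                   dataset$inputs[seq_len(k), seq_len(min(10, ncol(dataset$inputs))), drop = FALSE])
    utils::write.csv(slice, sub("\\.rds$", "_head.csv", file),
                     row.names = FALSE)
  }
  invisible(file)
}

#' Read a dataset container written by [write_dataset()]
#' @param file `.rds` path.
#' @return an `eit_dataset`.
#' @export
read_dataset <- function(file) {
  ds <- readRDS(file)
  if (!inherits(ds, "eit_dataset")) {
    stop_eit("file does not contain an eit_dataset",
             class = "eit_validation_error")
  }
  ds
}
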