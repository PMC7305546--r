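## End-to-end reconstruction (normalization followed by the MLP inverse
## map), fat/muscle border detection on the layer profile, percentage
## errors, the geometry-transfer ablation and the robustness screen.

#' Detect fat and muscle borders in a layer profile
#'
#' The fat border `l_f` is located at the largest relative increase
#' between consecutive values within `1..L-2`, provided it exceeds
#' `min_jump`. A finite-resolution inverse map can smear a sharp
#' interface across one layer, producing two consecutive super-threshold
#' increases; such a run is treated as a single abrupt rise whose border
#' is its last layer - training targets quantize interfaces to layer
#' boundaries, so the partially-risen intermediate layer is the one
#' containing the interface and still counts as fat. The muscle border
#' `l_m` is found the same way among the subsequent decreases (NA when
#' no drop exceeds the threshold). A profile without any sufficient jump
#' has no fat-muscle structure and both are NA.
#'
#' @param values numeric length-`L` layer conductivity profile.
#' @param min_jump minimal relative increase counting as an "abrupt" change
#'   (default 0.3; the smallest fat-muscle contrast in the training designs
#'   is a factor 2, i.e. a relative jump of 1).
#' @param floor_value denominator floor for the relative change (default
#'   0.5, half the smallest physical conductivity in the layered designs).
#'   Rectified network outputs can be exactly zero, and without a floor a
#'   zero-to-small step would dominate the relative-change statistic.
#' @return list with integer `l_f` and `l_m` (NA when not detected).
#' @export
detect_borders <- function(values, min_jump = 0.3, floor_value = 0.5) {
  L <- length(values)
  if (L < 3L) stop_eit("need at least 3 layers", class = "eit_validation_error")
  base <- pmax(values[seq_len(L - 1L)], floor_value)
  rel <- (values[-1L] - values[-L]) / base
  ## last index of the run of consecutive super-threshold steps that
  ## contains the largest step
  run_end <- function(steps, start_at) {
    idx <- which(steps > min_jump)
    idx <- idx[idx >= start_at]
    if (!length(idx)) return(NA_integer_)
    peak <- idx[which.max(steps[idx])]
    while ((peak + 1L) %in% idx) peak <- peak + 1L
    as.integer(peak)
  }
  up <- rel[seq_len(L - 2L)]
  if (max(up) <= min_jump) return(list(l_f = NA_integer_, l_m = NA_integer_))
  l_f <- run_end(up, 1L)
  l_m <- NA_integer_
  if (l_f + 1L <= L - 1L) {
    l_m <- run_end(-rel[seq_len(L - 1L)], l_f + 1L)
  }
  list(l_f = l_f, l_m = l_m)
}

#' Percentage error
#'
#' `100 * |est - truth| / |truth|`.
#'
#' @param est estimate.
#' @param truth nonzero reference value.
#' @return percent error.
#' @export
percentage_error <- function(est, truth) {
  if (any(truth == 0)) stop_eit("truth must be nonzero",
                                class = "eit_validation_error")
  100 * abs(est - truth) / abs(truth)
}

#' End-to-end reconstruction from a voltage vector
#'
#' Normalizes the measured voltages against the homogeneous reference,
#' applies the fitted MLP inverse map, detects the fat/muscle borders, and
#' reports thicknesses and the fat conductivity (mean over the detected
#' fat layers). Provenance hashes of voltages, reference and model must
#' agree; a mismatch (e.g. voltages from another mesh) is refused.
#'
#' @param V an `eit_voltages` object (raw or already normalized).
#' @param ref the [reference_set()] matching `V`.
#' @param model a fitted [eit_mlp()].
#' @param d0 layer thickness in cm (defaults to the model's).
#' @param min_jump border-detection threshold.
#' @return object of class `eit_reconstruction`: layer values, detected
#'   borders, thicknesses, fat conductivity and a depth profile.
#' @export
reconstruct <- function(V, ref, model, d0 = model$d0, min_jump = 0.3) {
  stopifnot(inherits(V, "eit_voltages"), inherits(ref, "eit_reference"),
            inherits(model, "eit_mlp"))
  if (!identical(V$mesh_hash, ref$mesh_hash)) {
    stop_eit("voltages and reference come from different meshes",
             class = "eit_validation_error")
  }
  if (model$input_type == "normalized") {
    vhat <- if (V$normalized) V else normalize_voltages(V, ref)
    x <- vhat$V
  } else {
    if (V$normalized) stop_eit("raw-input model fed normalized voltages",
                               class = "eit_validation_error")
    x <- V$V
  }
  vals <- predict(model, x)
  det <- detect_borders(vals, min_jump = min_jump)
  fat_thick <- if (!is.na(det$l_f)) d0 * det$l_f else NA_real_
  muscle_thick <- if (!is.na(det$l_f) && !is.na(det$l_m)) {
    d0 * (det$l_m - det$l_f)
  } else NA_real_
  structure(list(
    layer_values = vals,
    l_f_hat = det$l_f, l_m_hat = det$l_m,
    fat_thickness_cm = fat_thick,
    muscle_thickness_cm = muscle_thick,
    fat_conductivity_hat = if (!is.na(det$l_f)) mean(vals[seq_len(det$l_f)]) else NA_real_,
    profile = data.frame(depth_cm = (seq_along(vals) - 0.5) * d0,
                         conductivity = vals),
    d0 = d0, min_jump = min_jump
  ), class = "eit_reconstruction")
}

#' @exportS3Method base::print
print.eit_reconstruction <- function(x, ...) {
  if (is.na(x$l_f_hat)) {
    cat("Reconstruction: no fat-muscle structure detected\n")
  } else {
    cat(sprintf("Reconstruction: fat %.1f cm (layers 1..%d, conductivity %.2f)",
                x$fat_thickness_cm, x$l_f_hat, x$fat_conductivity_hat))
    if (!is.na(x$l_m_hat)) {
      cat(sprintf(", muscle %.1f cm (to layer %d)", x$muscle_thickness_cm,
                  x$l_m_hat))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
plot.eit_reconstruction <- function(x, truth = NULL, ...) {
  p <- x$profile
  graphics::plot(p$depth_cm, p$conductivity, type = "s",
                 xlab = "depth from boundary (cm)",
                 ylab = "conductivity (relative)", ...)
  if (!is.null(truth)) graphics::lines(p$depth_cm, truth, type = "s", lty = 2)
  invisible(x)
}

#' Geometry-transfer ablation
#'
#' Trains two inverse maps on the same training corpus - one on normalized
#' voltages, one on raw voltages - and evaluates both on a test case
#' simulated on a different body geometry. With normalization the
#' conductivity-unit inputs transfer across geometries; raw voltages do
#' not, so the raw-trained map should fail to recover the fat border.
#'
#' @param train_dataset an [generate_dataset()] corpus (carries both
#'   normalized and raw inputs).
#' @param test_mesh,test_layers,test_protocol geometry/partition/protocol
#'   of the test domain.
#' @param test_spec an [layered_conductivity()] specification to simulate
#'   on the test domain.
#' @param test_ref a [reference_set()] for the test mesh (computed if
#'   missing).
#' @param model_norm,model_orig optionally pre-fitted models (trained on
#'   `train_dataset` with `inputs = "normalized"` / `"raw"`); fitted here
#'   when missing.
#' @param min_jump border-detection threshold.
#' @param ... further arguments passed to [eit_mlp()] when fitting.
#' @return list of class `eit_transfer_report` with both reconstructions,
#'   thickness estimates and errors.
#' @export
geometry_transfer_experiment <- function(train_dataset, test_mesh, test_layers,
                                         test_protocol, test_spec,
                                         test_ref = NULL,
                                         model_norm = NULL, model_orig = NULL,
                                         min_jump = 0.3, ...) {
  stopifnot(inherits(train_dataset, "eit_dataset"))
  if (is.null(model_norm)) {
    model_norm <- eit_mlp(train_dataset, inputs = "normalized", ...)
  }
  if (is.null(model_orig)) {
    model_orig <- eit_mlp(train_dataset, inputs = "raw", ...)
  }
  if (!identical(model_norm$dataset_hash, model_orig$dataset_hash)) {
    stop_eit("the two models were not trained on the same corpus",
             class = "eit_validation_error")
  }
  if (is.null(test_ref)) test_ref <- reference_set(test_mesh, test_protocol)
  sf <- spec_to_field(test_spec, test_layers)
  fields <- solve_forward(test_mesh, sf$field, test_protocol)
  V <- measure_voltages(fields, test_protocol)
  rec_norm <- reconstruct(V, test_ref, model_norm, d0 = test_layers$d0,
                          min_jump = min_jump)
  rec_orig <- reconstruct(V, test_ref, model_orig, d0 = test_layers$d0,
                          min_jump = min_jump)
  truth_cm <- test_layers$d0 * test_spec$l_f
  err <- function(rec) {
    if (is.na(rec$fat_thickness_cm)) Inf
    else percentage_error(rec$fat_thickness_cm, truth_cm)
  }
  structure(list(
    truth = list(l_f = test_spec$l_f, thickness_cm = truth_cm,
                 target = sf$target),
    normalized = list(reconstruction = rec_norm, thickness_err_pct = err(rec_norm)),
    raw = list(reconstruction = rec_orig, thickness_err_pct = err(rec_orig)),
    model_norm = model_norm, model_orig = model_orig
  ), class = "eit_transfer_report")
}

#' @exportS3Method base::print
print.eit_transfer_report <- function(x, ...) {
  cat(sprintf("Geometry transfer: true fat %.1f cm\n", x$truth$thickness_cm))
  cat(sprintf("  normalized-input model: %s (err %.1f%%)\n",
              fmt_thick(x$normalized$reconstruction),
              x$normalized$thickness_err_pct))
  cat(sprintf("  raw-input model:        %s (err %s)\n",
              fmt_thick(x$raw$reconstruction),
              if (is.finite(x$raw$thickness_err_pct))
                sprintf("%.1f%%", x$raw$thickness_err_pct) else "no border"))
  invisible(x)
}

fmt_thick <- function(rec) {
  if (is.na(rec$fat_thickness_cm)) "no fat border detected"
  else sprintf("%.1f cm", rec$fat_thickness_cm)
}

#' Robustness screen on non-abdominal inputs
#'
#' Feeds the fitted inverse map three families of out-of-distribution
#' inputs and records whether a fat-muscle structure is (wrongly)
#' detected: (a) anomaly phantoms - homogeneous background 2 with two
#' internal anomalies of conductivity 7 and 5; (b) Gaussian random
#' per-element conductivity fields; (c) pure Gaussian random voltage
#' vectors. In-distribution layered inputs serve as positive controls.
#'
#' @param model a fitted [eit_mlp()] (normalized inputs).
#' @param mesh,layers,protocol,ref the simulation geometry matching the
#'   model's training provenance.
#' @param n_random number of random voltage vectors.
#' @param n_fields number of random conductivity fields.
#' @param n_controls number of in-distribution positive controls.
#' @param seed RNG seed.
#' @param min_jump border-detection threshold.
#' @return list of class `eit_robustness_report`: per-family detection
#'   fractions and details.
#' @export
robustness_screen <- function(model, mesh, layers, protocol, ref,
                              n_random = 100L, n_fields = 10L,
                              n_controls = 5L, seed = 1L, min_jump = 0.3) {
  stopifnot(inherits(model, "eit_mlp"))
  d0 <- layers$d0
  detected <- function(x) {
    !is.na(detect_borders(predict(model, x), min_jump = min_jump)$l_f)
  }
  ## (a) anomaly phantoms: background 2, anomalies 7 (upper) and 5 (lower)
  ctr <- mesh$domain$centroid
  scale_r <- min(sqrt(rowSums(sweep(mesh$nodes[seq_len(mesh$n_boundary), ], 2, ctr)^2)))
  anors <- with_seed(seed + 7L, cbind(stats::runif(3L, 0.25, 0.45),
                                      stats::runif(3L, 0.1, 0.3)))
  anomaly_hits <- logical(3L)
  for (k in 1:3) {
    g <- rep(2, nrow(mesh$triangles))
    up <- c(ctr[1], ctr[2] + anors[k, 1] * scale_r)
    dn <- c(ctr[1] - anors[k, 2] * scale_r, ctr[2] - anors[k, 1] * scale_r)
    r_an <- 0.18 * scale_r
    d_up <- sqrt((mesh$centroids[, 1] - up[1])^2 + (mesh$centroids[, 2] - up[2])^2)
    d_dn <- sqrt((mesh$centroids[, 1] - dn[1])^2 + (mesh$centroids[, 2] - dn[2])^2)
    g[d_up < r_an] <- 7
    g[d_dn < r_an] <- 5
    V <- measure_voltages(solve_forward(mesh, g, protocol), protocol)
    anomaly_hits[k] <- detected(normalize_voltages(V, ref)$V)
  }
  ## (b) Gaussian random conductivity fields (truncated positive)
  field_hits <- logical(n_fields)
  gs <- with_seed(seed + 11L,
                  matrix(stats::rnorm(n_fields * nrow(mesh$triangles), 2, 0.7),
                         nrow = n_fields))
  for (k in seq_len(n_fields)) {
    g <- pmax(0.1, gs[k, ])
    V <- measure_voltages(solve_forward(mesh, g, protocol), protocol)
    field_hits[k] <- detected(normalize_voltages(V, ref)$V)
  }
  ## (c) pure Gaussian random voltage vectors at the scale of measured
  ## data (sd of the homogeneous reference voltages), passed through the
  ## same normalization as measured data
  v_scale <- stats::sd(ref$V1$V)
  rv <- with_seed(seed + 13L,
                  matrix(stats::rnorm(n_random * protocol$M_star, sd = v_scale),
                         nrow = n_random))
  random_hits <- logical(n_random)
  for (k in seq_len(n_random)) {
    random_hits[k] <- detected(ref$S / rv[k, ])
  }
  ## positive controls: in-distribution layered specs
  ctrl_specs <- with_seed(seed + 17L, data.frame(
    l_f = sample(3:10, n_controls, replace = TRUE)))
  ctrl_hits <- logical(n_controls)
  for (k in seq_len(n_controls)) {
    sp <- layered_conductivity(ctrl_specs$l_f[k], 14L, 1, 6, 5.5, layers$L)
    sf <- spec_to_field(sp, layers)
    V <- measure_voltages(solve_forward(mesh, sf$field, protocol), protocol)
    ctrl_hits[k] <- detected(normalize_voltages(V, ref)$V)
  }
  n_neg <- length(anomaly_hits) + n_fields + n_random
  structure(list(
    anomaly_detected = anomaly_hits,
    field_detected = field_hits,
    random_detected = random_hits,
    control_detected = ctrl_hits,
    fraction_negative_clean = 1 - (sum(anomaly_hits) + sum(field_hits) +
                                     sum(random_hits)) / n_neg,
    fraction_controls_detected = mean(ctrl_hits),
    seed = seed
  ), class = "eit_robustness_report")
}

#' @exportS3Method base::print
print.eit_robustness_report <- function(x, ...) {
  cat(sprintf("Robustness screen: %.0f%% of non-abdominal inputs show no fat-muscle structure\n",
              100 * x$fraction_negative_clean))
  cat(sprintf("  anomaly phantoms flagged: %d/%d; random fields: %d/%d; random voltages: %d/%d\n",
              sum(x$anomaly_detected), length(x$anomaly_detected),
              sum(x$field_detected), length(x$field_detected),
              sum(x$random_detected), length(x$random_detected)))
  cat(sprintf("  positive controls detected: %.0f%%\n",
              100 * x$fraction_controls_detected))
  invisible(x)
}
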