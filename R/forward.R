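## Forward model: pairwise current-injection protocol, FEM solution of the
## generalized Laplace equation div(gamma grad u) = 0 with Neumann boundary
## data, and assembly of the ordered current-voltage vector.

#' Pairwise drive/measurement protocol
#'
#' Enumerates all `C(E,2)` unordered drive pairs in lexicographic order and,
#' for each drive, all `C(E-2,2)` measurement pairs among the non-driving
#' electrodes (also lexicographic). Measurements sharing an electrode with
#' the drive are excluded, which side-steps skin-electrode contact
#' impedance. For `E = 10` this yields 45 drives, 28 measurements each,
#' 1260 voltages in total.
#'
#' @param n_electrodes electrode count `E` (at least 4, else no admissible
#'   measurement pair exists).
#' @param current drive current amplitude in mA (default 1).
#' @return object of class `eit_protocol` with the drive table, the flat
#'   ordered measurement index (the canonical ordering of the voltage
#'   vector), and a pair-index lookup.
#' @export
make_protocol <- function(n_electrodes = 10L, current = 1) {
  E <- as.integer(n_electrodes)
  if (E < 4L) {
    stop_eit("need at least 4 electrodes: with fewer, no measurement pair ",
             "disjoint from the drive exists", class = "eit_validation_error")
  }
  check_positive(current, "current")
  drives <- t(utils::combn(E, 2L))
  M <- nrow(drives)
  pair_idx <- matrix(NA_integer_, E, E)
  for (k in seq_len(M)) {
    pair_idx[drives[k, 1], drives[k, 2]] <- k
    pair_idx[drives[k, 2], drives[k, 1]] <- k
  }
  rows <- vector("list", M)
  for (j in seq_len(M)) {
    rem <- setdiff(seq_len(E), drives[j, ])
    mp <- t(utils::combn(rem, 2L))
    rows[[j]] <- cbind(drive = j, jp = drives[j, 1], jm = drives[j, 2],
                       ip = mp[, 1], im = mp[, 2],
                       pair = pair_idx[mp])
  }
  flat <- as.data.frame(do.call(rbind, rows))
  proto <- structure(list(
    E = E, current = current, drives = drives, M = M,
    n_meas_per_drive = choose(E - 2L, 2L),
    M_star = nrow(flat), flat = flat, pair_idx = pair_idx
  ), class = "eit_protocol")
  proto$hash <- content_hash(list(E, current, drives, flat))
  proto
}

#' @exportS3Method base::print
print.eit_protocol <- function(x, ...) {
  cat(sprintf("EIT protocol: %d electrodes, %d drive pairs x %d measurements = %d voltages, I = %g mA\n",
              x$E, x$M, x$n_meas_per_drive, x$M_star, x$current))
  invisible(x)
}

## Assemble the global stiffness matrix for a per-element conductivity.
fem_assemble <- function(mesh, gamma) {
  fem <- mesh$fem
  m <- fem$m
  if (length(gamma) == 1L) gamma <- rep(gamma, m)
  if (length(gamma) != m) {
    stop_eit("conductivity must be scalar or one value per element",
             class = "eit_validation_error")
  }
  if (any(!is.finite(gamma)) || any(gamma <= 0)) {
    stop_eit("conductivity must be positive and finite",
             class = "eit_validation_error")
  }
  sparseMatrix(i = fem$trip_i, j = fem$trip_j,
               x = fem$trip_v * gamma[fem$trip_e],
               dims = c(fem$n, fem$n))
}

## Load matrix (n x M): uniform current density +I/|e| on the positive and
## -I/|e| on the negative drive electrode. Columns sum to zero exactly
## (conservation) because each row of the averaging matrix sums to one.
fem_loads <- function(mesh, drives, current) {
  tR <- Matrix::t(mesh$fem$R)
  as.matrix(current * (tR[, drives[, 1], drop = FALSE] -
                         tR[, drives[, 2], drop = FALSE]))
}

## Solve the grounded system for all drive columns and restore the
## zero-mass-weighted-mean gauge. Returns the dense n x M potential matrix.
fem_solve <- function(mesh, gamma, drives, current) {
  K <- fem_assemble(mesh, gamma)
  Fm <- fem_loads(mesh, drives, current)
  n <- nrow(K)
  Ch <- tryCatch(
    Cholesky(forceSymmetric(K[-1L, -1L, drop = FALSE]), LDL = FALSE, perm = TRUE),
    error = function(e) stop_eit("stiffness factorization failed: ",
                                 conditionMessage(e), class = "eit_solver_error"))
  X <- as.matrix(solve(Ch, Fm[-1L, , drop = FALSE]))
  U <- rbind(0, X)
  mass <- mesh$fem$mass
  mu <- colSums(U * mass) / sum(mass)
  U - rep(mu, each = n)
}

#' Solve all drive patterns of a protocol
#'
#' FEM solution of `div(gamma grad u) = 0` with uniform Neumann current
#' density on the drive electrode pair (gap/shunt-free electrode model),
#' grounded by the zero mass-weighted-mean gauge, for every drive in the
#' protocol. A single sparse Cholesky factorization is shared by all
#' right-hand sides.
#'
#' @param mesh an [build_mesh()] mesh.
#' @param gamma per-element conductivity (or a scalar), positive; relative
#'   units or S/m.
#' @param protocol an [make_protocol()] protocol (electrode count must match
#'   the mesh).
#' @return object of class `eit_fields`: the dense node-by-drive potential
#'   matrix plus provenance.
#' @export
solve_forward <- function(mesh, gamma, protocol) {
  stopifnot(inherits(mesh, "eit_mesh"), inherits(protocol, "eit_protocol"))
  if (protocol$E != mesh$electrodes$n) {
    stop_eit("protocol electrode count does not match the mesh",
             class = "eit_validation_error")
  }
  U <- fem_solve(mesh, gamma, protocol$drives, protocol$current)
  structure(list(U = U, Uel = as.matrix(mesh$fem$R %*% U),
                 gamma = gamma, current = protocol$current,
                 mesh_hash = mesh$hash, protocol_hash = protocol$hash),
            class = "eit_fields")
}

#' Solve a single drive pattern
#'
#' @param mesh an [build_mesh()] mesh.
#' @param gamma per-element (or scalar) positive conductivity.
#' @param drive length-2 vector of distinct drive electrode indices.
#' @param current drive current in mA.
#' @return nodal potential vector with a zero mass-weighted mean.
#' @export
solve_drive <- function(mesh, gamma, drive, current = 1) {
  stopifnot(inherits(mesh, "eit_mesh"))
  drive <- as.integer(drive)
  if (length(drive) != 2L || drive[1] == drive[2] ||
      any(drive < 1L) || any(drive > mesh$electrodes$n)) {
    stop_eit("drive must be two distinct electrode indices",
             class = "eit_validation_error")
  }
  drop(fem_solve(mesh, gamma, matrix(drive, 1L), current))
}

#' Assemble the ordered voltage vector from solved fields
#'
#' For each retained (drive, measurement) pair, the voltage is the
#' difference of electrode potentials, each taken as the arc average of the
#' nodal potential over the electrode with the same edge-length weights
#' used by the load assembly.
#'
#' @param fields an [solve_forward()] object (one field per drive).
#' @param protocol the protocol used to solve the fields.
#' @return object of class `eit_voltages`: the length-`M*` entries in
#'   canonical order plus the index table.
#' @export
measure_voltages <- function(fields, protocol) {
  stopifnot(inherits(fields, "eit_fields"), inherits(protocol, "eit_protocol"))
  if (!identical(fields$protocol_hash, protocol$hash)) {
    stop_eit("fields were solved under a different protocol",
             class = "eit_validation_error")
  }
  if (ncol(fields$U) != protocol$M) {
    stop_eit("need one solved field per drive", class = "eit_validation_error")
  }
  mesh_hash <- fields$mesh_hash
  Uel <- fields$Uel
  flat <- protocol$flat
  if (is.null(Uel)) {
    stop_eit("fields are missing electrode readouts; solve with solve_forward",
             class = "eit_validation_error")
  }
  V <- Uel[cbind(flat$ip, flat$drive)] - Uel[cbind(flat$im, flat$drive)]
  new_voltages(V, protocol, mesh_hash, normalized = FALSE)
}

new_voltages <- function(V, protocol, mesh_hash, normalized) {
  structure(list(V = as.numeric(V), index = protocol$flat,
                 M_star = protocol$M_star, normalized = normalized,
                 mesh_hash = mesh_hash, protocol_hash = protocol$hash),
            class = "eit_voltages")
}

#' @exportS3Method base::print
print.eit_voltages <- function(x, ...) {
  cat(sprintf("%s voltage vector: %d entries, range [%.4g, %.4g]\n",
              if (x$normalized) "Normalized" else "Measured",
              length(x$V), min(x$V), max(x$V)))
  invisible(x)
}

#' @export
as.numeric.eit_voltages <- function(x, ...) x$V

#' Energy bilinear form between two potential fields
#'
#' Computes `(1/I) * integral_Omega gamma grad(u_j) . grad(u_i) dr`, the
#' quantity that approximates the measured voltage `V[j,i]` and defines both
#' the normalization weights and the sensitivity matrix.
#'
#' @param mesh an [build_mesh()] mesh.
#' @param gamma per-element (or scalar) conductivity.
#' @param u_j,u_i nodal potential vectors on `mesh`.
#' @param current drive current in mA.
#' @return scalar energy value (positive when `u_j == u_i`).
#' @export
energy_form <- function(mesh, gamma, u_j, u_i, current = 1) {
  stopifnot(inherits(mesh, "eit_mesh"))
  fem <- mesh$fem
  if (length(u_j) != fem$n || length(u_i) != fem$n) {
    stop_eit("fields do not match the mesh node count",
             class = "eit_validation_error")
  }
  if (length(gamma) == 1L) gamma <- rep(gamma, fem$m)
  gxj <- as.vector(fem$Gx %*% u_j); gyj <- as.vector(fem$Gy %*% u_j)
  gxi <- as.vector(fem$Gx %*% u_i); gyi <- as.vector(fem$Gy %*% u_i)
  sum(gamma * mesh$areas * (gxj * gxi + gyj * gyi)) / current
}

#' Add multiplicative Gaussian noise to a voltage vector
#'
#' Entrywise `V * (1 + rel_level * z)` with `z` standard normal,
#' reproducible for a given seed. The global RNG state is not disturbed.
#'
#' @param V an `eit_voltages` object or numeric vector.
#' @param rel_level relative noise level (0 = identity).
#' @param seed integer seed (optional).
#' @return object of the same type as `V`.
#' @export
add_noise <- function(V, rel_level, seed = NULL) {
  if (rel_level < 0) stop_eit("rel_level must be >= 0",
                              class = "eit_validation_error")
  vals <- if (inherits(V, "eit_voltages")) V$V else as.numeric(V)
  if (rel_level > 0) {
    z <- with_seed(seed, stats::rnorm(length(vals)))
    vals <- vals * (1 + rel_level * z)
  }
  if (inherits(V, "eit_voltages")) {
    V$V <- vals
    V
  } else vals
}

#' Write a voltage vector to CSV
#'
#' Columns `jp, jm, ip, im, V`; provenance hashes and the normalization flag
#' are stored in `#`-prefixed header comments.
#'
#' @param V an `eit_voltages` object.
#' @param file output path.
#' @export
write_voltages <- function(V, file) {
  stopifnot(inherits(V, "eit_voltages"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# mesh_hash: %s", V$mesh_hash),
    sprintf("# protocol_hash: %s", V$protocol_hash),
    sprintf("# normalized: %s", V$normalized)
  ), con)
  df <- data.frame(jp = V$index$jp, jm = V$index$jm,
                   ip = V$index$ip, im = V$index$im, V = V$V)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' Read a voltage vector written by [write_voltages()]
#'
#' @param file CSV path.
#' @param protocol the matching protocol (index order is validated).
#' @return an `eit_voltages` object.
#' @export
read_voltages <- function(file, protocol) {
  hdr <- readLines(file, n = 3L)
  meta <- sub("^# [a-z_]+: ", "", hdr)
  df <- utils::read.csv(file, comment.char = "#")
  if (nrow(df) != protocol$M_star ||
      !all(df$jp == protocol$flat$jp & df$im == protocol$flat$im)) {
    stop_eit("voltage file does not match the protocol ordering",
             class = "eit_validation_error")
  }
  new_voltages(df$V, protocol, meta[1], identical(meta[3], "TRUE"))
}
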