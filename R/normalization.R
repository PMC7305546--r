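## Voltage normalization: homogeneous reference solutions and the
## entrywise map V -> Vhat = S / V that removes geometry and electrode
## dependency. For a homogeneous conductivity c the normalized data equal c
## in every entry, regardless of the body shape.

#' Homogeneous reference solution set
#'
#' Solves every drive pattern at unit conductivity on the given mesh and
#' assembles the reference energies
#' `S[j,i] = (1/I) * integral grad(v_j) . grad(v_i)`, the normalization
#' weights. Reference and measured data must come from the same
#' mesh/protocol/gauge so that discretization bias cancels in the ratio;
#' the object carries the mesh and protocol hashes to enforce this.
#'
#' @param mesh an [build_mesh()] mesh.
#' @param protocol an [make_protocol()] protocol.
#' @return object of class `eit_reference`: the full drive-by-drive energy
#'   matrix, the flat `S` vector in canonical voltage order, the unit-
#'   conductivity fields (reused by the sensitivity baseline), and the
#'   voltages measured at unit conductivity.
#' @export
reference_set <- function(mesh, protocol) {
  stopifnot(inherits(mesh, "eit_mesh"), inherits(protocol, "eit_protocol"))
  fields <- solve_forward(mesh, 1, protocol)
  K1 <- fem_assemble(mesh, 1)
  Emat <- as.matrix(Matrix::crossprod(fields$U, K1 %*% fields$U)) / protocol$current
  flat <- protocol$flat
  S <- Emat[cbind(flat$drive, flat$pair)]
  V1 <- measure_voltages(fields, protocol)
  structure(list(Emat = Emat, S = S, fields = fields, V1 = V1,
                 mesh_hash = mesh$hash, protocol_hash = protocol$hash),
            class = "eit_reference")
}

#' @exportS3Method base::print
print.eit_reference <- function(x, ...) {
  cat(sprintf("Homogeneous reference set: %d drives, %d normalization weights\n",
              ncol(x$Emat), length(x$S)))
  invisible(x)
}

#' Normalize a voltage vector
#'
#' Applies the entrywise normalization `Vhat[j,i] = S[j,i] / V[j,i]`. The
#' result is in conductivity units: for data simulated at a homogeneous
#' conductivity `c`, every entry of `Vhat` equals `c`; for layered
#' conductivities the entries behave as weighted harmonic averages and stay
#' between the extreme conductivity values.
#'
#' @param V an `eit_voltages` object (raw, same mesh/protocol as `ref`).
#' @param ref an [reference_set()] object.
#' @return normalized `eit_voltages`.
#' @export
normalize_voltages <- function(V, ref) {
  stopifnot(inherits(V, "eit_voltages"), inherits(ref, "eit_reference"))
  if (V$normalized) {
    stop_eit("voltages are already normalized", class = "eit_validation_error")
  }
  if (!identical(V$mesh_hash, ref$mesh_hash) ||
      !identical(V$protocol_hash, ref$protocol_hash)) {
    stop_eit("voltages and reference set come from different mesh/protocol ",
             "(provenance hash mismatch)", class = "eit_validation_error")
  }
  ## Index pairs whose reference weight is at roundoff scale are
  ## symmetry-degenerate: on a mirror-symmetric body with equally spaced
  ## electrodes both S and V vanish identically, so the ratio is a 0/0
  ## carrying no information. They are identified a priori from S alone.
  degen <- abs(ref$S) < 1e-6 * max(abs(ref$S))
  floor_v <- 1e-12 * max(abs(V$V))
  bad <- which(!degen & abs(V$V) <= floor_v)
  if (length(bad)) {
    ix <- V$index[bad[1], ]
    stop_eit(sprintf(
      "near-zero voltage at drive (%d,%d), measurement (%d,%d): cannot normalize",
      ix$jp, ix$jm, ix$ip, ix$im), class = "eit_nearzero_error")
  }
  out <- V
  out$V <- ref$S / V$V
  ## degenerate entries whose voltage also sits below the division floor
  ## are set to zero (deterministic, information-free) instead of a
  ## roundoff quotient
  out$V[degen & abs(V$V) <= floor_v] <- 0
  out$normalized <- TRUE
  out
}
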