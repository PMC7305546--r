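## Conventional comparator: the discretized sensitivity matrix linearized
## at homogeneous unit conductivity and a Tikhonov-regularized
## least-squares solve for the per-layer conductivity.

#' Assemble the layer sensitivity matrix
#'
#' Entry `(alpha, beta)` with `alpha = (j, i)` and `beta = l` is
#' `(1/I) * integral_{Omega_l} grad(u_j) . grad(u_i) dr`, the energy overlap
#' of the drive-`j` and drive-`i` unit-conductivity fields restricted to
#' layer `l`. Rows follow the canonical voltage ordering; row sums equal the
#' whole-domain energy form.
#'
#' @param mesh an [build_mesh()] mesh.
#' @param layers an [compute_layers()] partition on the same mesh.
#' @param protocol the measurement protocol.
#' @param ref a [reference_set()] on the same mesh/protocol (its unit-
#'   conductivity fields are the linearization point); computed if missing.
#' @return dense `M* x L` matrix of class `eit_sensitivity`.
#' @export
sensitivity_matrix <- function(mesh, layers, protocol, ref = NULL) {
  stopifnot(inherits(mesh, "eit_mesh"), inherits(layers, "eit_layers"),
            inherits(protocol, "eit_protocol"))
  if (!identical(layers$mesh_hash, mesh$hash)) {
    stop_eit("layer partition belongs to a different mesh",
             class = "eit_validation_error")
  }
  if (is.null(ref)) ref <- reference_set(mesh, protocol)
  if (!identical(ref$mesh_hash, mesh$hash)) {
    stop_eit("reference set belongs to a different mesh",
             class = "eit_validation_error")
  }
  fem <- mesh$fem
  U <- ref$fields$U
  GxU <- as.matrix(fem$Gx %*% U)
  GyU <- as.matrix(fem$Gy %*% U)
  L <- layers$L
  Pind <- sparseMatrix(i = seq_len(fem$m), j = layers$layer, x = 1,
                       dims = c(fem$m, L))
  flat <- protocol$flat
  S <- matrix(0, nrow = protocol$M_star, ncol = L)
  A <- mesh$areas
  for (j in seq_len(protocol$M)) {
    rows <- which(flat$drive == j)
    cols <- flat$pair[rows]
    W <- A * (GxU[, j] * GxU[, cols, drop = FALSE] +
                GyU[, j] * GyU[, cols, drop = FALSE])
    S[rows, ] <- as.matrix(Matrix::crossprod(Pind, W)) |> t()
  }
  S <- S / protocol$current
  structure(S, class = c("eit_sensitivity", "matrix"),
            mesh_hash = mesh$hash, protocol_hash = protocol$hash, L = L)
}

#' Regularized least-squares layer reconstruction
#'
#' Minimizes `0.5 * ||S g - V||^2 + 0.5 * lambda * g' R g` via the normal
#' equations `(S'S + lambda R) g = S'V`, with `R` the identity (plain
#' Tikhonov) or a first-difference smoothing penalty in layer index. This
#' is the conventional single-step linearized reconstruction the layered
#' MLP is compared against.
#'
#' @param S an [sensitivity_matrix()] (or plain `M* x L` matrix).
#' @param V an `eit_voltages` object or numeric vector of length `M*`.
#' @param lambda regularization weight; default `1e-3 * trace(S'S) / L`.
#' @param reg `"tikhonov_identity"` or `"tikhonov_smooth"`.
#' @return numeric length-`L` per-layer conductivity with attributes
#'   `lambda` and `objective`.
#' @export
reconstruct_ls <- function(S, V, lambda = NULL,
                           reg = c("tikhonov_identity", "tikhonov_smooth")) {
  reg <- match.arg(reg)
  Sm <- unclass(S)
  v <- if (inherits(V, "eit_voltages")) V$V else as.numeric(V)
  if (length(v) != nrow(Sm)) {
    stop_eit("voltage length does not match sensitivity rows",
             class = "eit_validation_error")
  }
  L <- ncol(Sm)
  StS <- crossprod(Sm)
  if (is.null(lambda)) lambda <- 1e-3 * sum(diag(StS)) / L
  check_positive(lambda, "lambda")
  R <- if (reg == "tikhonov_identity") {
    diag(L)
  } else {
    D <- diff(diag(L))
    crossprod(D)
  }
  g <- tryCatch(solve(StS + lambda * R, crossprod(Sm, v)),
                error = function(e) stop_eit("regularized system is singular: ",
                                             conditionMessage(e),
                                             class = "eit_numerical_error"))
  g <- drop(g)
  obj <- 0.5 * sum((Sm %*% g - v)^2) + 0.5 * lambda * sum(g * (R %*% g))
  attr(g, "lambda") <- lambda
  attr(g, "objective") <- obj
  g
}
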