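#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix sparseMatrix forceSymmetric Cholesky crossprod t solve
#' @importFrom stats rnorm runif sd spline approx
#' @importFrom utils head tail write.csv read.csv modifyList
NULL

## Content hash of an arbitrary R object (md5 of its version-2 serialization).
## Used to stamp meshes, protocols and datasets so that cross-stage
## provenance mismatches (e.g. voltages from one mesh fed to a reference
## set from another) are hard errors.
content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

stop_eit <- function(..., class) {
  stop(structure(
    class = c(class, "eit_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_eit(name, " must be a single positive finite number",
             class = "eit_validation_error")
  }
  invisible(x)
}

## Evaluate expr with a private RNG stream: the global .Random.seed is
## saved and restored, so seeded helpers do not perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}
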