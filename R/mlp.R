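## Multilayer-perceptron inverse map: a fully connected network from the
## normalized voltage vector (length M*) to the per-layer conductivity
## (length L), fit by sum-of-squared-errors. Following the layered-EIT
## formulation the network has no bias terms and applies the rectifier at
## every layer including the output; both choices can be relaxed by
## argument for ablations.

#' Initialize MLP weights
#'
#' Seeded He (variance-scaling) initialization: entries of the weight
#' matrix feeding layer `j+1` are drawn i.i.d. normal with standard
#' deviation `sqrt(2 / N_j)`, the standard scaling for rectifier networks.
#'
#' @param layer_sizes integer vector `(N_1, ..., N_J)`; `N_1` is the input
#'   (voltage) dimension and `N_J` the output (layer) dimension.
#' @param seed integer seed (reproducible; the global RNG is untouched).
#' @return list of `J-1` weight matrices, the `j`-th of shape
#'   `N_{j+1} x N_j`.
#' @export
mlp_init_weights <- function(layer_sizes, seed = 1L) {
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    stop_eit("need at least input and output layer, all sizes positive",
             class = "eit_validation_error")
  }
  J <- length(layer_sizes)
  with_seed(seed, lapply(seq_len(J - 1L), function(j) {
    matrix(stats::rnorm(layer_sizes[j + 1L] * layer_sizes[j],
                        sd = sqrt(2 / layer_sizes[j])),
           nrow = layer_sizes[j + 1L], ncol = layer_sizes[j])
  }))
}

#' Apply an MLP to inputs
#'
#' The forward pass `h_{J-1} o ... o h_1(x)` with
#' `h_j(o) = relu(W_j o)` (rectifier at every layer; optionally linear at
#' the output). Operates on a plain list of weight matrices, so it can be
#' used with hand-built toy networks as well as fitted models.
#'
#' @param weights list of weight matrices as in [mlp_init_weights()].
#' @param x numeric vector of length `N_1` or matrix with `N_1` columns
#'   (rows = cases).
#' @param output_activation `"relu"` (default) or `"linear"`.
#' @param biases optional list of bias vectors (one per weight matrix);
#'   NULL for the bias-free network.
#' @return matrix with `N_J` columns (or vector if `x` was a vector).
#' @export
mlp_apply <- function(weights, x, output_activation = c("relu", "linear"),
                      biases = NULL) {
  output_activation <- match.arg(output_activation)
  vec <- is.null(dim(x))
  A <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(A) != ncol(weights[[1L]])) {
    stop_eit(sprintf("input length %d does not match network input size %d",
                     ncol(A), ncol(weights[[1L]])),
             class = "eit_validation_error")
  }
  J1 <- length(weights)
  for (j in seq_len(J1)) {
    A <- tcrossprod(A, weights[[j]])
    if (!is.null(biases)) A <- sweep(A, 2L, biases[[j]], "+")
    if (j < J1 || output_activation == "relu") A[A < 0] <- 0
  }
  if (vec) drop(A) else A
}

## Forward pass keeping pre-activations for backprop.
mlp_forward_cache <- function(weights, X, output_relu, biases = NULL) {
  J1 <- length(weights)
  As <- vector("list", J1 + 1L)
  Zs <- vector("list", J1)
  As[[1L]] <- X
  for (j in seq_len(J1)) {
    Z <- tcrossprod(As[[j]], weights[[j]])
    if (!is.null(biases)) Z <- sweep(Z, 2L, biases[[j]], "+")
    Zs[[j]] <- Z
    if (j < J1 || output_relu) Z <- pmax(Z, 0)
    As[[j + 1L]] <- Z
  }
  list(As = As, Zs = Zs, out = As[[J1 + 1L]])
}

## Gradients of the summed squared error w.r.t. each weight matrix (and
## bias vector when biases are used).
mlp_backward <- function(weights, cache, Tgt, output_relu, with_bias = FALSE) {
  J1 <- length(weights)
  delta <- 2 * (cache$out - Tgt)
  if (output_relu) delta <- delta * (cache$Zs[[J1]] > 0)
  grads <- vector("list", J1)
  bgrads <- if (with_bias) vector("list", J1) else NULL
  for (j in rev(seq_len(J1))) {
    grads[[j]] <- crossprod(delta, cache$As[[j]])
    if (with_bias) bgrads[[j]] <- colSums(delta)
    if (j > 1L) delta <- (delta %*% weights[[j]]) * (cache$Zs[[j - 1L]] > 0)
  }
  list(W = grads, b = bgrads)
}

#' Fit the MLP inverse map
#'
#' Trains a fully connected rectifier network mapping voltage vectors to
#' per-layer conductivities by minimizing the summed squared error over the
#' training set, using adaptive-moment (Adam) stochastic gradient descent
#' with seeded shuffling. This is the model-fitting core of the package;
#' the fitted object supports `print`, `summary`, `coef`, `predict`,
#' `fitted`, `residuals` and `plot`.
#'
#' @param dataset an [generate_dataset()] object, or a list with elements
#'   `inputs` (N x M* matrix) and `targets` (N x L matrix).
#' @param hidden hidden layer sizes; default `c(512, 256, 128, 64, 32)`
#'   (five hidden layers, seven layers in total).
#' @param inputs train on `"normalized"` voltages (default) or `"raw"`
#'   ones (geometry-transfer ablation).
#' @param output_activation rectifier (default) or linear output layer.
#' @param bias add trainable bias vectors to every layer (default TRUE).
#'   The mathematical formulation is bias-free and `bias = FALSE`
#'   reproduces it exactly, but the bias-free form needs roughly three
#'   times the training budget for the same fit quality; see the methods
#'   vignette.
#' @param clip winsorization bounds applied to inputs before the network,
#'   in the input's own units. Normalized voltages are conductivity-unit
#'   quantities inside the training range except for symmetry-degenerate
#'   index pairs, whose unbounded roundoff quotients would otherwise
#'   dominate the first layer; the default `c(0, 20)` leaves all regular
#'   entries untouched. `NULL` disables. Stored in the model and applied
#'   by `predict` as well.
#' @param standardize center/scale inputs by their training column means
#'   and a global scale (default TRUE). With bias-free rectifier layers
#'   and all-positive conductivity-unit inputs most first-layer units are
#'   dead at initialization; centering restores sign diversity and is
#'   essential for the bias-free network to train.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam step size; halved every `lr_halve_every` epochs.
#' @param lr_halve_every step-decay interval in epochs.
#' @param validation_split fraction of rows held out for the validation
#'   curve (0 disables; the split is seeded and used for early stopping
#'   diagnostics only).
#' @param patience stop after this many epochs without validation
#'   improvement (ignored when `validation_split = 0`).
#' @param target_rmse stop once the training root-mean-square error per
#'   output entry falls below this value.
#' @param eval_every evaluate the training/validation losses every this
#'   many epochs (a full forward pass over the corpus costs about a third
#'   of an epoch, so per-epoch evaluation is wasteful on large runs).
#' @param restarts maximum number of fresh seeded re-initializations when
#'   a fit collapses (non-convex optimization occasionally lands on a
#'   degenerate optimum with several times the typical training error).
#' @param restart_rmse training RMSE above which a fit counts as
#'   collapsed and a restart is attempted.
#' @param seed seed controlling initialization, split and shuffling.
#' @param verbose print a line every 25 epochs.
#' @return object of class `eit_mlp`.
#' @export
eit_mlp <- function(dataset, hidden = c(512L, 256L, 128L, 64L, 32L),
                    inputs = c("normalized", "raw"),
                    output_activation = c("relu", "linear"),
                    bias = TRUE, clip = c(0, 20), standardize = TRUE,
                    epochs = 600L, batch_size = 128L, lr = 1e-3,
                    lr_halve_every = 150L, validation_split = 0.1,
                    patience = Inf, target_rmse = 0.03, eval_every = 10L,
                    restarts = 2L, restart_rmse = 1, seed = 1L,
                    verbose = FALSE) {
  inputs <- match.arg(inputs)
  output_activation <- match.arg(output_activation)
  X <- if (inherits(dataset, "eit_dataset")) {
    if (inputs == "normalized") dataset$inputs else dataset$raw
  } else dataset$inputs
  Tgt <- dataset$targets
  if (is.null(X) || is.null(Tgt) || nrow(X) != nrow(Tgt)) {
    stop_eit("dataset must provide row-aligned inputs and targets",
             class = "eit_validation_error")
  }
  if (inputs == "raw" && identical(clip, c(0, 20))) {
    ## the default clip bounds are on the conductivity scale and make no
    ## sense for raw voltages; scale them to the raw data range instead
    clip <- range(X)
  }
  prep <- list(clip = clip, center = NULL, scale = NULL)
  if (!is.null(clip)) X <- pmin(pmax(X, clip[1]), clip[2])
  ## centering needs at least two rows: with one, the centered input is
  ## identically zero and every rectifier unit is born dead
  if (standardize && nrow(X) >= 2L) {
    prep$center <- colMeans(X)
    prep$scale <- max(stats::sd(X), 1e-12)
    X <- (X - rep(prep$center, each = nrow(X))) / prep$scale
  }

  ## Non-convex fit: occasionally a seed lands on a collapsed optimum
  ## (training RMSE several times the typical value). Restart from fresh
  ## seeded initializations until the fit is acceptable; keep the best.
  best_fit <- NULL
  attempt_seeds <- seed + 100000L * (0:restarts)
  for (sk in attempt_seeds) {
    fit <- mlp_fit_once(X, Tgt, hidden, output_activation, bias, epochs,
                        batch_size, lr, lr_halve_every, validation_split,
                        patience, target_rmse, eval_every, sk, verbose)
    if (is.null(best_fit) || fit$train_rmse < best_fit$train_rmse) {
      best_fit <- fit
    }
    if (best_fit$train_rmse <= restart_rmse) break
    if (verbose && sk != attempt_seeds[length(attempt_seeds)]) {
      message(sprintf("  fit collapsed (train RMSE %.2f); restarting",
                      fit$train_rmse))
    }
  }
  fit <- best_fit

  fitted_all <- mlp_apply(fit$weights, X,
                          if (output_activation == "relu") "relu" else "linear",
                          fit$biases)
  structure(list(
    weights = fit$weights, biases = fit$biases, sizes = fit$sizes,
    activation = "relu",
    output_activation = output_activation, input_type = inputs,
    prep = prep,
    history = fit$history, fitted = fitted_all, targets = Tgt,
    d0 = if (inherits(dataset, "eit_dataset")) dataset$d0 else NA_real_,
    L = ncol(Tgt), M_star = ncol(X),
    hyper = list(epochs = epochs, batch_size = batch_size, lr = lr,
                 lr_halve_every = lr_halve_every, bias = bias,
                 standardize = standardize,
                 validation_split = validation_split, patience = patience,
                 target_rmse = target_rmse, attempts = fit$attempt),
    seed = seed,
    provenance = if (inherits(dataset, "eit_dataset")) dataset$provenance else NULL,
    dataset_hash = if (inherits(dataset, "eit_dataset")) dataset$hash else NULL
  ), class = "eit_mlp")
}

## One seeded optimization run; eit_mlp() wraps this with restarts.
mlp_fit_once <- function(X, Tgt, hidden, output_activation, bias, epochs,
                         batch_size, lr, lr_halve_every, validation_split,
                         patience, target_rmse, eval_every, seed, verbose) {
  N <- nrow(X)
  sizes <- c(ncol(X), as.integer(hidden), ncol(Tgt))
  weights <- mlp_init_weights(sizes, seed = seed)
  output_relu <- output_activation == "relu"
  J1 <- length(weights)
  if (output_relu && !bias) {
    ## With a rectified output and no bias, an output unit whose
    ## pre-activation is negative for every training case has zero gradient
    ## forever. Its inputs are post-rectifier (>= 0), so non-negative
    ## initial output weights keep every output unit alive at the start.
    weights[[J1]] <- abs(weights[[J1]])
  }
  biases <- if (bias) lapply(sizes[-1L], function(n) numeric(n)) else NULL

  idx_val <- if (validation_split > 0 && N >= 10L) {
    with_seed(seed + 1L, sample.int(N, max(1L, round(validation_split * N))))
  } else integer(0)
  idx_tr <- setdiff(seq_len(N), idx_val)
  Xtr <- X[idx_tr, , drop = FALSE]; Ttr <- Tgt[idx_tr, , drop = FALSE]
  Xva <- X[idx_val, , drop = FALSE]; Tva <- Tgt[idx_val, , drop = FALSE]
  ntr <- nrow(Xtr)

  mW <- lapply(weights, function(w) array(0, dim(w))); vW <- mW
  mB <- if (bias) lapply(biases, function(b) numeric(length(b))) else NULL
  vB <- mB
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  hist <- vector("list", epochs)
  best_val <- Inf; best_w <- weights; best_b <- biases; stall <- 0L
  n_entries_tr <- length(Ttr)
  oa <- if (output_relu) "relu" else "linear"

  for (ep in seq_len(epochs)) {
    lr_ep <- lr * 0.5^((ep - 1L) %/% lr_halve_every)
    ord <- with_seed(seed + 1000L + ep, sample.int(ntr))
    for (b0 in seq(1L, ntr, by = batch_size)) {
      rows <- ord[b0:min(b0 + batch_size - 1L, ntr)]
      cache <- mlp_forward_cache(weights, Xtr[rows, , drop = FALSE],
                                 output_relu, biases)
      grads <- mlp_backward(weights, cache, Ttr[rows, , drop = FALSE],
                            output_relu, with_bias = bias)
      step <- step + 1L
      cb1 <- 1 - b1^step; cb2 <- 1 - b2^step
      for (j in seq_along(weights)) {
        mW[[j]] <- b1 * mW[[j]] + (1 - b1) * grads$W[[j]]
        vW[[j]] <- b2 * vW[[j]] + (1 - b2) * grads$W[[j]]^2
        weights[[j]] <- weights[[j]] -
          lr_ep * (mW[[j]] / cb1) / (sqrt(vW[[j]] / cb2) + eps)
        if (bias) {
          mB[[j]] <- b1 * mB[[j]] + (1 - b1) * grads$b[[j]]
          vB[[j]] <- b2 * vB[[j]] + (1 - b2) * grads$b[[j]]^2
          biases[[j]] <- biases[[j]] -
            lr_ep * (mB[[j]] / cb1) / (sqrt(vB[[j]] / cb2) + eps)
        }
      }
    }
    if (ep %% eval_every != 0L && ep != epochs) next
    loss_tr <- sum((mlp_apply(weights, Xtr, oa, biases) - Ttr)^2)
    if (!is.finite(loss_tr)) {
      stop_eit("training diverged (loss is not finite); try a smaller lr",
               class = "eit_training_error")
    }
    loss_va <- if (length(idx_val)) {
      sum((mlp_apply(weights, Xva, oa, biases) - Tva)^2)
    } else NA_real_
    rmse_tr <- sqrt(loss_tr / n_entries_tr)
    hist[[ep]] <- c(epoch = ep, train_loss = loss_tr, val_loss = loss_va,
                    train_rmse = rmse_tr)
    if (verbose && ep %% 50L == 0L) {
      message(sprintf("  epoch %d: train SSE %.4g, RMSE %.4f", ep, loss_tr, rmse_tr))
    }
    if (length(idx_val)) {
      if (loss_va < best_val - 1e-12) {
        best_val <- loss_va; best_w <- weights; best_b <- biases; stall <- 0L
      } else {
        stall <- stall + eval_every
        if (stall >= patience) break
      }
    }
    if (rmse_tr < target_rmse) { best_w <- weights; best_b <- biases; break }
  }
  history <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
  use_best <- length(idx_val) && best_val < Inf &&
    history$train_rmse[nrow(history)] >= target_rmse
  final_w <- if (use_best) best_w else weights
  final_b <- if (use_best) best_b else biases
  final_rmse <- sqrt(sum((mlp_apply(final_w, Xtr, oa, final_b) - Ttr)^2) /
                       n_entries_tr)
  list(weights = final_w, biases = final_b, sizes = sizes,
       history = history, train_rmse = final_rmse, attempt = seed)
}

#' @exportS3Method base::print
print.eit_mlp <- function(x, ...) {
  cat(sprintf("EIT MLP inverse map: %s, %s inputs\n",
              paste(x$sizes, collapse = "-"), x$input_type))
  n <- nrow(x$history)
  if (n) cat(sprintf("  trained %d epochs, final train RMSE %.4f per layer value\n",
                     max(x$history$epoch), x$history$train_rmse[n]))
  invisible(x)
}

#' @exportS3Method base::summary
summary.eit_mlp <- function(object, ...) {
  res <- object$targets - object$fitted
  out <- list(
    sizes = object$sizes,
    n_weights = sum(vapply(object$weights, length, 1L)),
    input_type = object$input_type,
    epochs_run = nrow(object$history),
    final_train_rmse = sqrt(mean(res^2)),
    max_abs_residual = max(abs(res)),
    hyper = object$hyper
  )
  class(out) <- "summary.eit_mlp"
  out
}

#' @exportS3Method base::print
print.summary.eit_mlp <- function(x, ...) {
  cat(sprintf("EIT MLP %s (%d weights), %s inputs\n",
              paste(x$sizes, collapse = "-"), x$n_weights, x$input_type))
  cat(sprintf("  %d epochs; train RMSE %.4f; max |residual| %.3f\n",
              x$epochs_run, x$final_train_rmse, x$max_abs_residual))
  invisible(x)
}

#' @export
coef.eit_mlp <- function(object, ...) object$weights

#' Predict per-layer conductivities from voltage data
#'
#' @param object a fitted [eit_mlp()].
#' @param newdata numeric vector (length `M*`), matrix (`M*` columns), or
#'   an `eit_voltages` object whose normalization state must match the
#'   model's input type.
#' @param ... unused.
#' @return per-layer conductivity vector (or matrix, rows = cases).
#' @export
predict.eit_mlp <- function(object, newdata, ...) {
  if (inherits(newdata, "eit_voltages")) {
    want_norm <- object$input_type == "normalized"
    if (newdata$normalized != want_norm) {
      stop_eit(sprintf("model expects %s voltages but got %s ones",
                       object$input_type,
                       if (newdata$normalized) "normalized" else "raw"),
               class = "eit_validation_error")
    }
    newdata <- newdata$V
  }
  x <- newdata
  pr <- object$prep
  if (!is.null(pr$clip)) x <- pmin(pmax(x, pr$clip[1]), pr$clip[2])
  if (!is.null(pr$center)) {
    if (is.null(dim(x))) {
      x <- (x - pr$center) / pr$scale
    } else {
      x <- (x - rep(pr$center, each = nrow(x))) / pr$scale
    }
  }
  mlp_apply(object$weights, x, object$output_activation, object$biases)
}

#' @export
fitted.eit_mlp <- function(object, ...) object$fitted

#' @export
residuals.eit_mlp <- function(object, ...) object$targets - object$fitted

#' @export
plot.eit_mlp <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", log = "y",
                 xlab = "epoch", ylab = "summed squared error",
                 main = "MLP training curve", ...)
  if (!all(is.na(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  }
  invisible(x)
}

#' Evaluate a fitted model on labelled test rows
#'
#' For each test row: predict the layer profile, detect the fat and muscle
#' borders, and score the fat thickness and fat conductivity against the
#' truth as percentage errors.
#'
#' @param model a fitted [eit_mlp()].
#' @param test_inputs matrix of voltage vectors (matching the model's input
#'   type), rows = cases.
#' @param test_specs data.frame with at least `l_f` and `gamma_f` columns
#'   (true classes).
#' @param d0 layer thickness in cm (defaults to the model's).
#' @param min_jump border-detection threshold (relative jump).
#' @return data.frame with detected borders, estimates and percentage
#'   errors per row.
#' @export
evaluate_model <- function(model, test_inputs, test_specs, d0 = model$d0,
                           min_jump = 0.3) {
  pred <- predict(model, test_inputs)
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1L)
  n <- nrow(pred)
  out <- data.frame(l_f_true = test_specs$l_f,
                    l_f_hat = NA_integer_, l_m_hat = NA_integer_,
                    thickness_true = d0 * test_specs$l_f,
                    thickness_hat = NA_real_,
                    thickness_err_pct = NA_real_,
                    fat_cond_true = test_specs$gamma_f,
                    fat_cond_hat = NA_real_,
                    fat_cond_err_pct = NA_real_)
  for (k in seq_len(n)) {
    det <- detect_borders(pred[k, ], min_jump = min_jump)
    if (!is.na(det$l_f)) {
      out$l_f_hat[k] <- det$l_f
      out$l_m_hat[k] <- det$l_m
      out$thickness_hat[k] <- d0 * det$l_f
      out$thickness_err_pct[k] <-
        percentage_error(out$thickness_hat[k], out$thickness_true[k])
      out$fat_cond_hat[k] <- mean(pred[k, seq_len(det$l_f)])
      out$fat_cond_err_pct[k] <-
        percentage_error(out$fat_cond_hat[k], out$fat_cond_true[k])
    }
  }
  out
}
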