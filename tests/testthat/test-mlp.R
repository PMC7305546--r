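test_that("weight initialization is seeded with the stated shapes", {
  w <- mlp_init_weights(c(1260L, 512L, 256L, 128L, 64L, 32L, 15L), seed = 1)
  expect_length(w, 6L)
  expect_equal(dim(w[[1]]), c(512L, 1260L))
  expect_equal(dim(w[[6]]), c(15L, 32L))
  expect_identical(w, mlp_init_weights(c(1260L, 512L, 256L, 128L, 64L, 32L, 15L), seed = 1))
  expect_false(identical(w[[1]],
    mlp_init_weights(c(1260L, 512L, 256L, 128L, 64L, 32L, 15L), seed = 2)[[1]]))
  ## He scaling: empirical sd close to sqrt(2/N_in)
  expect_equal(sd(w[[1]]), sqrt(2 / 1260), tolerance = 0.01)
  expect_error(mlp_init_weights(c(5L)), class = "eit_validation_error")
})

test_that("forward pass equals a straight-line hand evaluation", {
  ## hand-computed 2-layer ReLU example
  w <- list(matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(mlp_apply(w, c(1, -1)), c(1, 0))
  ## all-zero weights give zero output
  wz <- list(matrix(0, 3, 4), matrix(0, 2, 3))
  expect_equal(mlp_apply(wz, runif(4)), c(0, 0))
  ## random 3-layer toy against an independent chain evaluation
  set.seed(5)
  w3 <- list(matrix(rnorm(12), 3, 4), matrix(rnorm(6), 2, 3))
  x <- rnorm(4)
  manual <- pmax(w3[[2]] %*% pmax(w3[[1]] %*% x, 0), 0)
  expect_equal(mlp_apply(w3, x), as.vector(manual), tolerance = 1e-12)
  ## linear output option skips the final rectifier
  manual_lin <- w3[[2]] %*% pmax(w3[[1]] %*% x, 0)
  expect_equal(mlp_apply(w3, x, "linear"), as.vector(manual_lin))
  expect_error(mlp_apply(w3, rnorm(3)), class = "eit_validation_error")
})

test_that("bias-free rectifier network is positively homogeneous", {
  ## forward(c*W, x) = c^(J-1) forward(W, x) for c > 0
  set.seed(9)
  w <- list(matrix(rnorm(20), 5, 4), matrix(rnorm(15), 3, 5))
  x <- rnorm(4)
  for (c0 in c(0.5, 2, 7)) {
    wc <- lapply(w, function(m) c0 * m)
    expect_equal(mlp_apply(wc, x), c0^2 * mlp_apply(w, x), tolerance = 1e-12)
  }
  ## and degree 1 in the input
  expect_equal(mlp_apply(w, 3 * x), 3 * mlp_apply(w, x), tolerance = 1e-12)
})

test_that("backpropagation gradients match finite differences", {
  set.seed(21)
  X <- matrix(runif(4 * 6, 0.5, 2), 4, 6)
  Tg <- matrix(runif(4 * 2, 1, 3), 4, 2)
  for (with_bias in c(FALSE, TRUE)) {
    w <- mlp_init_weights(c(6L, 5L, 2L), seed = 2)
    b <- if (with_bias) list(rnorm(5, sd = 0.1), rnorm(2, sd = 0.1)) else NULL
    cache <- eitfat:::mlp_forward_cache(w, X, TRUE, b)
    gr <- eitfat:::mlp_backward(w, cache, Tg, TRUE, with_bias = with_bias)
    loss <- function(w, b) sum((mlp_apply(w, X, "relu", b) - Tg)^2)
    h <- 1e-6
    for (j in 1:2) {
      for (k in 1:4) {
        wp <- w; wp[[j]][k] <- wp[[j]][k] + h
        wm <- w; wm[[j]][k] <- wm[[j]][k] - h
        expect_equal(gr$W[[j]][k], (loss(wp, b) - loss(wm, b)) / (2 * h),
                     tolerance = 1e-4)
      }
      if (with_bias) {
        bp <- b; bp[[j]][1] <- bp[[j]][1] + h
        bm <- b; bm[[j]][1] <- bm[[j]][1] - h
        expect_equal(gr$b[[j]][1], (loss(w, bp) - loss(w, bm)) / (2 * h),
                     tolerance = 1e-4)
      }
    }
  }
})

test_that("a small network memorizes a single training pair", {
  ## optimizer sanity check with a linear output layer: with a rectified
  ## output and a single sample, an output unit that starts negative is
  ## permanently dead, so memorization would be a coin flip
  set.seed(3)
  x <- matrix(runif(8, 1, 5), 1, 8)
  tgt <- matrix(c(1, 4, 2), 1, 3)
  m <- eit_mlp(list(inputs = x, targets = tgt), hidden = c(16L, 8L),
               output_activation = "linear", clip = NULL,
               epochs = 2000L, batch_size = 1L, lr = 1e-2,
               lr_halve_every = 1000L, validation_split = 0,
               target_rmse = 1e-3, eval_every = 5L, seed = 1)
  expect_lt(sum((predict(m, x) - tgt)^2), 1e-4)
})

test_that("training is deterministic given a seed and logs a decreasing loss", {
  kit <- tiny_model_kit()
  ds <- kit$ds
  m1 <- eit_mlp(ds, hidden = c(32L, 16L), epochs = 150L, eval_every = 1L,
                validation_split = 0, seed = 7)
  m2 <- eit_mlp(ds, hidden = c(32L, 16L), epochs = 150L, eval_every = 1L,
                validation_split = 0, seed = 7)
  expect_identical(m1$weights, m2$weights)
  ## loss non-increasing in at least 95% of logged steps
  d <- diff(m1$history$train_loss)
  expect_gte(mean(d <= 0), 0.95)
})

test_that("in-distribution rows recover their thickness class", {
  ## the miniature 16-row fixture model; the full-scale >=90% recovery
  ## property is exercised by the acceptance sweep
  kit <- tiny_model_kit()
  ev <- evaluate_model(kit$model, kit$ds$inputs, kit$specs, d0 = 0.3)
  expect_gte(mean(ev$l_f_hat == kit$specs$l_f, na.rm = TRUE), 0.8)
})

test_that("model methods expose the usual fitted-model surface", {
  kit <- tiny_model_kit()
  m <- kit$model
  expect_s3_class(m, "eit_mlp")
  expect_output(print(m), "MLP inverse map")
  s <- summary(m)
  expect_output(print(s), "weights")
  expect_length(coef(m), 3L)
  expect_equal(dim(fitted(m)), dim(kit$ds$targets))
  expect_equal(residuals(m), kit$ds$targets - fitted(m))
  ## predict on an eit_voltages object enforces normalization state
  V1 <- disk_coarse_ref()$V1
  expect_error(predict(m, V1), class = "eit_validation_error")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})

test_that("a non-finite training loss aborts with advice", {
  set.seed(4)
  X <- matrix(runif(40, 1, 10), 4, 10)
  X[2, 3] <- NaN
  ds <- list(inputs = X, targets = matrix(runif(12, 1, 10), 4, 3))
  expect_error(
    eit_mlp(ds, hidden = c(8L), clip = NULL, standardize = FALSE,
            epochs = 5L, validation_split = 0, eval_every = 1L,
            restarts = 0L),
    class = "eit_training_error")
})
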