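test_that("border detection finds constructed jumps and ignores flat profiles", {
  expect_equal(detect_borders(c(1, 1, 1, 5, 5, 2, rep(2, 9))),
               list(l_f = 3L, l_m = 5L))
  flat <- detect_borders(rep(2, 15))
  expect_true(is.na(flat$l_f) && is.na(flat$l_m))
  ## monotone noise below the threshold does not trigger
  expect_true(is.na(detect_borders(seq(1, 2, length.out = 15))$l_f))
  expect_error(detect_borders(c(1, 2)), class = "eit_validation_error")
})

test_that("border detection recovers every true layered profile", {
  ## self-consistency: the detector applied to the exact target vector
  ## recovers (l_f, l_m) whenever the profile has a genuine drop
  set.seed(31)
  n_ok <- 0L
  n <- 1000L
  pick <- function(x) x[sample.int(length(x), 1L)] # sample() mis-handles length-1 vectors
  for (k in seq_len(n)) {
    l_f <- pick(1:13)
    l_m <- pick((l_f + 1):14)
    gm <- runif(1, 2.4, 10)
    gr <- runif(1, 1.5, 0.65 * gm) # the muscle-rest drop stays above min_jump
    v <- c(rep(1, l_f), rep(gm, l_m - l_f), rep(gr, 15 - l_m))
    det <- detect_borders(v)
    if (identical(det$l_f, l_f) && identical(det$l_m, l_m)) n_ok <- n_ok + 1L
  }
  expect_equal(n_ok, n)
})

test_that("percentage errors are computed and validated", {
  expect_equal(percentage_error(2.1, 2.1), 0)
  expect_equal(percentage_error(0.6, 0.3), 100)
  expect_equal(percentage_error(0.3 * 11, 0.3 * 10), 10)
  expect_error(percentage_error(1, 0), class = "eit_validation_error")
})

test_that("reconstruct runs the full pipeline with provenance checks", {
  kit <- tiny_model_kit()
  k <- kit$kit
  sp <- layered_conductivity(6L, 10L, 1, 8, 5.5, 15L) # member of the tiny corpus
  sf <- spec_to_field(sp, k$layers)
  V <- measure_voltages(solve_forward(k$mesh, sf$field, k$protocol), k$protocol)
  rec <- reconstruct(V, kit$ref, kit$model, d0 = 0.3)
  expect_s3_class(rec, "eit_reconstruction")
  expect_equal(rec$l_f_hat, 6L)
  expect_equal(rec$fat_thickness_cm, 1.8)
  ## thickness is quantized to multiples of d0
  expect_equal(rec$fat_thickness_cm, 0.3 * rec$l_f_hat, tolerance = 1e-12)
  expect_equal(nrow(rec$profile), 15L)
  ## determinism
  rec2 <- reconstruct(V, kit$ref, kit$model, d0 = 0.3)
  expect_identical(rec$layer_values, rec2$layer_values)
  ## a flat profile yields the none-case: thickness reported as NA
  flat_model <- kit$model
  flat_model$weights <- list(matrix(0, 15L, kit$model$M_star))
  flat_model$biases <- NULL
  rech <- reconstruct(V, kit$ref, flat_model, d0 = 0.3)
  expect_true(is.na(rech$l_f_hat))
  expect_true(is.na(rech$fat_thickness_cm))
  ## mesh mix-up refused
  V_alien <- V; V_alien$mesh_hash <- "0000"
  expect_error(reconstruct(V_alien, kit$ref, kit$model),
               class = "eit_validation_error")
})

test_that("geometry transfer pipeline keeps targets fixed across input types", {
  kit <- tiny_model_kit()
  ## audit assertion: the raw- and normalized-input models are trained on
  ## the same corpus and targets; swapping the flag changes only inputs
  m_raw <- eit_mlp(kit$ds, inputs = "raw", hidden = c(32L, 16L),
                   epochs = 100L, validation_split = 0, seed = 7)
  expect_identical(m_raw$targets, kit$model$targets)
  expect_identical(m_raw$dataset_hash, kit$model$dataset_hash)
  expect_identical(m_raw$input_type, "raw")
})

test_that("robustness screen output is reproducible and well formed", {
  kit <- tiny_model_kit()
  k <- kit$kit
  r1 <- robustness_screen(kit$model, k$mesh, k$layers, k$protocol, kit$ref,
                          n_random = 10L, n_fields = 2L, n_controls = 2L,
                          seed = 5)
  r2 <- robustness_screen(kit$model, k$mesh, k$layers, k$protocol, kit$ref,
                          n_random = 10L, n_fields = 2L, n_controls = 2L,
                          seed = 5)
  expect_identical(r1$random_detected, r2$random_detected)
  expect_length(r1$random_detected, 10L)
  expect_gte(r1$fraction_negative_clean, 0)
  expect_lte(r1$fraction_negative_clean, 1)
  expect_output(print(r1), "Robustness screen")
})
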