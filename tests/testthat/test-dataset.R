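test_that("partition enumeration matches the closed form and brute force", {
  expect_equal(nrow(enumerate_partitions(15L)), 91L)
  expect_equal(enumerate_partitions(3L), data.frame(l_f = 1L, l_m = 2L))
  ## brute-force double loop oracle
  brute <- 0L
  for (a in 1:4) for (b in 1:4) if (a < b) brute <- brute + 1L
  expect_equal(nrow(enumerate_partitions(5L)), brute)
  p <- enumerate_partitions(15L)
  expect_true(all(p$l_f >= 1 & p$l_f < p$l_m & p$l_m <= 14))
  expect_error(enumerate_partitions(2L), class = "eit_validation_error")
})

test_that("conductivity grids reproduce the reference training design", {
  g <- enumerate_conductivities()
  expect_equal(length(unique(g$gamma_m)), 17L)
  expect_equal(length(unique(g$gamma_r)), 9L)
  expect_equal(nrow(g), 17L * 9L)
  ## full enumeration count 91 * 17 * 9
  expect_equal(nrow(enumerate_partitions(15L)) * nrow(g), 13923L)

  expect_equal(nrow(enumerate_conductivities(gamma_m = 5, gamma_r = 3)), 1L)
  ## ordering constraint filter, checked by enumeration
  g2 <- enumerate_conductivities(gamma_m = 2.0, gamma_r = c(1.5, 2.5),
                                 enforce_order = TRUE)
  expect_equal(nrow(g2), 1L)
  expect_equal(g2$gamma_r, 1.5)
  expect_error(enumerate_conductivities(gamma_m = 11),
               class = "eit_validation_error")
})

test_that("layered specifications build the stated fields and thicknesses", {
  k <- disk_coarse()
  sp <- layered_conductivity(3L, 7L, 1, 5, 2, 15L)
  sf <- spec_to_field(sp, k$layers)
  expect_equal(sf$target, c(rep(1, 3), rep(5, 4), rep(2, 8)))
  ## implied thicknesses at d0 = 0.3
  expect_equal(0.3 * sp$l_f, 0.9)
  expect_equal(0.3 * (sp$l_m - sp$l_f), 1.2)
  ## field is the target indexed by the element layer
  expect_equal(sf$field, sf$target[k$layers$layer])
  expect_error(layered_conductivity(5L, 5L, 1, 5, 2, 15L),
               class = "eit_validation_error")
  expect_error(layered_conductivity(1L, 2L, 1, 11, 2, 15L),
               class = "eit_validation_error")
})

test_that("dataset generation stores aligned, reproducible pairs", {
  k <- disk_coarse()
  ref <- disk_coarse_ref()
  specs <- data.frame(l_f = c(3L, 7L), l_m = c(8L, 14L), gamma_f = 1,
                      gamma_m = c(4, 6), gamma_r = c(2.5, 5.5))
  ds <- generate_dataset(k$mesh, k$layers, k$protocol, specs, ref = ref)
  expect_equal(dim(ds$inputs), c(2L, 1260L))
  expect_equal(dim(ds$targets), c(2L, 15L))
  expect_equal(ds$n_failed, 0L)
  ## bracketing of stored inputs on non-degenerate pairs
  ok <- abs(ref$S) >= 1e-6 * max(abs(ref$S))
  expect_true(all(ds$inputs[, ok] >= 0.95 & ds$inputs[, ok] <= 6 * 1.05))
  ## regenerating is bit-identical (hash equality)
  ds2 <- generate_dataset(k$mesh, k$layers, k$protocol, specs, ref = ref)
  expect_identical(ds$hash, ds2$hash)
  ## re-simulating a stored row reproduces the stored input
  sf <- spec_to_field(layered_conductivity(7L, 14L, 1, 6, 5.5, 15L), k$layers)
  V <- measure_voltages(solve_forward(k$mesh, sf$field, k$protocol), k$protocol)
  expect_equal(normalize_voltages(V, ref)$V, ds$inputs[2, ], tolerance = 1e-12)
  ## duplicates rejected
  expect_error(generate_dataset(k$mesh, k$layers, k$protocol,
                                rbind(specs, specs[1, ]), ref = ref),
               class = "eit_validation_error")
})

test_that("noisy generation is seed-reproducible", {
  k <- disk_coarse()
  ref <- disk_coarse_ref()
  specs <- data.frame(l_f = 5L, l_m = 10L, gamma_f = 1, gamma_m = 5,
                      gamma_r = 3)
  d1 <- generate_dataset(k$mesh, k$layers, k$protocol, specs, ref = ref,
                         noise = 0.01, seed = 3L)
  d2 <- generate_dataset(k$mesh, k$layers, k$protocol, specs, ref = ref,
                         noise = 0.01, seed = 3L)
  d3 <- generate_dataset(k$mesh, k$layers, k$protocol, specs, ref = ref,
                         noise = 0.01, seed = 4L)
  expect_identical(d1$hash, d2$hash)
  expect_false(identical(d1$hash, d3$hash))
})

test_that("dataset containers round-trip through disk", {
  kit <- tiny_model_kit()
  f <- tempfile(fileext = ".rds")
  write_dataset(kit$ds, f, csv_head = 3L)
  ds2 <- read_dataset(f)
  expect_identical(ds2$hash, kit$ds$hash)
  expect_true(file.exists(sub("\\.rds$", "_head.csv", f)))
})
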