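test_that("protocol combinatorics match brute-force enumeration", {
  for (E in c(4L, 5L, 10L)) {
    p <- make_protocol(E)
    bf <- brute_protocol_counts(E)
    expect_equal(p$M, unname(bf["drives"]))
    expect_equal(p$M_star, unname(bf["total"]))
    expect_equal(p$n_meas_per_drive, choose(E - 2, 2))
    ## drive/measurement disjointness (contact-impedance exclusion rule)
    expect_true(all(p$flat$ip != p$flat$jp & p$flat$ip != p$flat$jm &
                      p$flat$im != p$flat$jp & p$flat$im != p$flat$jm))
    ## lexicographic canonical order
    expect_true(all(diff(order(p$flat$drive, p$flat$ip, p$flat$im)) == 1L))
  }
  expect_error(make_protocol(3L), class = "eit_validation_error")
})

test_that("FEM disk solution matches the analytic series oracle", {
  k <- disk_coarse()
  mesh <- build_mesh(k$dom, k$el, h = 0.3)
  centers_theta <- k$el$centers / 10 # arc length to angle on r = 10
  u <- solve_drive(mesh, 1, c(1, 4), current = 1)
  Rm <- mesh$fem$R
  uel <- as.vector(Rm %*% u)
  for (meas in list(c(6, 9), c(7, 10), c(5, 8))) {
    v_fem <- uel[meas[1]] - uel[meas[2]]
    v_ser <- disk_series_voltage(10, 1, 1, centers_theta, 2,
                                 drive = c(1, 4), meas = meas)
    expect_lt(abs(v_fem - v_ser) / abs(v_ser), 0.01)
  }
})

test_that("FEM voltages converge to the analytic solution at order >= 1.5", {
  k <- disk_coarse()
  centers_theta <- k$el$centers / 10
  v_ser <- disk_series_voltage(10, 1, 1, centers_theta, 2,
                               drive = c(1, 4), meas = c(6, 9))
  hs <- c(0.6, 0.3, 0.15)
  errs <- vapply(hs, function(h) {
    mesh <- build_mesh(k$dom, k$el, h = h)
    u <- solve_drive(mesh, 1, c(1, 4), 1)
    uel <- as.vector(mesh$fem$R %*% u)
    abs(uel[6] - uel[9] - v_ser)
  }, 1)
  orders <- diff(log(errs)) / diff(log(hs))
  expect_gte(min(orders), 1.5)
})

test_that("reciprocity holds to solver precision", {
  ref <- disk_coarse_ref()
  p <- disk_coarse()$protocol
  V <- ref$V1$V
  key <- paste(p$flat$drive, p$flat$pair)
  m <- match(paste(p$flat$pair, p$flat$drive), key)
  expect_lt(max(abs(V - V[m])) / max(abs(V)), 1e-8)
})

test_that("voltages scale inversely with conductivity", {
  k <- disk_coarse()
  ref <- disk_coarse_ref()
  V1 <- ref$V1$V
  for (c0 in c(0.5, 2, 10)) {
    Vc <- measure_voltages(solve_forward(k$mesh, c0, k$protocol), k$protocol)$V
    expect_lt(max(abs(Vc - V1 / c0)) / max(abs(V1 / c0)), 1e-10)
  }
})

test_that("load vectors conserve current and potentials have zero mean", {
  k <- disk_coarse()
  Fm <- eitfat:::fem_loads(k$mesh, k$protocol$drives, 1)
  expect_lt(max(abs(colSums(Fm))), 1e-12)
  u <- solve_drive(k$mesh, 1, c(2, 7), 1)
  mass <- k$mesh$fem$mass
  expect_lt(abs(sum(u * mass) / sum(mass)) / max(abs(u)), 1e-10)
})

test_that("energy form approximates voltages and is bilinear", {
  k <- disk_coarse()
  ref <- disk_coarse_ref()
  U <- ref$fields$U
  ## diagonal: positive
  e11 <- energy_form(k$mesh, 1, U[, 1], U[, 1], 1)
  expect_gt(e11, 0)
  ## off-diagonal against the measured voltage (discretely exact here by
  ## load/readout duality; 2% bound is the analytic relation)
  i <- which(k$protocol$flat$drive == 1)[10]
  fl <- k$protocol$flat[i, ]
  e <- energy_form(k$mesh, 1, U[, 1], U[, fl$pair], 1)
  expect_equal(e, ref$V1$V[i], tolerance = 0.02)
  ## doubling gamma with fields fixed doubles the value
  expect_equal(energy_form(k$mesh, 2, U[, 1], U[, 2], 1),
               2 * energy_form(k$mesh, 1, U[, 1], U[, 2], 1),
               tolerance = 1e-12)
  expect_error(energy_form(k$mesh, 1, U[1:10, 1], U[, 2], 1),
               class = "eit_validation_error")
})

test_that("solver rejects invalid conductivities and drives", {
  k <- disk_coarse()
  expect_error(solve_forward(k$mesh, -1, k$protocol),
               class = "eit_validation_error")
  expect_error(solve_forward(k$mesh, c(1, 2), k$protocol),
               class = "eit_validation_error")
  expect_error(solve_drive(k$mesh, 1, c(3, 3)),
               class = "eit_validation_error")
})

test_that("multiplicative noise is seeded, reproducible and calibrated", {
  ref <- disk_coarse_ref()
  V <- ref$V1
  expect_identical(add_noise(V, 0, seed = 1)$V, V$V)
  n1 <- add_noise(V, 0.02, seed = 7)$V
  n2 <- add_noise(V, 0.02, seed = 7)$V
  expect_identical(n1, n2)
  expect_false(identical(n1, add_noise(V, 0.02, seed = 8)$V))
  ## sample std of the relative perturbation approximates the level
  expect_equal(sd(n1 / V$V - 1), 0.02, tolerance = 0.1)
})

test_that("voltage vectors round-trip through CSV with provenance", {
  k <- disk_coarse()
  ref <- disk_coarse_ref()
  f <- tempfile(fileext = ".csv")
  write_voltages(ref$V1, f)
  V2 <- read_voltages(f, k$protocol)
  expect_equal(V2$V, ref$V1$V, tolerance = 1e-12)
  expect_identical(V2$mesh_hash, ref$V1$mesh_hash)
  expect_false(V2$normalized)
})
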