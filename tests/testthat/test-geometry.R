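test_that("domain constructors give correct perimeter, area and validation", {
  d <- make_domain("disk", radius = 10)
  expect_equal(d$perimeter, 2 * pi * 10, tolerance = 1e-5)
  expect_equal(d$area, pi * 100, tolerance = 1e-4)

  e <- make_domain("ellipse")
  expect_equal(e$area, pi * 15 * 9, tolerance = 1e-4)

  expect_error(make_domain("disk", radius = -1), class = "eit_validation_error")
  expect_error(make_domain("ellipse", a = 0), class = "eit_validation_error")
})

test_that("abdomen outline is a smooth star-shaped surrogate with sane area", {
  a <- make_domain("abdomen")
  ## ~30 cm wide, ~20 cm deep
  xr <- range(a$dense[, "x"]); yr <- range(a$dense[, "y"])
  expect_equal(diff(xr), 30, tolerance = 0.05 * 30)
  expect_equal(diff(yr), 20, tolerance = 0.08 * 20)
  ## area within 10% of the reference ellipse of the same bounding box,
  ## checked against an independent shoelace computation
  ell_area <- pi * diff(xr) / 2 * diff(yr) / 2
  sa <- shoelace_area(a$dense[, c("x", "y")])
  expect_equal(a$area, sa, tolerance = 1e-8)
  expect_lt(abs(a$area - ell_area) / ell_area, 0.10)
})

test_that("self-intersecting control polygons are rejected", {
  bad <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1)) * 10 # bow-tie
  expect_error(make_domain("abdomen", control = rbind(bad, bad + 0.01)),
               class = "eit_geometry_error")
})

test_that("electrode placement spaces electrodes evenly and checks packing", {
  d <- make_domain("disk", radius = 10)
  el <- place_electrodes(d, 10L, width = 1, arc_span = 1)
  gaps <- diff(c(el$centers, el$centers[1] + d$perimeter)) - 1
  expect_equal(gaps, rep((2 * pi * 10 - 10) / 10, 10), tolerance = 1e-5)

  ## a third of the boundary: all centers inside a 120-degree arc
  el3 <- place_electrodes(d, 10L, width = 0.8, arc_span = 1 / 3)
  span <- (max(el3$centers) - min(el3$centers)) %% d$perimeter
  expect_lt(span, d$perimeter / 3)

  expect_error(place_electrodes(d, 2L, width = 40),
               class = "eit_geometry_error")
})

test_that("fixed-pitch belts cover the same arc length on any body", {
  d <- make_domain("disk", radius = 10)
  e <- make_domain("ellipse")
  for (dom in list(d, e)) {
    el <- place_electrodes(dom, 10L, width = 2, pitch = 3.5)
    expect_equal(el$span_len, 9 * 3.5 + 2)
    ## circular gaps: 9 pitch-sized gaps plus one wrap-around remainder
    circ <- diff(c(sort(el$centers), sort(el$centers)[1] + dom$perimeter))
    expect_equal(sort(circ)[1:9], rep(3.5, 9), tolerance = 1e-5)
    expect_equal(max(circ), dom$perimeter - 9 * 3.5, tolerance = 1e-5)
  }
  ## a belt longer than the boundary cannot be placed
  small <- make_domain("disk", radius = 4)
  expect_error(place_electrodes(small, 10L, width = 2, pitch = 3.5),
               class = "eit_geometry_error")
})

test_that("meshes are conforming with labelled, refined electrode edges", {
  k <- disk_coarse()
  mesh <- k$mesh
  expect_true(all(mesh$areas > 0))
  ## every electrode covered by >= 4 boundary edges, refined to <= h/2
  be <- mesh$boundary_edges
  for (e in 1:10) {
    ed <- be[be$electrode == e, ]
    expect_gte(nrow(ed), 4L)
    expect_lte(max(ed$length), mesh$h / 2 + 1e-9)
  }
  ## total labelled arc length equals E * width
  expect_equal(sum(be$length[be$electrode > 0]), 10 * 2, tolerance = 1e-3)
  expect_error(build_mesh(k$dom, k$el, h = -1), class = "eit_validation_error")
})

test_that("mesh refinement changes a fixed voltage by under 1 percent", {
  k <- disk_coarse()
  ref1 <- disk_coarse_ref()
  mesh2 <- build_mesh(k$dom, k$el, h = 0.3)
  ref2 <- reference_set(mesh2, k$protocol)
  ## compare a well-separated, non-degenerate voltage entry
  i <- which(k$protocol$flat$jp == 1 & k$protocol$flat$jm == 2 &
               k$protocol$flat$ip == 5 & k$protocol$flat$im == 6)
  v1 <- ref1$V1$V[i]
  v2 <- ref2$V1$V[i]
  expect_lt(abs(v1 - v2) / abs(v2), 0.01)
})

test_that("disk layers are concentric annuli with half-open assignment", {
  k <- disk_coarse()
  layers <- k$layers
  r <- sqrt(rowSums(k$mesh$centroids^2))
  ## annulus membership from exact radii (half-open [d0(l-1), d0 l) depth)
  expected <- pmin(15L, floor((10 - r) / 0.3) + 1L)
  expect_equal(layers$layer, expected)
  ## partition property: disjoint and exhaustive by construction
  expect_equal(sort(unique(layers$layer)), 1:15)
  expect_equal(sum(tabulate(layers$layer, 15L)), nrow(k$mesh$triangles))
  expect_error(compute_layers(k$mesh, d0 = 0.3, L = 2L),
               class = "eit_validation_error")
  expect_error(compute_layers(k$mesh, d0 = 1, L = 12L),
               class = "eit_validation_error") # 11 cm exceeds inradius
})

test_that("disk layer areas match annulus areas within mesh error", {
  ## at h = 0.3 the ring spacing (h/2) aligns two element rows per layer
  k <- disk_coarse()
  mesh <- build_mesh(k$dom, k$el, h = 0.3)
  layers <- compute_layers(mesh, d0 = 0.3, L = 15L)
  radii <- 10 - 0.3 * (0:14)
  ann <- pi * (radii[-15]^2 - (radii[-15] - 0.3)^2)
  expect_equal(layers$layer_areas[1:14], ann, tolerance = 0.02)
})

test_that("abdomen layers are restricted to the frontal sector", {
  dom <- make_domain("abdomen")
  el <- place_electrodes(dom, 10L, width = 2, arc_span = 0.45)
  mesh <- build_mesh(dom, el, h = 0.8)
  layers <- compute_layers(mesh, d0 = 0.3, L = 15L)
  expect_identical(layers$roi, "frontal")
  ## elements well below the centroid (back side) all belong to layer L
  back <- mesh$centroids[, 2] < dom$centroid[2] - 2
  expect_true(all(layers$layer[back] == 15L))
  ## frontal near-boundary elements are layered
  front <- mesh$centroids[, 2] > dom$centroid[2] + 2
  expect_true(any(layers$layer[front] < 15L))
})

test_that("mesh round-trips through Gmsh MSH export", {
  k <- disk_coarse()
  f <- tempfile(fileext = ".msh")
  write_mesh_msh(k$mesh, f)
  lines <- readLines(f)
  expect_equal(lines[1], "$MeshFormat")
  n_nodes <- as.integer(lines[5])
  expect_equal(n_nodes, nrow(k$mesh$nodes))
  ## element count: boundary edges + triangles
  i_el <- which(lines == "$Elements")
  expect_equal(as.integer(lines[i_el + 1L]),
               nrow(k$mesh$boundary_edges) + nrow(k$mesh$triangles))
})
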