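## Geometry: 2D imaging domains, electrode placement, structured meshing,
## and distance-to-boundary layer partitions.
##
## All domains are star-shaped with respect to their centroid, which makes
## both the ray-based structured mesher and the distance-to-boundary layer
## partition well defined.

N_DENSE <- 8192L

#' Construct a 2D imaging domain
#'
#' Builds a closed, star-shaped imaging domain: a disk, an ellipse, or a
#' smooth abdomen-like outline interpolated through control points. All
#' lengths are in centimetres. The boundary is stored as a dense arc-length
#' parametrized polyline from which electrode positions, meshes and
#' distance computations are derived.
#'
#' @param kind one of `"disk"`, `"ellipse"`, `"abdomen"`.
#' @param radius disk radius (cm).
#' @param a,b ellipse semi-axes (cm). The default 15 x 9 cm semi-axes give
#'   a 30 x 18 cm body, comparable to an abdominal cross-section (and to
#'   the default abdomen outline).
#' @param control for `kind = "abdomen"`, a two-column matrix of control
#'   points forming a simple closed loop (do not repeat the first point).
#'   Default: a smooth outline about 30 cm wide and 20 cm deep.
#' @return an object of class `eit_domain` with the boundary polyline,
#'   perimeter, enclosed area and centroid.
#' @examples
#' d <- make_domain("disk", radius = 10)
#' d$perimeter  # 2*pi*10
#' @export
make_domain <- function(kind = c("disk", "ellipse", "abdomen"),
                        radius = 10, a = 15, b = 9, control = NULL) {
  kind <- match.arg(kind)
  if (kind == "disk") {
    check_positive(radius, "radius")
    th <- seq(0, 2 * pi, length.out = N_DENSE + 1L)
    xy <- cbind(radius * cos(th), radius * sin(th))
    params <- list(radius = radius)
  } else if (kind == "ellipse") {
    check_positive(a, "a")
    check_positive(b, "b")
    th <- seq(0, 2 * pi, length.out = N_DENSE + 1L)
    xy <- cbind(a * cos(th), b * sin(th))
    params <- list(a = a, b = b)
  } else {
    if (is.null(control)) control <- abdomen_control_points()
    control <- as.matrix(control)
    if (ncol(control) != 2L || nrow(control) < 6L) {
      stop_eit("abdomen control points must be an n x 2 matrix, n >= 6",
               class = "eit_validation_error")
    }
    xy <- spline_outline(control)
    params <- list(control = control)
  }
  centroid <- polygon_centroid(xy)
  ## star-shapedness: radius about the centroid must stay positive and the
  ## polar angle must wind exactly once
  rel <- sweep(xy[-nrow(xy), , drop = FALSE], 2, centroid)
  rho <- sqrt(rowSums(rel^2))
  if (any(rho <= 0)) {
    stop_eit("degenerate outline: boundary touches its centroid",
             class = "eit_geometry_error")
  }
  ang <- atan2(rel[, 2], rel[, 1])
  wind <- sum(diff(c(ang, ang[1])) %% (2 * pi) %% (2 * pi))
  if (abs(abs(wind) - 2 * pi) > 1e-6 * 2 * pi) {
    stop_eit("outline is not star-shaped about its centroid ",
             "(polar angle does not wind monotonically)",
             class = "eit_geometry_error")
  }
  area <- polygon_area(xy)
  if (area <= 0) {
    stop_eit("outline encloses no area or is negatively oriented",
             class = "eit_geometry_error")
  }
  seg <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seg))
  structure(list(
    kind = kind, params = params,
    dense = cbind(s = s, x = xy[, 1], y = xy[, 2]),
    perimeter = s[length(s)],
    area = area,
    centroid = centroid,
    min_ray = min(rho)
  ), class = "eit_domain")
}

## Default abdomen outline: a smooth superellipse-like closed curve,
## width ~30 cm, depth ~20 cm, slightly flattened at the back. This is a
## synthetic parametric stand-in for a CT-derived abdominal cross-section.
abdomen_control_points <- function(n = 24L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  p <- 2.4
  rho <- (abs(cos(th) / 15)^p + abs(sin(th) / 10)^p)^(-1 / p)
  ## flatten the back (negative y) a little
  rho <- rho * (1 - 0.06 * pmax(0, -sin(th)))
  cbind(rho * cos(th), rho * sin(th))
}

## Periodic cubic spline through closed control points, in polar form about
## their centroid (guarantees a simple star-shaped outline).
spline_outline <- function(control, n_out = N_DENSE) {
  c0 <- colMeans(control)
  rel <- sweep(control, 2, c0)
  th <- atan2(rel[, 2], rel[, 1])
  rho <- sqrt(rowSums(rel^2))
  o <- order(th)
  th <- th[o]; rho <- rho[o]
  if (anyDuplicated(signif(th, 12))) {
    stop_eit("abdomen control points do not form a simple loop ",
             "(duplicate polar angles)", class = "eit_geometry_error")
  }
  thp <- c(th, th[1] + 2 * pi)
  rhop <- c(rho, rho[1])
  tt <- seq(th[1], th[1] + 2 * pi, length.out = n_out + 1L)
  rr <- stats::spline(thp, rhop, xout = tt, method = "periodic")$y
  if (any(rr <= 0)) {
    stop_eit("splined outline self-intersects (non-positive radius)",
             class = "eit_geometry_error")
  }
  cbind(c0[1] + rr * cos(tt), c0[2] + rr * sin(tt))
}

polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  0.5 * abs(sum(x[-n] * y[-1] - x[-1] * y[-n]))
}

polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  cr <- x[-n] * y[-1] - x[-1] * y[-n]
  A <- sum(cr) / 2
  c(sum((x[-n] + x[-1]) * cr), sum((y[-n] + y[-1]) * cr)) / (6 * A)
}

## Point on the boundary at arc length s (vectorized, s taken mod perimeter).
boundary_point <- function(domain, s) {
  P <- domain$perimeter
  s <- s %% P
  d <- domain$dense
  x <- stats::approx(d[, "s"], d[, "x"], xout = s, rule = 2)$y
  y <- stats::approx(d[, "s"], d[, "y"], xout = s, rule = 2)$y
  cbind(x, y)
}

#' @exportS3Method base::print
print.eit_domain <- function(x, ...) {
  cat(sprintf("EIT imaging domain: %s\n", x$kind))
  cat(sprintf("  perimeter %.2f cm, area %.1f cm^2, centroid (%.2f, %.2f)\n",
              x$perimeter, x$area, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Place surface electrodes on a domain boundary
#'
#' Places `n` equal-width electrodes centered on the front of the body.
#' By default the belt has a fixed center-to-center `pitch` in cm,
#' emulating an electrode array mounted on a rigid curved plate: the same
#' physical belt applied to different bodies covers the same arc length,
#' which is what makes normalized data comparable across geometries.
#' Alternatively `arc_span` spreads the electrodes equally over that
#' fraction of the whole boundary (1 = all the way around).
#'
#' The belt is centered on the frontal (largest-y) boundary point: the
#' flat front of the abdomen outline, the flat minor-axis end of an
#' ellipse (an abdomen lies with its wide axis horizontal), any point of
#' a disk.
#'
#' @param domain an [make_domain()] object.
#' @param n number of electrodes (10 in the reference configuration).
#' @param width electrode width along the boundary, cm.
#' @param pitch center-to-center electrode distance, cm (default 3.5,
#'   i.e. a 33.5 cm belt for 10 electrodes of 2 cm). Ignored when
#'   `arc_span` is given.
#' @param arc_span fraction of the boundary covered by the electrode
#'   belt; overrides `pitch`.
#' @return object of class `eit_electrodes`: ordered electrode centers (arc
#'   length), width and the covered span.
#' @export
place_electrodes <- function(domain, n = 10L, width = 2, pitch = 3.5,
                             arc_span = NULL) {
  stopifnot(inherits(domain, "eit_domain"))
  n <- as.integer(n)
  if (n < 2L) stop_eit("need at least 2 electrodes",
                       class = "eit_validation_error")
  check_positive(width, "width")
  P <- domain$perimeter
  d <- domain$dense
  s_front <- d[which.max(d[, "y"]), "s"]
  if (!is.null(arc_span)) {
    if (arc_span <= 0 || arc_span > 1) {
      stop_eit("arc_span must be in (0, 1]", class = "eit_validation_error")
    }
    A <- arc_span * P
    if (n * width >= A) {
      stop_eit(sprintf(
        "electrodes overlap: %d electrodes of width %.2f cm do not fit in a %.2f cm arc",
        n, width, A), class = "eit_geometry_error")
    }
    s0 <- s_front - A / 2
    centers <- (s0 + (seq_len(n) - 0.5) * A / n) %% P
  } else {
    check_positive(pitch, "pitch")
    if (pitch <= width) {
      stop_eit("electrodes overlap: pitch must exceed the electrode width",
               class = "eit_geometry_error")
    }
    A <- (n - 1L) * pitch + width
    if (A >= P) {
      stop_eit(sprintf(
        "electrode belt (%.1f cm) does not fit on the boundary (%.1f cm)",
        A, P), class = "eit_geometry_error")
    }
    centers <- (s_front + (seq_len(n) - (n + 1) / 2) * pitch) %% P
    s0 <- s_front - A / 2
  }
  o <- order(centers)
  structure(list(
    n = n, centers = centers[o], width = width,
    arc_span = A / P, pitch = if (is.null(arc_span)) pitch else NA_real_,
    span_start = s0 %% P, span_len = A,
    domain_kind = domain$kind
  ), class = "eit_electrodes")
}

#' @exportS3Method base::print
print.eit_electrodes <- function(x, ...) {
  cat(sprintf("%d electrodes, width %.2f cm, covering %.0f%% of the boundary\n",
              x$n, x$width, 100 * x$arc_span))
  invisible(x)
}

#' Build a structured triangular finite-element mesh
#'
#' Generates a conforming triangulation of a star-shaped domain by offsetting
#' the boundary discretization inward along rays toward the centroid:
#' fine rings of spacing `h/2` near the boundary (where the layered
#' conductivity model lives), geometrically coarsening rings toward the
#' interior, and a central fan. Electrode arcs are refined to edge length
#' at most `h/2` and their endpoints coincide with mesh nodes, so boundary
#' edges carry exact electrode labels.
#'
#' @param domain an [make_domain()] object.
#' @param electrodes an [place_electrodes()] object.
#' @param h target boundary edge length, cm (default 0.3).
#' @param fine_depth depth of the finely ringed band, cm; defaults to
#'   `min(4.5, 0.8 * r_min)` where `r_min` is the shortest centroid ray,
#'   enough for 15 layers of 0.3 cm.
#' @param grade geometric coarsening factor for interior ring spacing.
#' @return object of class `eit_mesh`: nodes, triangles, labelled boundary
#'   edges, element areas/centroids, and precomputed FEM assembly arrays.
#' @export
build_mesh <- function(domain, electrodes, h = 0.3,
                       fine_depth = NULL, grade = 1.6) {
  stopifnot(inherits(domain, "eit_domain"),
            inherits(electrodes, "eit_electrodes"))
  check_positive(h, "h")
  P <- domain$perimeter
  w <- electrodes$width

  ## --- boundary discretization: electrode arcs at <= h/2, gaps at <= h ---
  n_el <- electrodes$n
  starts <- (electrodes$centers - w / 2) %% P
  ends <- (electrodes$centers + w / 2) %% P
  s_nodes <- numeric(0)
  lab_of_edge_start <- NULL
  for (e in seq_len(n_el)) {
    ne <- max(4L, ceiling(w / (h / 2)))
    s_nodes <- c(s_nodes, (starts[e] + (0:(ne - 1L)) * w / ne))
    ## include the end point; dedup handles coincidences
    s_nodes <- c(s_nodes, ends[e])
  }
  ## gaps between consecutive electrode ends and next starts
  o <- order(starts)
  for (k in seq_len(n_el)) {
    e <- o[k]; e2 <- o[if (k == n_el) 1L else k + 1L]
    gap <- (starts[e2] - ends[e]) %% P
    if (gap < 1e-9) next
    ng <- max(1L, ceiling(gap / h))
    if (ng > 1L) {
      s_nodes <- c(s_nodes, (ends[e] + (1:(ng - 1L)) * gap / ng) %% P)
    }
  }
  s_nodes <- sort(unique(round(s_nodes %% P, 9)))
  ## drop nearly-coincident nodes (can arise from the modular wrap)
  keep <- c(TRUE, diff(s_nodes) > 1e-7)
  s_nodes <- s_nodes[keep]
  Nb <- length(s_nodes)
  bxy <- boundary_point(domain, s_nodes)

  ## --- ring depth schedule ---
  cxy <- domain$centroid
  rays <- cbind(bxy[, 1] - cxy[1], bxy[, 2] - cxy[2])
  raylen <- sqrt(rowSums(rays^2))
  uhat <- rays / raylen
  minray <- min(raylen)
  if (is.null(fine_depth)) fine_depth <- min(4.5, 0.8 * minray)
  fine_depth <- min(fine_depth, 0.8 * minray)
  delta <- h / 2
  depths <- seq(delta, fine_depth, by = delta)
  ## graded rings continue until the central fan has radius ~2h along the
  ## shortest ray, so the fan region refines together with the rest of
  ## the mesh
  dmax <- min(0.98 * minray, minray - 2 * h)
  ## graded steps are capped at 2h so deep-interior cells refine with h
  ## (unbounded geometric growth would leave an h-independent radial size
  ## there and stall the convergence of boundary voltages)
  step <- delta
  d <- depths[length(depths)]
  while (TRUE) {
    step <- min(step * grade, 2 * h)
    d <- min(d + step, dmax)
    if (d <= depths[length(depths)] + 0.25 * delta) break
    depths <- c(depths, d)
    if (d >= dmax) break
  }
  K <- length(depths)

  ## --- nodes: boundary ring, K inner rings, centroid ---
  nodes <- matrix(0, nrow = (K + 1L) * Nb + 1L, ncol = 2L)
  nodes[seq_len(Nb), ] <- bxy
  for (k in seq_len(K)) {
    nodes[k * Nb + seq_len(Nb), ] <- bxy - depths[k] * uhat
  }
  nid_center <- (K + 1L) * Nb + 1L
  nodes[nid_center, ] <- cxy

  ## --- triangles ---
  i1 <- seq_len(Nb)
  i2 <- c(2:Nb, 1L)
  tri <- vector("list", K + 1L)
  for (k in 0:(K - 1L)) {
    a <- k * Nb + i1; b <- k * Nb + i2
    c2 <- (k + 1L) * Nb + i2; d2 <- (k + 1L) * Nb + i1
    tri[[k + 1L]] <- rbind(cbind(a, b, c2), cbind(a, c2, d2))
  }
  tri[[K + 1L]] <- cbind(K * Nb + i1, K * Nb + i2, nid_center)
  triangles <- do.call(rbind, tri)
  dimnames(triangles) <- NULL

  ## orient positively and validate areas
  x1 <- nodes[triangles[, 1], 1]; y1 <- nodes[triangles[, 1], 2]
  x2 <- nodes[triangles[, 2], 1]; y2 <- nodes[triangles[, 2], 2]
  x3 <- nodes[triangles[, 3], 1]; y3 <- nodes[triangles[, 3], 2]
  a2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  flip <- a2 < 0
  if (any(flip)) {
    tmp <- triangles[flip, 2]
    triangles[flip, 2] <- triangles[flip, 3]
    triangles[flip, 3] <- tmp
    a2 <- abs(a2)
  }
  areas <- a2 / 2
  if (any(areas <= 1e-10)) {
    stop_eit(sprintf("meshing produced %d degenerate triangles (min area %.2e)",
                     sum(areas <= 1e-10), min(areas)),
             class = "eit_meshing_error")
  }
  centroids <- cbind((x1 + x2 + x3) / 3, (y1 + y2 + y3) / 3)

  ## --- boundary edges with electrode labels ---
  ## midpoint arc position of each boundary edge (wrap on the closing edge)
  mid_s <- ifelse(i2 == 1L,
                  ((s_nodes[i1] + s_nodes[1] + P) / 2) %% P,
                  (s_nodes[i1] + s_nodes[i2]) / 2)
  lab <- integer(Nb)
  for (e in seq_len(n_el)) {
    inside <- ((mid_s - starts[e]) %% P) < w
    lab[inside] <- e
  }
  elen <- sqrt(rowSums((bxy[i2, , drop = FALSE] - bxy[i1, , drop = FALSE])^2))
  boundary_edges <- data.frame(n1 = i1, n2 = i2, length = elen,
                               electrode = lab, mid_s = mid_s)
  cnt <- tabulate(lab, nbins = n_el)
  if (any(cnt < 4L)) {
    stop_eit("an electrode is covered by fewer than 4 boundary edges",
             class = "eit_meshing_error")
  }

  mesh <- structure(list(
    nodes = nodes, triangles = triangles,
    areas = areas, centroids = centroids,
    boundary_edges = boundary_edges,
    boundary_s = s_nodes,
    n_boundary = Nb, n_rings = K, depths = depths,
    domain = domain, electrodes = electrodes, h = h
  ), class = "eit_mesh")
  mesh$fem <- fem_precompute(mesh)
  mesh$hash <- content_hash(list(nodes, triangles, lab, electrodes$n))
  mesh
}

## Precompute P1 FEM assembly arrays: per-element stiffness triplets at unit
## conductivity, element gradient operators, electrode averaging matrix and
## lumped mass vector.
fem_precompute <- function(mesh) {
  tr <- mesh$triangles
  nd <- mesh$nodes
  m <- nrow(tr)
  n <- nrow(nd)
  x <- matrix(nd[tr, 1], ncol = 3)
  y <- matrix(nd[tr, 2], ncol = 3)
  ## gradient coefficients: b_i = y_j - y_k, c_i = x_k - x_j
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2])
  cc <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1])
  A <- mesh$areas
  ## local stiffness (unit conductivity): K_ij = (b_i b_j + c_i c_j) / (4A)
  ii <- jj <- vv <- vector("list", 9L)
  idx <- 1L
  for (i in 1:3) for (j in 1:3) {
    ii[[idx]] <- tr[, i]
    jj[[idx]] <- tr[, j]
    vv[[idx]] <- (b[, i] * b[, j] + cc[, i] * cc[, j]) / (4 * A)
    idx <- idx + 1L
  }
  trip_i <- unlist(ii); trip_j <- unlist(jj)
  trip_v <- unlist(vv); trip_e <- rep(seq_len(m), times = 9L)
  ## element gradient operators Gx, Gy (m x n): grad u on element e
  Gx <- sparseMatrix(i = rep(seq_len(m), 3L), j = as.vector(tr),
                     x = as.vector(b) / (2 * A), dims = c(m, n))
  Gy <- sparseMatrix(i = rep(seq_len(m), 3L), j = as.vector(tr),
                     x = as.vector(cc) / (2 * A), dims = c(m, n))
  ## electrode averaging matrix R (E x n): arc average with edge-length
  ## weights; the same weights define the load vector, so readout and load
  ## are exactly dual.
  be <- mesh$boundary_edges
  E <- mesh$electrodes$n
  Rw <- matrix(0, nrow = E, ncol = n)
  widths <- numeric(E)
  for (e in seq_len(E)) {
    ed <- be[be$electrode == e, ]
    widths[e] <- sum(ed$length)
    wts <- ed$length / 2
    for (k in seq_len(nrow(ed))) {
      Rw[e, ed$n1[k]] <- Rw[e, ed$n1[k]] + wts[k]
      Rw[e, ed$n2[k]] <- Rw[e, ed$n2[k]] + wts[k]
    }
    Rw[e, ] <- Rw[e, ] / widths[e]
  }
  Rmat <- as(Rw, "CsparseMatrix")
  ## lumped mass (node area weights) for the zero-mean gauge
  tt <- as.vector(tr)
  mass <- as.vector(Matrix::sparseMatrix(i = tt, j = rep(1L, length(tt)),
                                         x = rep(A / 3, 3L), dims = c(n, 1L)))
  list(trip_i = trip_i, trip_j = trip_j, trip_v = trip_v, trip_e = trip_e,
       Gx = Gx, Gy = Gy, R = Rmat, widths = widths, mass = mass, n = n, m = m)
}

#' @exportS3Method base::print
print.eit_mesh <- function(x, ...) {
  cat(sprintf("EIT FE mesh on a %s domain: %d nodes, %d triangles, h = %.2f cm\n",
              x$domain$kind, nrow(x$nodes), nrow(x$triangles), x$h))
  cat(sprintf("  %d boundary nodes, %d rings, %d electrodes\n",
              x$n_boundary, x$n_rings, x$electrodes$n))
  invisible(x)
}

#' @export
plot.eit_mesh <- function(x, layers = NULL, ...) {
  tr <- x$triangles
  nd <- x$nodes
  col <- if (!is.null(layers)) {
    pal <- grDevices::hcl.colors(layers$L, "viridis")
    pal[layers$layer]
  } else NA
  graphics::plot(nd, type = "n", asp = 1, xlab = "x (cm)", ylab = "y (cm)", ...)
  for (k in seq_len(nrow(tr))) {
    graphics::polygon(nd[tr[k, ], 1], nd[tr[k, ], 2],
                      border = grDevices::grey(0.7), lwd = 0.3,
                      col = if (is.null(layers)) NA else col[k])
  }
  be <- x$boundary_edges
  el <- be[be$electrode > 0, ]
  graphics::segments(nd[el$n1, 1], nd[el$n1, 2], nd[el$n2, 1], nd[el$n2, 2],
                     col = "red", lwd = 3)
  invisible(x)
}

#' Partition mesh elements into distance-to-boundary layers
#'
#' Assigns every element to one of `L` disjoint layers of thickness `d0` by
#' the distance of its centroid to the domain boundary, using the half-open
#' convention: layer `l` collects centroids with distance in
#' `[d0*(l-1), d0*l)`, and layer `L` absorbs everything deeper. For abdomen
#' domains only the frontal sector under the electrode belt is layered
#' (measured voltages are insensitive to conductivity far from the
#' electrodes); elements outside it are assigned to layer `L`. Disks and
#' ellipses are layered all around (concentric annuli / offset bands).
#'
#' @param mesh an [build_mesh()] mesh.
#' @param d0 layer thickness, cm (default 0.3).
#' @param L number of layers (default 15; at least 3 for fat, muscle, rest).
#' @param roi `"auto"` (frontal for abdomen, full otherwise), `"full"`, or
#'   `"frontal"`.
#' @return object of class `eit_layers` with per-element layer indices and
#'   per-layer areas.
#' @export
compute_layers <- function(mesh, d0 = 0.3, L = 15L, roi = c("auto", "full", "frontal")) {
  stopifnot(inherits(mesh, "eit_mesh"))
  roi <- match.arg(roi)
  check_positive(d0, "d0")
  L <- as.integer(L)
  if (L < 3L) {
    stop_eit("need at least 3 layers (fat, muscle, rest)",
             class = "eit_validation_error")
  }
  minray <- min(sqrt(rowSums(sweep(mesh$nodes[seq_len(mesh$n_boundary), ],
                                   2, mesh$domain$centroid)^2)))
  if (d0 * (L - 1L) >= minray) {
    stop_eit(sprintf("d0*(L-1) = %.2f cm exceeds the domain inradius %.2f cm",
                     d0 * (L - 1L), minray), class = "eit_validation_error")
  }
  db <- dist_to_boundary(mesh)
  layer <- pmin(L, floor(db$dist / d0) + 1L)
  frontal <- if (roi == "frontal" || (roi == "auto" && mesh$domain$kind == "abdomen")) TRUE else FALSE
  if (frontal) {
    el <- mesh$electrodes
    P <- mesh$domain$perimeter
    in_span <- ((db$near_s - el$span_start) %% P) <= el$span_len
    layer[!in_span | db$dist >= d0 * L] <- L
  }
  areas <- as.vector(tapply(mesh$areas, factor(layer, levels = seq_len(L)), sum))
  areas[is.na(areas)] <- 0
  structure(list(L = L, d0 = d0, layer = layer, roi = if (frontal) "frontal" else "full",
                 layer_areas = areas, dist = db$dist, mesh_hash = mesh$hash),
            class = "eit_layers")
}

#' @exportS3Method base::print
print.eit_layers <- function(x, ...) {
  cat(sprintf("%d distance-to-boundary layers of %.2f cm (%s region)\n",
              x$L, x$d0, x$roi))
  cat("  elements per layer:", paste(tabulate(x$layer, x$L), collapse = " "), "\n")
  invisible(x)
}

## Distance from each element centroid to the boundary polyline, plus the
## arc position of the nearest boundary segment (used for the frontal ROI).
dist_to_boundary <- function(mesh) {
  be <- mesh$boundary_edges
  nd <- mesh$nodes
  px <- mesh$centroids[, 1]; py <- mesh$centroids[, 2]
  best <- rep(Inf, length(px))
  near_s <- numeric(length(px))
  for (k in seq_len(nrow(be))) {
    x1 <- nd[be$n1[k], 1]; y1 <- nd[be$n1[k], 2]
    x2 <- nd[be$n2[k], 1]; y2 <- nd[be$n2[k], 2]
    vx <- x2 - x1; vy <- y2 - y1
    L2 <- vx * vx + vy * vy
    t <- pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / L2))
    dx <- px - (x1 + t * vx); dy <- py - (y1 + t * vy)
    d2 <- dx * dx + dy * dy
    upd <- d2 < best
    best[upd] <- d2[upd]
    near_s[upd] <- be$mid_s[k]
  }
  list(dist = sqrt(best), near_s = near_s)
}

#' Write a mesh to Gmsh MSH 2.2 ASCII format
#'
#' Boundary edges are written as 2-node line elements with their electrode
#' label as physical tag (0 off-electrode); triangles as 3-node elements.
#'
#' @param mesh an [build_mesh()] mesh.
#' @param file output path.
#' @export
write_mesh_msh <- function(mesh, file) {
  nd <- mesh$nodes; tr <- mesh$triangles; be <- mesh$boundary_edges
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(nd))), con)
  writeLines(sprintf("%d %.10g %.10g 0", seq_len(nrow(nd)), nd[, 1], nd[, 2]), con)
  writeLines(c("$EndNodes", "$Elements",
               as.character(nrow(be) + nrow(tr))), con)
  writeLines(sprintf("%d 1 2 %d 0 %d %d", seq_len(nrow(be)),
                     be$electrode, be$n1, be$n2), con)
  writeLines(sprintf("%d 2 2 0 0 %d %d %d", nrow(be) + seq_len(nrow(tr)),
                     tr[, 1], tr[, 2], tr[, 3]), con)
  writeLines("$EndElements", con)
  invisible(file)
}
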