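## Independent oracles used across the test suite.

## Analytic Fourier-series solution for the Neumann problem on a
## homogeneous disk of radius R and conductivity gam: uniform current
## density +I/w on the arc of electrode p, -I/w on electrode q.
## Returns the arc-average potential over a measurement electrode arc.
## Series truncated at n_modes (default 400; coefficients decay like 1/n^2).
disk_series_voltage <- function(R, gam, I, centers_theta, width_cm,
                                drive, meas, n_modes = 400L) {
  w_ang <- width_cm / R # electrode angular width
  n <- seq_len(n_modes)
  ## a_n = (1/pi) int g(theta) cos(n theta) dtheta with g = I/width on the
  ## arc (per unit arc length; the theta integral needs no extra factor R)
  g_coef <- function(center) {
    t1 <- center - w_ang / 2
    t2 <- center + w_ang / 2
    list(a = I / (pi * width_cm) * (sin(n * t2) - sin(n * t1)) / n,
         b = I / (pi * width_cm) * (cos(n * t1) - cos(n * t2)) / n)
  }
  cp <- g_coef(centers_theta[drive[1]])
  cm <- g_coef(centers_theta[drive[2]])
  a <- cp$a - cm$a
  b <- cp$b - cm$b
  ## u(R, theta) = sum R/(n gam) (a_n cos + b_n sin); arc average over
  ## [t1,t2] integrates cos/sin analytically.
  arc_avg <- function(center) {
    t1 <- center - w_ang / 2
    t2 <- center + w_ang / 2
    ca <- (sin(n * t2) - sin(n * t1)) / (n * (t2 - t1))
    cb <- (cos(n * t1) - cos(n * t2)) / (n * (t2 - t1))
    sum((R / (n * gam)) * (a * ca + b * cb))
  }
  arc_avg(centers_theta[meas[1]]) - arc_avg(centers_theta[meas[2]])
}

## Brute-force enumeration of the pairwise protocol (used to check the
## drive/measurement combinatorics independently of make_protocol).
brute_protocol_counts <- function(E) {
  drives <- 0L
  meas_total <- 0L
  for (p in 1:(E - 1)) for (q in (p + 1):E) {
    drives <- drives + 1L
    rem <- setdiff(1:E, c(p, q))
    for (i in seq_along(rem)) for (j in seq_along(rem)) {
      if (i < j) meas_total <- meas_total + 1L
    }
  }
  c(drives = drives, total = meas_total)
}

## Shoelace polygon area on a dense boundary polyline.
shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  0.5 * abs(sum(x[-n] * y[-1] - x[-1] * y[-n]))
}

## Dense grid search minimizer of the regularized LS objective for tiny
## problems (oracle for reconstruct_ls).
grid_search_ls <- function(S, v, lambda, lo = -2, hi = 4, n = 81L) {
  g1 <- seq(lo, hi, length.out = n)
  best <- NULL; best_f <- Inf
  for (x1 in g1) for (x2 in g1) {
    g <- c(x1, x2)
    f <- 0.5 * sum((S %*% g - v)^2) + 0.5 * lambda * sum(g^2)
    if (f < best_f) { best_f <- f; best <- g }
  }
  list(par = best, value = best_f)
}
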