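test_that("von Mises sampler: uniform at kappa 0, concentrated at large kappa", {
  set.seed(11)
  # kappa = 0: Rayleigh test on the doubled angles must not reject
  # uniformity (statistic 2 n Rbar^2 ~ chi^2_2 under H0)
  th <- sample_fiber_angles(10000, mean = 0.7, kappa = 0)
  stat <- 2 * 10000 * axial_resultant(th)^2
  expect_lt(stat, qchisq(0.99, df = 2))
  expect_true(all(th > -pi / 2 & th <= pi / 2))

  # kappa = 100: axial mean within ~2 SE of the target mean
  th <- sample_fiber_angles(10000, mean = 0, kappa = 100)
  expect_lt(abs(angle_diff(axial_mean(th), 0)), 0.02)

  # degenerate concentration collapses on the mean
  th <- sample_fiber_angles(1000, mean = 0.3, kappa = 1e8)
  expect_lt(max(abs(angle_diff(th, 0.3))), 1e-3)

  expect_error(sample_fiber_angles(10, 0, kappa = -1), "kappa")
})

test_that("von Mises sampler matches the target density (chi-square fit)", {
  set.seed(12)
  kappa <- 3; mu <- 0.5
  x <- rvonmises(20000, mu = mu, kappa = kappa)
  breaks <- seq(-pi, pi, length.out = 37)
  obs <- table(cut(x - mu + 2 * pi * ((x - mu) < -pi) -
                     2 * pi * ((x - mu) > pi), breaks))
  dens <- function(t) exp(kappa * cos(t)) / (2 * pi * besselI(kappa, 0))
  p <- vapply(seq_len(36), function(i)
    integrate(dens, breaks[i], breaks[i + 1])$value, numeric(1))
  stat <- sum((as.numeric(obs) - 20000 * p)^2 / (20000 * p))
  expect_lt(stat, qchisq(0.999, df = 35))
})

test_that("delaunay reproduces the empty-circumcircle oracle", {
  brute_delaunay <- function(x, y) {
    n <- length(x); out <- NULL
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      d <- 2 * (x[i] * (y[j] - y[k]) + x[j] * (y[k] - y[i]) +
                  x[k] * (y[i] - y[j]))
      if (abs(d) < 1e-12) next
      a2 <- x[i]^2 + y[i]^2; b2 <- x[j]^2 + y[j]^2; c2 <- x[k]^2 + y[k]^2
      ux <- (a2 * (y[j] - y[k]) + b2 * (y[k] - y[i]) + c2 * (y[i] - y[j])) / d
      uy <- (a2 * (x[k] - x[j]) + b2 * (x[i] - x[k]) + c2 * (x[j] - x[i])) / d
      r2 <- (ux - x[i])^2 + (uy - y[i])^2
      o <- setdiff(seq_len(n), c(i, j, k))
      if (all((x[o] - ux)^2 + (y[o] - uy)^2 > r2 * (1 - 1e-12)))
        out <- rbind(out, c(i, j, k))
    }
    out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
  }
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(6:20, 1)
    x <- c(0, 1, 0, 1, runif(n - 4)); y <- c(0, 0, 1, 1, runif(n - 4))
    expect_identical(unname(delaunay(x, y)), unname(brute_delaunay(x, y)))
  }
  # four corners alone: two triangles covering the rectangle
  expect_equal(nrow(delaunay(c(0, 2, 0, 2), c(0, 0, 1, 1))), 2)
  expect_error(delaunay(c(0, 1, 2), c(0, 1, 2)), "collinear")
  expect_error(delaunay(c(0, 0, 1), c(0, 0, 1)), "duplicate")
})

test_that("fiber fields interpolate angles pi-periodically and in-hull", {
  f <- fiber_field(100, 100, mean_direction = 0.2, kappa = 5, seed = 3,
                   n_vertices = 60)
  # query at a vertex returns that vertex's angle
  for (i in c(1, 5, 20)) {
    expect_equal(query_fiber_angle(f, f$vx[i], f$vy[i]), f$angle[i],
                 tolerance = 1e-9)
  }
  # constant field: any interior point returns the constant
  fc <- fiber_field(10, 10, 0, kappa = 1, seed = 1, n_vertices = 5)
  fc$angle[] <- 0.77
  qs <- cbind(runif(50, 0, 10), runif(50, 0, 10))
  expect_equal(query_fiber_angle(fc, qs[, 1], qs[, 2]), rep(0.77, 50))

  # centroid of a triangle with angles (0, 0.3, 0.6): axial mean 0.3
  f3 <- fiber_field(1, 1, 0, kappa = 1, seed = 1, n_vertices = 3)
  tri1 <- f3$tri[1, ]
  f3$angle[tri1] <- c(0, 0.3, 0.6)
  cx <- mean(f3$vx[tri1]); cy <- mean(f3$vy[tri1])
  expect_equal(query_fiber_angle(f3, cx, cy), 0.3, tolerance = 1e-6)

  # interpolated angle lies in the axial hull of its triangle's vertices
  set.seed(31)
  f2 <- fiber_field(50, 50, 0.1, kappa = 2, seed = 9, n_vertices = 40)
  for (rep in 1:200) {
    px <- runif(1, 0, 50); py <- runif(1, 0, 50)
    a <- query_fiber_angle(f2, px, py)
    t <- vsmcabm:::locate_triangle(f2, px, py)
    va <- f2$angle[f2$tri[t, ]]
    ref <- axial_mean(va)
    spread <- max(abs(angle_diff(va, ref)))
    expect_lte(abs(angle_diff(a, ref)), spread + 1e-9)
  }
  expect_error(query_fiber_angle(f2, -1, 5), "outside")
})

test_that("field generation is reproducible and concentrates as kappa grows", {
  fa <- fiber_field(200, 200, 0.3, kappa = 5, seed = 42)
  fb <- fiber_field(200, 200, 0.3, kappa = 5, seed = 42)
  expect_identical(fa, fb)

  # vertex angles are exact von Mises draws: kappa recovers within 30%
  k_vertex <- axial_concentration(fa$angle)
  expect_lt(abs(k_vertex - 5) / 5, 0.30)
  # dense queries: shape-function interpolation averages angles within each
  # triangle, so the field is smoother than its vertex draws and the
  # re-estimated concentration is biased upward (observed ~1.7x at the
  # default vertex density); it must stay the same order of magnitude
  set.seed(8)
  qx <- runif(10000, 0, 200); qy <- runif(10000, 0, 200)
  ang <- query_fiber_angle(fa, qx, qy)
  k_hat <- axial_concentration(ang)
  expect_gt(k_hat, 0.9 * k_vertex)
  expect_lt(k_hat, 2.5 * 5)

  fhigh <- fiber_field(200, 200, 0.3, kappa = 1e8, seed = 4)
  ang <- query_fiber_angle(fhigh, qx[1:500], qy[1:500])
  expect_lt(max(abs(angle_diff(ang, 0.3))), 1e-3)
})
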