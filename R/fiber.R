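#' Specify a fiber field for a simulation
#'
#' Configuration stub consumed by [simulation_config()]: the field itself is
#' synthesised at run time (one fresh field per run, mimicking construct-to-
#' construct variability in decellularized tissue).
#'
#' @param mean_deg mean fiber axis in degrees (0 = along x, i.e. along a
#'   strain applied in x; 90 = perpendicular).
#' @param kappa von Mises concentration of the fiber orientations.
#' @param density scalar fiber density phi_f in \[0, 1\]: 0 for bare
#'   elastomer (PDMS), 1 for dense decellularized collagenous tissue.
#' @param n_vertices number of random interior mesh vertices per field (the
#'   four domain corners are always added).
#' @return a `fiber_spec` list.
#' @export
fiber_spec <- function(mean_deg = 0, kappa = 5, density = 1, n_vertices = 200) {
  stopifnot(is.finite(mean_deg), kappa >= 0, density >= 0, density <= 1,
            n_vertices >= 3)
  structure(list(mean_deg = mean_deg, kappa = kappa, density = density,
                 n_vertices = as.integer(n_vertices)),
            class = "fiber_spec")
}

#' Build a continuous 2D fiber-orientation field
#'
#' Scatters `n_vertices` uniform random vertices over the rectangle (plus its
#' four corners so the triangulation covers the whole domain), assigns each
#' vertex an independent axial von Mises draw, and Delaunay-triangulates the
#' vertex set. Queries interpolate vertex angles with linear shape functions
#' (barycentric weights) inside the containing triangle, performed on
#' doubled-angle unit vectors so the interpolation is pi-periodic-safe.
#'
#' @param width,height domain size (micrometres).
#' @param mean_direction mean fiber axis, radians.
#' @param kappa von Mises concentration, `>= 0`.
#' @param density scalar fiber density phi_f in \[0, 1\].
#' @param n_vertices number of random interior vertices.
#' @param seed integer seed making the field reproducible; ignored when an
#'   internal `stream` is supplied.
#' @param stream optional internal RNG stream.
#' @return an object of class `fiber_field`.
#' @seealso [query_fiber_angle()], [fiber_grid()]
#' @export
#' @examples
#' f <- fiber_field(1000, 1000, mean_direction = 0, kappa = 5, seed = 1)
#' query_fiber_angle(f, 500, 500)
fiber_field <- function(width, height, mean_direction = 0, kappa = 5,
                        density = 1, n_vertices = 200, seed = 1,
                        stream = NULL) {
  stopifnot(width > 0, height > 0, kappa >= 0, n_vertices >= 3)
  if (is.null(stream)) stream <- new_stream(seed)
  for (attempt in 1:5) {
    vx <- c(0, width, 0, width, st_runif(stream, n_vertices, 0, width))
    vy <- c(0, 0, height, height, st_runif(stream, n_vertices, 0, height))
    tri <- tryCatch(delaunay(vx, vy), error = function(e) NULL)
    if (!is.null(tri)) break
  }
  if (is.null(tri)) stop("could not triangulate fiber field vertices")
  ang <- sample_fiber_angles(length(vx), mean = mean_direction, kappa = kappa,
                             stream = stream)

  # cache the barycentric transform and bounding box of every triangle
  i1 <- tri[, 1]; i2 <- tri[, 2]; i3 <- tri[, 3]
  x1 <- vx[i1]; y1 <- vy[i1]; x2 <- vx[i2]; y2 <- vy[i2]
  x3 <- vx[i3]; y3 <- vy[i3]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  structure(
    list(width = width, height = height,
         mean_direction = wrap_angle(mean_direction), kappa = kappa,
         density = density,
         vx = vx, vy = vy, angle = ang, tri = tri,
         b11 = (y2 - y3) / det, b12 = (x3 - x2) / det,
         b21 = (y3 - y1) / det, b22 = (x1 - x3) / det,
         x3 = x3, y3 = y3,
         bbx1 = pmin(x1, x2, x3), bbx2 = pmax(x1, x2, x3),
         bby1 = pmin(y1, y2, y3), bby2 = pmax(y1, y2, y3)),
    class = "fiber_field")
}

# Containing triangle index for one point; boundary ties resolved by lowest
# triangle index (triangles are stored in deterministic sorted order).
locate_triangle <- function(field, x, y, tol = 1e-9) {
  cand <- which(x >= field$bbx1 - tol & x <= field$bbx2 + tol &
                y >= field$bby1 - tol & y <= field$bby2 + tol)
  for (t in cand) {
    w1 <- field$b11[t] * (x - field$x3[t]) + field$b12[t] * (y - field$y3[t])
    w2 <- field$b21[t] * (x - field$x3[t]) + field$b22[t] * (y - field$y3[t])
    w3 <- 1 - w1 - w2
    if (w1 >= -tol && w2 >= -tol && w3 >= -tol) return(t)
  }
  NA_integer_
}

#' Query the local fiber angle of a field
#'
#' @param field a [fiber_field()].
#' @param x,y coordinates of the query point(s), inside the domain.
#' @return interpolated axial fiber angle(s) in (-pi/2, pi/2].
#' @export
query_fiber_angle <- function(field, x, y) {
  stopifnot(inherits(field, "fiber_field"), length(x) == length(y))
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    if (!is.finite(x[i]) || !is.finite(y[i]) ||
        x[i] < 0 || x[i] > field$width || y[i] < 0 || y[i] > field$height)
      stop("query point outside the field domain")
    t <- locate_triangle(field, x[i], y[i])
    if (is.na(t)) stop("query point outside the field domain")
    w1 <- field$b11[t] * (x[i] - field$x3[t]) + field$b12[t] * (y[i] - field$y3[t])
    w2 <- field$b21[t] * (x[i] - field$x3[t]) + field$b22[t] * (y[i] - field$y3[t])
    w3 <- 1 - w1 - w2
    th <- field$angle[field$tri[t, ]]
    vxs <- w1 * cos(2 * th[1]) + w2 * cos(2 * th[2]) + w3 * cos(2 * th[3])
    vys <- w1 * sin(2 * th[1]) + w2 * sin(2 * th[2]) + w3 * sin(2 * th[3])
    if (vxs^2 + vys^2 < 1e-24) {
      out[i] <- th[which.max(c(w1, w2, w3))] # antipodal degenerate blend
    } else {
      out[i] <- wrap_angle(atan2(vys, vxs) / 2)
    }
  }
  out
}

#' @export
print.fiber_field <- function(x, ...) {
  cat(sprintf("Fiber field %g x %g um, mean axis %.3f rad, kappa %g, phi_f %g\n",
              x$width, x$height, x$mean_direction, x$kappa, x$density))
  cat(sprintf("  %d vertices, %d triangles\n", length(x$vx), nrow(x$tri)))
  invisible(x)
}

#' @describeIn fiber_field vertex mesh as a data frame (x, y, angle_rad),
#'   suitable for CSV export.
#' @param x a `fiber_field`.
#' @param row.names,optional,... passed on conventions of the generic.
#' @export
as.data.frame.fiber_field <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(x = x$vx, y = x$vy, angle_rad = x$angle)
}

#' Rasterize a fiber field on a regular grid
#'
#' @param field a [fiber_field()].
#' @param nx,ny grid resolution.
#' @return data frame (x, y, angle_rad) of interpolated angles, for plotting
#'   or CSV export.
#' @export
fiber_grid <- function(field, nx = 25, ny = 25) {
  gx <- seq(0, field$width, length.out = nx)
  gy <- seq(0, field$height, length.out = ny)
  g <- expand.grid(x = gx, y = gy)
  g$angle_rad <- query_fiber_angle(field, g$x, g$y)
  g
}

#' @export
plot.fiber_field <- function(x, nx = 25, ny = 25, scale = 0.8, ...) {
  g <- fiber_grid(x, nx, ny)
  dx <- scale * x$width / nx / 2; dy <- scale * x$height / ny / 2
  len <- min(dx, dy)
  graphics::plot(NA, xlim = c(0, x$width), ylim = c(0, x$height),
                 xlab = "x (um)", ylab = "y (um)", asp = 1, ...)
  graphics::segments(g$x - len * cos(g$angle_rad), g$y - len * sin(g$angle_rad),
                     g$x + len * cos(g$angle_rad), g$y + len * sin(g$angle_rad))
  invisible(g)
}
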