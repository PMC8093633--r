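#' Applied cyclic strain
#'
#' Describes an in-plane engineering-strain cycle by the two extremes of each
#' component: normal strains along x and y and the engineering shear strain.
#' The cycle "0--10% along x" is `strain_cycle(x = c(0, 0.10))`.
#'
#' @param x,y,shear length-2 numeric vectors `c(min, max)` giving the two
#'   extremes of the cycle for each engineering-strain component
#'   (dimensionless; shear is the engineering shear gamma_xy).
#' @param convention how the cycle maps to the strain-amplitude tensor that
#'   drives the cells: `"half-range"` (default) takes the amplitude as
#'   (max - min)/2 about the cycle midpoint; `"peak-to-peak"` takes the full
#'   excursion (max - min). The half-range convention is the one the shipped
#'   calibrated parameters were frozen under.
#' @return an object of class `applied_strain`.
#' @seealso [mohr_decompose()]
#' @export
#' @examples
#' strain_cycle(x = c(0, 0.10))          # 0-10% uniaxial cycle
#' strain_cycle(x = c(0.04, 0.06))       # 4-6% cycle
strain_cycle <- function(x = c(0, 0), y = c(0, 0), shear = c(0, 0),
                         convention = c("half-range", "peak-to-peak")) {
  convention <- match.arg(convention)
  chk <- function(v, nm) {
    if (length(v) == 1L) v <- c(v, v)
    if (length(v) != 2L || !all(is.finite(v)))
      stop("strain component '", nm, "' must be two finite numbers c(min, max)")
    if (v[2] < v[1])
      stop("strain component '", nm, "': max must be >= min")
    if (any(abs(v) >= 1))
      stop("strain component '", nm, "': engineering strains must lie in (-1, 1)")
    v
  }
  x <- chk(x, "x"); y <- chk(y, "y"); shear <- chk(shear, "shear")
  structure(
    list(eps_x_min = x[1], eps_x_max = x[2],
         eps_y_min = y[1], eps_y_max = y[2],
         gamma_xy_min = shear[1], gamma_xy_max = shear[2],
         convention = convention),
    class = "applied_strain")
}

#' @export
print.applied_strain <- function(x, ...) {
  cat("Applied cyclic strain (", x$convention, " amplitude convention)\n", sep = "")
  cat(sprintf("  eps_x:    %7.4f .. %7.4f\n", x$eps_x_min, x$eps_x_max))
  cat(sprintf("  eps_y:    %7.4f .. %7.4f\n", x$eps_y_min, x$eps_y_max))
  cat(sprintf("  gamma_xy: %7.4f .. %7.4f\n", x$gamma_xy_min, x$gamma_xy_max))
  invisible(x)
}

#' Principal decomposition of a cyclic strain (Mohr's circle)
#'
#' Splits the applied cycle into a mean-strain tensor (the cycle midpoint)
#' and a strain-amplitude tensor, then diagonalises the amplitude tensor.
#' The maximum principal amplitude `eps_max` is the strain amplitude a cell
#' aligned with the principal direction experiences; the strain-avoidance
#' direction `theta_csa` is perpendicular to the principal direction.
#'
#' When the amplitude tensor is isotropic (equibiaxial cycle) the principal
#' direction is degenerate and is reported as 0 by convention.
#'
#' @param applied an [strain_cycle()] object.
#' @return an object of class `principal_strain` with fields `eps_max`,
#'   `eps_min` (principal amplitudes, `eps_max >= eps_min`), `theta_p`
#'   (direction of maximum principal amplitude, radians in (-pi/2, pi/2]),
#'   `theta_csa = theta_p + pi/2` wrapped, and the mean-strain tensor
#'   components `mean_x`, `mean_y`, `mean_gamma`.
#' @export
#' @examples
#' ps <- mohr_decompose(strain_cycle(x = c(0, 0.10)))
#' ps$eps_max   # 0.05 under the half-range convention
#' ps$theta_csa # pi/2: cells avoid strain by turning perpendicular to x
mohr_decompose <- function(applied) {
  stopifnot(inherits(applied, "applied_strain"))
  fac <- if (applied$convention == "half-range") 0.5 else 1
  dex <- fac * (applied$eps_x_max - applied$eps_x_min)
  dey <- fac * (applied$eps_y_max - applied$eps_y_min)
  dg  <- fac * (applied$gamma_xy_max - applied$gamma_xy_min)

  # amplitude tensor (engineering shear -> tensor shear /2)
  m <- matrix(c(dex, dg / 2, dg / 2, dey), 2, 2)
  tol <- 1e-14 * max(1, abs(dex), abs(dey), abs(dg))
  if (abs(dg) <= tol && abs(dex - dey) <= tol) {
    eps_max <- eps_min <- dex
    theta_p <- 0           # degenerate direction, deterministic convention
  } else {
    e <- eigen(m, symmetric = TRUE)
    eps_max <- e$values[1]
    eps_min <- e$values[2]
    v <- e$vectors[, 1]
    theta_p <- wrap_angle(atan2(v[2], v[1]))
  }
  structure(
    list(eps_max = eps_max, eps_min = eps_min,
         theta_p = theta_p, theta_csa = wrap_angle(theta_p + pi / 2),
         mean_x = (applied$eps_x_max + applied$eps_x_min) / 2,
         mean_y = (applied$eps_y_max + applied$eps_y_min) / 2,
         mean_gamma = (applied$gamma_xy_max + applied$gamma_xy_min) / 2),
    class = "principal_strain")
}

#' @export
print.principal_strain <- function(x, ...) {
  cat("Principal strain amplitudes (Mohr's circle)\n")
  cat(sprintf("  eps_max %.5f  eps_min %.5f\n", x$eps_max, x$eps_min))
  cat(sprintf("  theta_p %.4f rad  theta_csa %.4f rad\n", x$theta_p, x$theta_csa))
  invisible(x)
}

#' Effective strain experienced by a cell
#'
#' The strain amplitude resolved along the cell's axis:
#' `delta_eps * |cos(theta_cell - theta_p)|`. The absolute value reflects
#' that orientations are axes: a cell at `theta` and `theta + pi` experiences
#' the same stretch, so a signed resolved strain would be meaningless.
#'
#' @param delta_eps maximum principal strain amplitude (dimensionless, >= 0).
#' @param theta_cell cell orientation(s), radians.
#' @param theta_p direction of maximum principal strain, radians.
#' @return non-negative effective strain, same length as `theta_cell`.
#' @export
#' @examples
#' effective_strain(0.10, 0, 0)      # parallel: full amplitude
#' effective_strain(0.10, pi/2, 0)   # perpendicular: zero
effective_strain <- function(delta_eps, theta_cell, theta_p) {
  stopifnot(all(is.finite(delta_eps)), all(is.finite(theta_cell)),
            all(is.finite(theta_p)))
  delta_eps * abs(cos(theta_cell - theta_p))
}

#' Effective stimulus driving reorientation
#'
#' Rescales the effective strain linearly between a threshold below which the
#' stimulus is too weak to act and a saturation strain above which a cell is
#' already reorienting as fast as it can, clamped into \[0, 1\].
#'
#' @param eps_eff effective strain(s), dimensionless.
#' @param eps_thres threshold strain (calibrated value 0.0).
#' @param eps_max_param saturation strain (calibrated value 0.4); must exceed
#'   `eps_thres`.
#' @return stimulus in \[0, 1\], same length as `eps_eff`.
#' @export
#' @examples
#' effective_stimulus(0.2, 0, 0.4) # 0.5
effective_stimulus <- function(eps_eff, eps_thres, eps_max_param) {
  if (!is.finite(eps_thres) || !is.finite(eps_max_param) ||
      eps_max_param <= eps_thres || eps_thres < 0)
    stop("require eps_max_param > eps_thres >= 0")
  pmin(pmax((eps_eff - eps_thres) / (eps_max_param - eps_thres), 0), 1)
}
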