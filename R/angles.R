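#' Wrap an orientation into (-pi/2, pi/2]
#'
#' Cell and fiber orientations are axes (a cell pointing at `theta` and
#' `theta + pi` is the same state), so every orientation in the package is
#' stored modulo pi in the half-open interval (-pi/2, pi/2].
#'
#' @param theta numeric vector of angles in radians.
#' @return numeric vector of the same length, wrapped into (-pi/2, pi/2].
#' @export
#' @examples
#' wrap_angle(c(0, pi/2, -pi/2, 2))
wrap_angle <- function(theta) {
  w <- (theta + pi / 2) %% pi
  w[w == 0] <- pi
  w - pi / 2
}

#' Shortest signed pi-periodic angular difference
#'
#' Returns the signed rotation (in \[-pi/2, pi/2)) that carries `current`
#' onto `target` along the shortest arc, treating both as axial angles.
#' Naive subtraction gives the wrong rotation direction near +/-pi/2.
#'
#' @param target,current numeric vectors of angles in radians.
#' @return signed difference `target - current` reduced modulo pi into
#'   \[-pi/2, pi/2).
#' @export
#' @examples
#' angle_diff(1.5, -1.5) # short way through the wrap, not 3.0
angle_diff <- function(target, current) {
  ((target - current + pi / 2) %% pi) - pi / 2
}

#' Axial circular statistics
#'
#' Mean direction, resultant length and von Mises concentration estimate for
#' axial (pi-periodic) data, computed on the doubled-angle circle.
#'
#' @param theta numeric vector of axial angles (radians).
#' @return `axial_mean`: mean axis in (-pi/2, pi/2]. `axial_resultant`: mean
#'   resultant length in \[0, 1\] of the doubled angles. `axial_concentration`:
#'   approximate maximum-likelihood von Mises concentration (Fisher's
#'   approximation to the inverse of A1).
#' @export
axial_mean <- function(theta) {
  wrap_angle(atan2(mean(sin(2 * theta)), mean(cos(2 * theta))) / 2)
}

#' @rdname axial_mean
#' @export
axial_resultant <- function(theta) {
  sqrt(mean(cos(2 * theta))^2 + mean(sin(2 * theta))^2)
}

#' @rdname axial_mean
#' @export
axial_concentration <- function(theta) {
  r <- axial_resultant(theta)
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}
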