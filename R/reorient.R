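#' Reorientation rate parameters
#'
#' Bundles the calibrated constants of the orientation update: the rotation
#' rate constants for the strain and fiber regimes, the fiber-density
#' threshold and sigmoid slope of the cue blend, and the strain window that
#' maps effective strain to effective stimulus.
#'
#' Defaults are the calibrated values for rat aortic smooth muscle cells:
#' `k_rot_c = 0.001` rad/tick, `k_rot_f = 0.1` rad/tick, `eps_thres = 0`,
#' `eps_max = 0.4`. `phi_thres` and `M` could not be calibrated from the
#' available two-substrate data (phi_f is only ever 0 or 1 there); the
#' defaults 0.5 and 10 merely make intermediate-density demonstrations
#' runnable and are flagged as uncalibrated.
#'
#' @param k_rot_c strain-regime rotation constant (rad/tick).
#' @param k_rot_f fiber-regime rotation constant (rad/tick).
#' @param phi_thres fiber density at which fibers take over from strain.
#' @param M sigmoid slope of the cue blend.
#' @param eps_thres,eps_max strain window for the effective stimulus.
#' @return a `reorientation_params` list.
#' @export
reorientation_params <- function(k_rot_c = 0.001, k_rot_f = 0.1,
                                 phi_thres = 0.5, M = 10,
                                 eps_thres = 0, eps_max = 0.4) {
  stopifnot(k_rot_c >= 0, k_rot_f >= 0, phi_thres >= 0, phi_thres <= 1,
            M >= 0, eps_thres >= 0, eps_max > eps_thres)
  structure(list(k_rot_c = k_rot_c, k_rot_f = k_rot_f,
                 phi_thres = phi_thres, M = M,
                 eps_thres = eps_thres, eps_max = eps_max),
            class = "reorientation_params")
}

#' Weight of the mechanical cue in the blended target angle
#'
#' Sigmoid in the fiber density: `1 / (1 + M^(10 * (phi_f - phi_thres)))`.
#' At `phi_f = 0` (bare PDMS) the weight is ~1 and strain avoidance
#' dominates; at `phi_f = 1` (dense collagenous tissue) it is ~0 and the
#' local fiber axis dominates; `phi_thres` is the half-way density. The
#' functional form is isolated here so it can be swapped once data at
#' intermediate fiber densities exist.
#'
#' @param phi_f fiber density in \[0, 1\].
#' @param phi_thres threshold density.
#' @param M slope parameter (> 1 for a switch-like blend).
#' @return weight in (0, 1) applied to the strain-avoidance direction.
#' @export
fiber_weight <- function(phi_f, phi_thres, M) {
  1 / (1 + M^(10 * (phi_f - phi_thres)))
}

#' Target (desired) orientation from combined cues
#'
#' Blends the local fiber axis and the strain-avoidance direction:
#' `theta_f + d(theta_csa, theta_f) * w(phi_f)` where `d` is the shortest
#' signed pi-periodic difference and `w` is [fiber_weight()].
#'
#' @param theta_f local fiber axis, radians.
#' @param theta_csa strain-avoidance direction, radians.
#' @param phi_f fiber density in \[0, 1\].
#' @param phi_thres,M blend parameters, see [fiber_weight()].
#' @return target orientation(s) in (-pi/2, pi/2].
#' @export
#' @examples
#' desired_angle(0, pi/2, phi_f = 0, phi_thres = 0.5, M = 10)  # ~pi/2
#' desired_angle(0, pi/2, phi_f = 1, phi_thres = 0.5, M = 10)  # ~0
desired_angle <- function(theta_f, theta_csa, phi_f, phi_thres, M) {
  w <- fiber_weight(phi_f, phi_thres, M)
  wrap_angle(theta_f + angle_diff(theta_csa, theta_f) * w)
}

#' Magnitude of one reorientation step
#'
#' Below the fiber-density threshold the cell is in the strain regime and
#' turns at `z_eff * k_rot_c` rad/tick; at or above the threshold it is in
#' the fiber regime and turns at `|sin(theta_f - theta_cell)| * k_rot_f`
#' rad/tick (the tie at `phi_f == phi_thres` goes to the fiber regime).
#'
#' @param theta_cell current orientation(s), radians.
#' @param z_eff effective stimulus in \[0, 1\] (strain regime).
#' @param theta_f local fiber axis (fiber regime).
#' @param phi_f fiber density.
#' @param params a [reorientation_params()] object.
#' @return unsigned step magnitude(s), rad/tick.
#' @export
rotation_step <- function(theta_cell, z_eff, theta_f, phi_f, params) {
  stopifnot(inherits(params, "reorientation_params"),
            all(z_eff >= 0), all(z_eff <= 1))
  if (phi_f < params$phi_thres) {
    z_eff * params$k_rot_c
  } else {
    abs(sin(theta_f - theta_cell)) * params$k_rot_f
  }
}

#' Apply a rotation step toward a target orientation
#'
#' Rotates by at most `delta` along the shortest pi-periodic arc toward
#' `theta_final`; the step is clamped to the remaining angular distance so
#' the cell never overshoots (an unclamped update oscillates around the
#' target in a limit cycle once `delta` exceeds the remaining distance).
#'
#' @param theta_cell current orientation(s), radians.
#' @param theta_final target orientation(s), radians.
#' @param delta unsigned step magnitude(s), `>= 0`.
#' @return updated orientation(s) in (-pi/2, pi/2].
#' @export
#' @examples
#' apply_rotation(0, 0.5, 0.001)  # 0.001, stepping toward the target
#' apply_rotation(0.5, 0.5, 0.1)  # stays at 0.5
apply_rotation <- function(theta_cell, theta_final, delta) {
  stopifnot(all(delta >= 0))
  beta <- angle_diff(theta_final, theta_cell)
  dir <- ifelse(beta >= 0, 1, -1)
  wrap_angle(theta_cell + dir * pmin(delta, abs(beta)))
}
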