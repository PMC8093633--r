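#' Read a simulation configuration from a YAML file
#'
#' Maps a flat YAML document onto [simulation_config()]. Recognised keys
#' (all optional; missing keys keep the package defaults):
#'
#' ```yaml
#' domain: [1000, 1000]      # um
#' density: 55               # cells/mm^2 (or density_cm2: 5.5e3)
#' radius: 0.3888            # um
#' ticks: 72
#' tick_hours: 1
#' seed: 1
#' strain:
#'   x: [0.0, 0.10]
#'   y: [0.0, 0.0]
#'   shear: [0.0, 0.0]
#'   convention: half-range  # or peak-to-peak
#' fiber:                    # omit for an unstructured (PDMS) substrate
#'   mean_deg: 90
#'   kappa: 100
#'   density: 1
#'   n_vertices: 200
#' reorientation: {k_rot_c: 0.001, k_rot_f: 0.1, phi_thres: 0.5, M: 10,
#'                 eps_thres: 0.0, eps_max: 0.4}
#' turnover: {A_apop: 1, B_apop: 1.64, A_prolif: 3500, B_prolif: 500,
#'            C_prolif: 71, sigma_prolif: 9, apoptosis_every: 3}
#' ```
#'
#' @param path path to the YAML file.
#' @return a [simulation_config()] object.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(defaults, given) {
    if (is.null(given)) return(defaults)
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    defaults[names(given)] <- given
    defaults
  }
  strain <- if (is.null(y$strain)) strain_cycle() else
    do.call(strain_cycle, take(list(x = c(0, 0), y = c(0, 0),
                                    shear = c(0, 0),
                                    convention = "half-range"), y$strain))
  fibers <- if (is.null(y$fiber)) NULL else
    do.call(fiber_spec, take(formals(fiber_spec), y$fiber))
  reo <- do.call(reorientation_params,
                 take(as.list(formals(reorientation_params)), y$reorientation))
  to_defaults <- lapply(as.list(formals(turnover_params)), function(f)
    if (is.call(f)) eval(f)[1] else f)
  to <- do.call(turnover_params, take(to_defaults, y$turnover))
  num <- function(v) if (is.null(v)) NULL else as.numeric(v)
  # YAML readers keep "1.33e4" (no "+") as a string; coerce numerics
  density <- if (!is.null(y$density_cm2)) cells_per_cm2(num(y$density_cm2))
             else if (!is.null(y$density)) num(y$density) else 55
  simulation_config(
    domain = if (is.null(y$domain)) c(1000, 1000) else as.numeric(unlist(y$domain)),
    density = density,
    radius = if (is.null(y$radius)) 0.3888 else num(y$radius),
    ticks = if (is.null(y$ticks)) 72 else num(y$ticks),
    tick_hours = if (is.null(y$tick_hours)) 1 else num(y$tick_hours),
    strain = strain, fibers = fibers, reorientation = reo, turnover = to,
    seed = if (is.null(y$seed)) 1 else num(y$seed))
}
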