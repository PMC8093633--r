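#' Seed the initial cell population
#'
#' Places `round(density * area)` non-overlapping cells uniformly at random
#' (rejection sampling with a retry cap), assigns uniform random axial
#' orientations in (-pi/2, pi/2] and initial ages per the configured rule.
#'
#' @param config a [simulation_config()].
#' @param stream optional internal RNG stream (defaults to a stream derived
#'   from the config seed, as in [run_simulation()]).
#' @return a list with vectors `x`, `y`, `theta`, `age`, `id`.
#' @export
seed_population <- function(config, stream = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(stream)) stream <- new_stream(sub_seed(config$seed, 1))
  area_mm2 <- prod(config$domain) / 1e6
  n <- round(config$density * area_mm2)
  w <- config$domain[1]; h <- config$domain[2]
  min2 <- (2 * config$radius)^2
  x <- numeric(n); y <- numeric(n)
  placed <- 0L; tries <- 0L; cap <- 1000 * n
  bx <- numeric(0); by <- numeric(0); bi <- 1L   # batched proposals
  while (placed < n) {
    if (bi > length(bx)) {
      bx <- st_runif(stream, n, 0, w); by <- st_runif(stream, n, 0, h)
      bi <- 1L
    }
    if (tries >= cap)
      stop(sprintf(paste0("could not place %d non-overlapping cells; ",
                          "achievable density ~%.0f cells/mm^2"),
                   n, placed / area_mm2))
    px <- bx[bi]; py <- by[bi]; bi <- bi + 1L
    tries <- tries + 1L
    if (placed == 0L ||
        min((x[seq_len(placed)] - px)^2 + (y[seq_len(placed)] - py)^2) >= min2) {
      placed <- placed + 1L
      x[placed] <- px; y[placed] <- py
    }
  }
  theta <- wrap_angle(st_runif(stream, n, -pi / 2, pi / 2))
  to <- config$turnover
  max_age <- if (to$initial_age == "uniform-cprolif") to$C_prolif
             else to$C_prolif * to$sigma_prolif
  age <- st_runif(stream, n, 0, max_age)
  list(x = x, y = y, theta = theta, age = age, id = seq_len(n))
}

#' Run the agent-based simulation
#'
#' Executes the tick loop. Each tick, in this frozen order: (1) every cell
#' senses its cues (local fiber axis, fiber density, effective strain and
#' stimulus) and rotates one step toward its blended target orientation;
#' (2) on apoptosis-check ticks (every `turnover$apoptosis_every` ticks)
#' each cell is removed with its strain-dependent probability; (3) ages
#' advance by one tick and each survivor attempts division with the
#' age-gated probability, placing a daughter tangentially if there is
#' space; (4) the state is recorded. Cells are processed in stable id
#' order and all randomness is drawn from named streams derived from the
#' config seed, so identical configurations reproduce bit-identically.
#'
#' @param config a [simulation_config()].
#' @return an object of class `vsmc_sim`: per-tick live counts, snapshots
#'   of the cell table at recorded ticks, the birth/death event log, the
#'   principal-strain decomposition, the synthesised fiber field (if any)
#'   and the resolved config.
#' @seealso [fold_change()], [orientation_histogram()]
#' @export
#' @examples
#' cfg <- simulation_config(ticks = 24, seed = 7,
#'                          strain = strain_cycle(x = c(0, 0.10)))
#' sim <- run_simulation(cfg)
#' fold_change(sim, 24)
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  s_seed  <- new_stream(sub_seed(config$seed, 1))
  s_fiber <- new_stream(sub_seed(config$seed, 2))
  s_apop  <- new_stream(sub_seed(config$seed, 3))
  s_prol  <- new_stream(sub_seed(config$seed, 4))
  s_place <- new_stream(sub_seed(config$seed, 5))

  re <- config$reorientation; to <- config$turnover
  ps <- mohr_decompose(config$strain)

  field <- NULL; phi_f <- 0
  if (!is.null(config$fibers)) {
    field <- fiber_field(config$domain[1], config$domain[2],
                         mean_direction = config$fibers$mean_deg * pi / 180,
                         kappa = config$fibers$kappa,
                         density = config$fibers$density,
                         n_vertices = config$fibers$n_vertices,
                         stream = s_fiber)
    phi_f <- field$density
  }

  pop <- seed_population(config, s_seed)
  x <- pop$x; y <- pop$y; theta <- pop$theta; age <- pop$age; id <- pop$id
  next_id <- length(id) + 1L
  # local fiber axis is static per position; cache it per cell
  th_f <- if (is.null(field)) theta else query_fiber_angle(field, x, y)

  ticks <- config$ticks
  counts <- integer(ticks + 1); counts[1] <- length(id)
  rec <- config$record_every
  snap_at <- unique(c(0L, if (!is.null(rec) && rec > 0)
    seq(rec, ticks, by = rec), ticks))
  snapshot <- function() data.frame(id = id, x = x, y = y, theta = theta,
                                    age = age)
  snaps <- list(); snaps[[as.character(0L)]] <- snapshot()
  events <- list()
  fiber_regime <- phi_f >= re$phi_thres
  w_csa <- fiber_weight(phi_f, re$phi_thres, re$M)

  for (t in seq_len(ticks)) {
    n <- length(id)
    if (n > 0L) {
      ## (1) sense cues and reorient
      eps_eff <- effective_strain(ps$eps_max, theta, ps$theta_p)
      if (is.null(field)) th_f <- theta  # no structural preference
      target <- wrap_angle(th_f + angle_diff(ps$theta_csa, th_f) * w_csa)
      delta <- if (fiber_regime) {
        abs(sin(th_f - theta)) * re$k_rot_f
      } else {
        effective_stimulus(eps_eff, re$eps_thres, re$eps_max) * re$k_rot_c
      }
      theta <- apply_rotation(theta, target, delta)
      eps_eff <- effective_strain(ps$eps_max, theta, ps$theta_p)
      eps_turn <- if (to$eps_source == "effective") eps_eff
                  else rep(ps$eps_max, n)

      ## (2) apoptosis on cadence ticks
      if (t %% to$apoptosis_every == 0L) {
        dead <- apoptosis_sweep(eps_turn, to, s_apop)
        if (any(dead)) {
          if (config$keep_events)
            events[[length(events) + 1L]] <-
              data.frame(tick = t, event = "death", cell_id = id[dead],
                         x = x[dead], y = y[dead], theta = theta[dead],
                         eps_eff = eps_eff[dead])
          keep <- !dead
          x <- x[keep]; y <- y[keep]; theta <- theta[keep]
          age <- age[keep]; id <- id[keep]; th_f <- th_f[keep]
          eps_eff <- eps_eff[keep]; eps_turn <- eps_turn[keep]
          n <- length(id)
        }
      }

      ## (3) ageing and proliferation
      if (n > 0L) {
        age <- age + config$tick_hours
        dividing <- integer(0)
        if (t %% to$proliferation_every == 0L) {
          td <- doubling_time(eps_turn, to)
          p_div <- proliferation_probability(age, td, to$sigma_prolif)
          dividing <- which(st_runif(s_prol, n) < p_div)
        }
        u_place <- if (length(dividing)) st_runif(s_place, length(dividing))
        for (di in seq_along(dividing)) {
          i <- dividing[di]
          site <- place_daughter(c(x[i], y[i]), x, y, config$radius,
                                 config$domain, u = u_place[di])
          if (is.null(site)) next  # no space: division does not occur
          age[i] <- 0
          d_theta <- if (to$daughter_orientation == "inherit") theta[i]
                     else wrap_angle(st_runif(s_prol, 1, -pi / 2, pi / 2))
          x <- c(x, site[1]); y <- c(y, site[2]); theta <- c(theta, d_theta)
          age <- c(age, 0); id <- c(id, next_id)
          th_f <- c(th_f, if (is.null(field)) d_theta
                          else query_fiber_angle(field, site[1], site[2]))
          if (config$keep_events)
            events[[length(events) + 1L]] <-
              data.frame(tick = t, event = "birth", cell_id = next_id,
                         x = site[1], y = site[2], theta = d_theta,
                         eps_eff = effective_strain(ps$eps_max, d_theta,
                                                    ps$theta_p))
          next_id <- next_id + 1L
        }
      }
    }
    counts[t + 1] <- length(id)
    if (t %in% snap_at) snaps[[as.character(t)]] <- snapshot()
  }

  structure(list(
    counts = counts,
    snapshots = snaps,
    events = if (length(events)) do.call(rbind, events)
             else data.frame(tick = integer(), event = character(),
                             cell_id = integer(), x = numeric(),
                             y = numeric(), theta = numeric(),
                             eps_eff = numeric()),
    principal = ps,
    field = field,
    config = config),
    class = "vsmc_sim")
}

#' Fold change in cell number
#'
#' @param sim a `vsmc_sim` result.
#' @param tick tick at which to evaluate (0 .. ticks).
#' @return live count at `tick` divided by the initial count.
#' @export
fold_change <- function(sim, tick = sim$config$ticks) {
  stopifnot(inherits(sim, "vsmc_sim"))
  if (length(tick) != 1 || tick < 0 || tick > sim$config$ticks ||
      tick != round(tick))
    stop("tick not recorded: must be an integer in 0..", sim$config$ticks)
  sim$counts[tick + 1] / sim$counts[1]
}

#' Orientation histogram of a recorded population
#'
#' Counts cell axes in bins of `width_deg` degrees spanning (-90, 90\].
#'
#' @param sim a `vsmc_sim` result (or a numeric vector of angles in
#'   radians).
#' @param tick recorded snapshot tick (default: final tick).
#' @param width_deg bin width in degrees.
#' @return data frame with bin limits (degrees) and counts.
#' @export
orientation_histogram <- function(sim, tick = NULL, width_deg = 10) {
  theta <- if (inherits(sim, "vsmc_sim")) {
    if (is.null(tick)) tick <- sim$config$ticks
    snap <- sim$snapshots[[as.character(tick)]]
    if (is.null(snap)) stop("no snapshot recorded at tick ", tick)
    snap$theta
  } else as.numeric(sim)
  breaks <- seq(-90, 90, by = width_deg)
  deg <- theta * 180 / pi
  deg[deg <= -90] <- deg[deg <= -90] + 180
  cut_idx <- findInterval(deg, breaks, left.open = TRUE, all.inside = TRUE)
  data.frame(lower_deg = breaks[-length(breaks)], upper_deg = breaks[-1],
             count = tabulate(cut_idx, nbins = length(breaks) - 1))
}

#' Export a recorded cell table as a quiver-style CSV
#'
#' Writes one row per live cell (x, y, theta_rad) at a recorded tick.
#'
#' @param sim a `vsmc_sim` result.
#' @param file output path.
#' @param tick recorded snapshot tick (default: final).
#' @return the written data frame, invisibly.
#' @export
write_quiver_csv <- function(sim, file, tick = NULL) {
  stopifnot(inherits(sim, "vsmc_sim"))
  if (is.null(tick)) tick <- sim$config$ticks
  snap <- sim$snapshots[[as.character(tick)]]
  if (is.null(snap)) stop("no snapshot recorded at tick ", tick)
  out <- data.frame(x = snap$x, y = snap$y, theta_rad = snap$theta)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}

#' @export
print.vsmc_sim <- function(x, ...) {
  cat(sprintf("vsmc_sim: %d ticks, %d -> %d cells (fold change %.3f)\n",
              x$config$ticks, x$counts[1], x$counts[length(x$counts)],
              fold_change(x)))
  invisible(x)
}

#' @export
summary.vsmc_sim <- function(object, ...) {
  final <- object$snapshots[[as.character(object$config$ticks)]]
  res <- list(
    ticks = object$config$ticks,
    initial = object$counts[1],
    final = object$counts[length(object$counts)],
    fold_change = fold_change(object),
    births = sum(object$events$event == "birth"),
    deaths = sum(object$events$event == "death"),
    axial_mean_deg = axial_mean(final$theta) * 180 / pi,
    axial_resultant = axial_resultant(final$theta))
  class(res) <- "summary.vsmc_sim"
  res
}

#' @export
print.summary.vsmc_sim <- function(x, ...) {
  cat(sprintf("Ticks: %d   cells %d -> %d   fold change %.3f\n",
              x$ticks, x$initial, x$final, x$fold_change))
  cat(sprintf("Events: %d births, %d deaths\n", x$births, x$deaths))
  cat(sprintf("Final orientation: mean axis %.1f deg, resultant %.3f\n",
              x$axial_mean_deg, x$axial_resultant))
  invisible(x)
}

#' @export
plot.vsmc_sim <- function(x, which = c("growth", "orientation"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if (length(which) > 1) {
    op <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(op))
  }
  if ("growth" %in% which) {
    graphics::plot(0:x$config$ticks, x$counts, type = "l",
                   xlab = "tick (h)", ylab = "live cells",
                   main = "Population", ...)
  }
  if ("orientation" %in% which) {
    h <- orientation_histogram(x)
    graphics::barplot(h$count, names.arg = (h$lower_deg + h$upper_deg) / 2,
                      xlab = "orientation (deg)", ylab = "cells",
                      main = "Final orientations", ...)
  }
  invisible(x)
}
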