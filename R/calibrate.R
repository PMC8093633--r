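#' Packaged experimental reference tables
#'
#' The calibration targets shipped with the package: unstrained day-3 cell
#' densities (`"table1"`), the rotation-constant sweep reference
#' (`"table3"`), fold changes on PDMS under three cyclic strain amplitudes
#' at 24 and 72 h (`"table4"`), and 10-day fold changes on structured
#' constructs (`"table6"`). Values are transcribed verbatim from the source
#' experiments; `model_*` columns are the original model's predictions and
#' are kept for comparison, never used in fitting.
#'
#' @param name one of `"table1"`, `"table3"`, `"table4"`, `"table6"`.
#' @return a data frame.
#' @export
#' @examples
#' calibration_tables("table1")
calibration_tables <- function(name = c("table1", "table3", "table4",
                                        "table6")) {
  name <- match.arg(name)
  f <- system.file("extdata", paste0(name, ".csv"), package = "vsmcabm",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

# Sum of squared z-scores of predictions against observed mean/SD pairs.
zscore_objective <- function(pred, obs_mean, obs_sd) {
  sum(((pred - obs_mean) / obs_sd)^2)
}

new_calibration <- function(best, objective, grid, n_seeds, seeds) {
  structure(list(best = best, objective = objective, grid = grid,
                 n_seeds = n_seeds, seeds = seeds),
            class = "vsmc_calibration")
}

#' @export
print.vsmc_calibration <- function(x, ...) {
  cat("Calibration result (", nrow(x$grid), " grid points, ",
      x$n_seeds, " seeds each)\n", sep = "")
  cat("  best: ", paste(names(x$best), signif(unlist(x$best), 6),
                        sep = " = ", collapse = ", "), "\n", sep = "")
  cat(sprintf("  objective (sum squared z-scores): %.4f\n", x$objective))
  invisible(x)
}

mean_density_day3 <- function(b_apop, density0, n_seeds, seed0, base_config) {
  folds <- vapply(seq_len(n_seeds), function(k) {
    cfg <- base_config
    cfg$density <- density0
    cfg$turnover$B_apop <- b_apop
    cfg$seed <- sub_seed(seed0, k)
    cfg$keep_events <- FALSE
    sim <- run_simulation(cfg)
    sim$counts[length(sim$counts)] / (prod(cfg$domain) / 1e6)
  }, numeric(1))
  mean(folds)
}

#' Calibrate the baseline apoptosis constant
#'
#' Sweeps `B_apop` on a grid (0.01 increments by default) and scores each
#' value by the summed squared z-scores of the predicted unstrained day-3
#' densities against the three experimental density targets. Strain is zero
#' throughout, so only `B_apop`, `C_prolif` and `sigma_prolif` act. Ties on
#' the objective are broken toward the lower `B_apop`.
#'
#' @param targets data frame with columns `density0_mm2`, `exp_day3_mean`,
#'   `exp_day3_sd` (default: the packaged targets).
#' @param grid candidate `B_apop` values (percent probability per check).
#' @param n_seeds replicate seeds per grid point (replicates share the same
#'   seed set across grid points, smoothing the objective surface).
#' @param seed master seed for the replicate streams.
#' @param base_config simulation configuration template; strain is forced to
#'   zero and the density overridden per target.
#' @return a `vsmc_calibration` with `best$B_apop`, the objective value and
#'   the full auditable grid.
#' @export
calibrate_bapop <- function(targets = calibration_tables("table1"),
                            grid = seq(1.0, 2.5, by = 0.01),
                            n_seeds = 10,
                            seed = 1,
                            base_config = simulation_config(ticks = 72)) {
  if (length(grid) == 0) stop("empty B_apop grid")
  stopifnot(all(c("density0_mm2", "exp_day3_mean", "exp_day3_sd") %in%
                  names(targets)))
  base_config$strain <- strain_cycle()
  res <- lapply(seq_along(grid), function(g) {
    pred <- vapply(seq_len(nrow(targets)), function(i) {
      mean_density_day3(grid[g], targets$density0_mm2[i], n_seeds,
                        sub_seed(seed, 100 + i), base_config)
    }, numeric(1))
    cbind(B_apop = grid[g],
          objective = zscore_objective(pred, targets$exp_day3_mean,
                                       targets$exp_day3_sd),
          t(stats::setNames(pred, paste0("pred_", seq_along(pred)))))
  })
  grid_df <- as.data.frame(do.call(rbind, res))
  best_i <- which(grid_df$objective == min(grid_df$objective))[1] # lower value wins ties
  new_calibration(list(B_apop = grid_df$B_apop[best_i]),
                  grid_df$objective[best_i], grid_df, n_seeds, seed)
}

table4_strains <- function() {
  list(`4-6` = strain_cycle(x = c(0.04, 0.06)),
       `2-8` = strain_cycle(x = c(0.02, 0.08)),
       `0-10` = strain_cycle(x = c(0.00, 0.10)))
}

mean_fold_strained <- function(params, strain, n_seeds, seed0, base_config,
                               at = c(24, 72)) {
  f <- matrix(0, n_seeds, length(at))
  for (k in seq_len(n_seeds)) {
    cfg <- base_config
    cfg$strain <- strain
    cfg$turnover[names(params)] <- params
    cfg$seed <- sub_seed(seed0, k)
    cfg$keep_events <- FALSE
    sim <- run_simulation(cfg)
    f[k, ] <- vapply(at, function(tt) fold_change(sim, tt), numeric(1))
  }
  colMeans(f)
}

#' Calibrate the strain-response constants by exhaustive grid search
#'
#' Evaluates every combination of `A_prolif`, `B_prolif` and `A_apop` on the
#' supplied grids (defaults reproduce the original search: 0--3500 by 500,
#' -100--500 by 50, 0--20 by 1, i.e. 8 x 13 x 21 = 2184 combinations)
#' against the six experimental fold-change targets (three strain
#' amplitudes x two time points) on an unstructured substrate. The
#' objective is the summed squared z-scores against the experimental
#' mean/SD. `B_apop`, `C_prolif`, `sigma_prolif` and the reorientation
#' constants stay fixed at their previously calibrated values.
#'
#' The full default grid is expensive (tens of minutes); pass smaller grids
#' for exploration.
#'
#' @param targets data frame with columns `strain` (`"4-6"`, `"2-8"`,
#'   `"0-10"`), `time_h`, `exp_mean`, `exp_sd`.
#' @param a_prolif,b_prolif,a_apop candidate grids.
#' @param n_seeds replicate seeds per combination.
#' @param seed master seed.
#' @param base_config configuration template (unstructured substrate).
#' @return a `vsmc_calibration`; `grid` holds the full auditable surface.
#' @export
calibrate_strain_response <- function(targets = calibration_tables("table4"),
                                      a_prolif = seq(0, 3500, by = 500),
                                      b_prolif = seq(-100, 500, by = 50),
                                      a_apop = seq(0, 20, by = 1),
                                      n_seeds = 10,
                                      seed = 1,
                                      base_config = simulation_config(ticks = 72)) {
  if (!length(a_prolif) || !length(b_prolif) || !length(a_apop))
    stop("empty parameter grid")
  strains <- table4_strains()
  combos <- expand.grid(A_prolif = a_prolif, B_prolif = b_prolif,
                        A_apop = a_apop, KEEP.OUT.ATTRS = FALSE)
  times <- sort(unique(targets$time_h))
  obj <- numeric(nrow(combos))
  preds <- matrix(NA_real_, nrow(combos), nrow(targets))
  for (ci in seq_len(nrow(combos))) {
    par <- as.list(combos[ci, ])
    pred <- targets
    pred$value <- NA_real_
    for (sn in names(strains)) {
      m <- mean_fold_strained(par, strains[[sn]], n_seeds,
                              sub_seed(seed, 200 + match(sn, names(strains))),
                              base_config, at = times)
      for (j in seq_along(times))
        pred$value[pred$strain == sn & pred$time_h == times[j]] <- m[j]
    }
    obj[ci] <- zscore_objective(pred$value, targets$exp_mean, targets$exp_sd)
    preds[ci, ] <- pred$value
  }
  colnames(preds) <- paste0("pred_", targets$strain, "_", targets$time_h, "h")
  grid_df <- cbind(combos, objective = obj, as.data.frame(preds))
  best_i <- which.min(obj)
  new_calibration(as.list(combos[best_i, ]), obj[best_i], grid_df, n_seeds,
                  seed)
}

#' Sweep the strain-regime rotation constant
#'
#' Runs the 0--10% PDMS protocol for each candidate `k_rot_c`, reporting the
#' replicate-mean 72 h fold change and the axial concentration of the final
#' pooled orientations (larger = sharper strain avoidance).
#'
#' @param values candidate `k_rot_c` values (rad/tick); must be non-empty.
#' @param n_seeds replicate seeds per value.
#' @param seed master seed.
#' @param base_config configuration template.
#' @return data frame with one row per value: mean and SD of the 72 h fold
#'   change and the pooled axial resultant/concentration.
#' @export
sweep_krot_c <- function(values, n_seeds = 10, seed = 1,
                         base_config = simulation_config(
                           ticks = 72, strain = strain_cycle(x = c(0, 0.10)))) {
  if (length(values) == 0) stop("empty value list")
  out <- lapply(values, function(v) {
    folds <- numeric(n_seeds); thetas <- list()
    for (k in seq_len(n_seeds)) {
      cfg <- base_config
      cfg$reorientation$k_rot_c <- v
      cfg$seed <- sub_seed(seed, 300 + k)
      cfg$keep_events <- FALSE
      sim <- run_simulation(cfg)
      folds[k] <- fold_change(sim, cfg$ticks)
      thetas[[k]] <- sim$snapshots[[as.character(cfg$ticks)]]$theta
    }
    th <- unlist(thetas)
    data.frame(k_rot_c = v, fold_mean = mean(folds), fold_sd = stats::sd(folds),
               axial_resultant = axial_resultant(th),
               axial_concentration = axial_concentration(th))
  })
  do.call(rbind, out)
}
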