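# Shared helpers: small configuration factories, replicate averaging and an
# independent expectation oracle for the birth-death dynamics.

quick_config <- function(..., ticks = 24, density = 55, seed = 1) {
  simulation_config(ticks = ticks, density = density, seed = seed,
                    keep_events = TRUE, ...)
}

mean_fold_over_seeds <- function(base_config, seeds, at = base_config$ticks) {
  f <- vapply(seeds, function(s) {
    cfg <- base_config
    cfg$seed <- s
    cfg$keep_events <- FALSE
    sim <- run_simulation(cfg)
    vapply(at, function(tt) fold_change(sim, tt), numeric(1))
  }, numeric(length(at)))
  if (length(at) == 1) mean(f) else rowMeans(matrix(f, nrow = length(at)))
}

# Deterministic age-structured expectation of the population size under zero
# strain: propagates the expected mass per age atom through the same per-tick
# schedule (apoptosis every `ae` ticks, ageing, division trial every `pe`
# ticks with both parent and daughter reset to age 0). Independent of the
# stochastic engine; crowding is ignored (valid in the dilute regime).
expected_fold_zero_strain <- function(ticks, to, tick_hours = 1,
                                      n_atoms = 2000) {
  p_ap <- apoptosis_probability(0, to)
  td <- doubling_time(0, to)
  max_age <- if (to$initial_age == "uniform-cprolif") to$C_prolif
             else to$C_prolif * to$sigma_prolif
  age <- (seq_len(n_atoms) - 0.5) / n_atoms * max_age
  mass <- rep(1 / n_atoms, n_atoms)
  for (t in seq_len(ticks)) {
    if (t %% to$apoptosis_every == 0L) mass <- mass * (1 - p_ap)
    age <- age + tick_hours
    if (t %% to$proliferation_every == 0L) {
      p <- proliferation_probability(age, td, to$sigma_prolif)
      born <- 2 * sum(mass * p)
      mass <- mass * (1 - p)
      age <- c(age, 0)
      mass <- c(mass, born)
    }
  }
  sum(mass)
}

min_pairwise_distance <- function(x, y) {
  if (length(x) < 2) return(Inf)
  min(stats::dist(cbind(x, y)))
}
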