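test_that("seeding honours density, non-overlap and the angle convention", {
  # 5.5e3 cells/cm^2 on 1 mm^2 -> 55 cells; 1.33e4 -> 133
  expect_equal(length(seed_population(
    simulation_config(density = cells_per_cm2(5.5e3)))$x), 55)
  pop <- seed_population(simulation_config(density = cells_per_cm2(1.33e4),
                                           seed = 4))
  expect_equal(length(pop$x), 133)
  expect_true(all(pop$theta > -pi / 2 & pop$theta <= pi / 2))
  expect_true(all(pop$age >= 0 & pop$age <= 71))
  expect_gte(min_pairwise_distance(pop$x, pop$y), 2 * 0.3888)
  # impossible density errors out with the achievable figure
  expect_error(seed_population(simulation_config(domain = c(10, 10),
                                                 density = 4e6, radius = 2)),
               "achievable density")
})

test_that("a zero-tick run returns the seeded state with fold change 1", {
  cfg <- quick_config(ticks = 0, seed = 8)
  sim <- run_simulation(cfg)
  expect_equal(fold_change(sim, 0), 1)
  expect_equal(nrow(sim$snapshots[["0"]]), sim$counts[1])
  expect_equal(nrow(sim$events), 0)
})

test_that("identical config and seed reproduce bit-identically", {
  cfg <- quick_config(ticks = 36, density = 133, seed = 123,
                      strain = strain_cycle(x = c(0, 0.10)),
                      fibers = fiber_spec(mean_deg = 90, kappa = 5))
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$events, b$events)
  expect_identical(a$field$angle, b$field$angle)
  # a different seed gives a different trajectory
  cfg$seed <- 124
  expect_false(identical(run_simulation(cfg)$counts, a$counts))
})

test_that("mean growth matches the analytic age-structured expectation", {
  # independent oracle: deterministic propagation of the expected mass per
  # age atom under the same apoptosis/division schedule (dilute limit)
  cfg <- quick_config(ticks = 48, density = 40, seed = 0)
  expected <- expected_fold_zero_strain(48, cfg$turnover)
  folds <- vapply(1:50, function(k) {
    cfg$seed <- 7000 + k
    cfg$keep_events <- FALSE
    fold_change(run_simulation(cfg))
  }, numeric(1))
  se <- stats::sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - expected), 3 * se)

  # death-only limit (proliferation switched off by a huge doubling time)
  cfg2 <- quick_config(ticks = 48, density = 100, seed = 0,
                       turnover = turnover_params(C_prolif = 1e6))
  expected2 <- (1 - 0.0164)^(48 %/% 4)
  folds2 <- vapply(1:50, function(k) {
    cfg2$seed <- 7100 + k
    cfg2$keep_events <- FALSE
    fold_change(run_simulation(cfg2))
  }, numeric(1))
  se2 <- stats::sd(folds2) / sqrt(length(folds2))
  expect_lt(abs(mean(folds2) - expected2), 3 * se2)
})

test_that("fold_change validates ticks and divides by the initial count", {
  cfg <- quick_config(ticks = 12, seed = 2)
  sim <- run_simulation(cfg)
  expect_equal(fold_change(sim, 0), 1)
  expect_equal(fold_change(sim, 12), sim$counts[13] / sim$counts[1])
  expect_error(fold_change(sim, 13), "not recorded")
  expect_error(fold_change(sim, -1), "not recorded")
})

test_that("strain avoidance emerges on PDMS even without cell rotation", {
  th <- unlist(lapply(1:8, function(k) {
    cfg <- quick_config(ticks = 72, density = 133, seed = 500 + k,
                        strain = strain_cycle(x = c(0, 0.10)),
                        reorientation = reorientation_params(k_rot_c = 0))
    cfg$keep_events <- FALSE
    run_simulation(cfg)$snapshots[["72"]]$theta
  }))
  # pooled final orientations concentrate near +/-90 deg to the strain axis
  expect_lt(abs(angle_diff(axial_mean(th), pi / 2)), 15 * pi / 180)
  expect_gt(axial_resultant(th), 0.15)
})

test_that("orientations converge to the fiber distribution on structured substrates", {
  cfg <- quick_config(ticks = 60, density = 133, seed = 42,
                      strain = strain_cycle(x = c(0, 0.10)),
                      fibers = fiber_spec(mean_deg = 30, kappa = 100))
  cfg$keep_events <- FALSE
  sim <- run_simulation(cfg)
  th <- sim$snapshots[["60"]]$theta
  expect_lt(abs(angle_diff(axial_mean(th), 30 * pi / 180)), 5 * pi / 180)
  expect_gt(axial_resultant(th), 0.9)
})

test_that("orientation histograms bin axial angles over (-90, 90]", {
  h <- orientation_histogram(c(0, 0.1, pi / 2, -pi / 2 + 0.01), width_deg = 10)
  expect_equal(nrow(h), 18)
  expect_equal(sum(h$count), 4)
  # bins are (lower, upper]: 0 rad falls in (-10, 0], 0.1 rad in (0, 10]
  expect_equal(h$count[h$lower_deg == -10], 1)
  expect_equal(h$count[h$lower_deg == 0], 1)
  expect_equal(h$count[h$lower_deg == 80], 1)   # pi/2
  expect_equal(h$count[h$lower_deg == -90], 1)  # just past the wrap
  cfg <- quick_config(ticks = 6, seed = 3)
  sim <- run_simulation(cfg)
  expect_equal(sum(orientation_histogram(sim)$count),
               sim$counts[7])
})

test_that("quiver export writes one row per live cell", {
  cfg <- quick_config(ticks = 6, seed = 31)
  sim <- run_simulation(cfg)
  f <- tempfile(fileext = ".csv")
  out <- write_quiver_csv(sim, f)
  back <- read.csv(f)
  expect_equal(nrow(back), sim$counts[7])
  expect_equal(names(back), c("x", "y", "theta_rad"))
  unlink(f)
})
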