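test_that("turnover laws evaluate to their calibrated values", {
  to <- turnover_params()
  # baseline apoptosis 1.64% per check; +1% per percent strain
  expect_equal(apoptosis_probability(0, to), 0.0164)
  expect_equal(apoptosis_probability(0.10, to), 0.1164)
  expect_equal(apoptosis_probability(0, turnover_params(A_apop = 0,
                                                        B_apop = 0)), 0)
  # clamped to [0, 1]
  expect_equal(apoptosis_probability(2, turnover_params(A_apop = 100)), 1)

  # doubling time: 71 h unstrained; quadratic in fractional strain
  expect_equal(doubling_time(0, to), 71)
  expect_equal(doubling_time(0.1, turnover_params(B_prolif = 450)), 151)
  expect_equal(doubling_time(0.3, turnover_params(A_prolif = 0,
                                                  B_prolif = 0)), 71)

  # age gate: 0 at birth, 1/2 at the doubling time, 1 for old cells
  expect_equal(proliferation_probability(71, 71, 9), 0.5)
  expect_lt(proliferation_probability(0, 71, 9), 1e-14)
  expect_equal(proliferation_probability(1e4, 71, 9), 1)
  ages <- seq(0, 200, by = 0.5)
  p <- proliferation_probability(ages, 71, 9)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) >= 0))
})

test_that("daughter placement respects space, boundaries and hard spheres", {
  dom <- c(100, 100); r <- 2
  # isolated parent mid-domain: a daughter appears at exactly 2 R_c
  set.seed(3)
  for (rep in 1:20) {
    site <- place_daughter(c(50, 50), 50, 50, r, dom, u = runif(1))
    expect_false(is.null(site))
    expect_equal(sqrt(sum((site - c(50, 50))^2)), 2 * r)
  }
  # hexagonal ring of touching neighbours: no space anywhere
  psi <- (0:5) * pi / 3
  nx <- c(50, 50 + 2 * r * cos(psi)); ny <- c(50, 50 + 2 * r * sin(psi))
  expect_null(place_daughter(c(50, 50), nx, ny, r, dom, u = 0.37))
  # corner parent: every candidate stays inside the rectangle
  for (u in seq(0, 0.99, by = 0.07)) {
    site <- place_daughter(c(0, 0), 0, 0, r, dom, u = u)
    expect_true(all(site >= 0 & site <= 100))
  }
  # a single blocking neighbour: no daughter lands within 2 R_c of it
  sites <- t(replicate(200, place_daughter(c(50, 50), c(50, 50),
                                           c(50, 50 + 2 * r), r, dom,
                                           u = runif(1))))
  d_neigh <- sqrt((sites[, 1] - 50)^2 + (sites[, 2] - (50 + 2 * r))^2)
  expect_true(all(d_neigh >= 2 * r * (1 - 1e-9)))
  expect_true(any(d_neigh < 4 * r))  # but nearby candidates still allowed
})

test_that("apoptosis sweep removals are binomial at the law's rate", {
  to <- turnover_params()
  expect_equal(sum(apoptosis_sweep(rep(0, 500),
                                   turnover_params(A_apop = 0, B_apop = 0))), 0)
  expect_equal(sum(apoptosis_sweep(rep(0, 500),
                                   turnover_params(A_apop = 0, B_apop = 100))),
               500)
  set.seed(9)
  removed <- sum(apoptosis_sweep(rep(0, 10000), to))
  # binomial n = 10000, p = 0.0164: mean 164, sd 12.7; stay within 3 sd
  expect_gt(removed, 164 - 3 * 12.7)
  expect_lt(removed, 164 + 3 * 12.7)
})

test_that("event log reconciles counts and no overlap ever appears", {
  cfg <- quick_config(ticks = 48, density = 133, seed = 5,
                      strain = strain_cycle(x = c(0, 0.10)))
  sim <- run_simulation(cfg)
  births <- sum(sim$events$event == "birth")
  deaths <- sum(sim$events$event == "death")
  expect_equal(sim$counts[49], sim$counts[1] + births - deaths)
  # per-tick reconciliation of the full count trajectory
  for (t in 1:48) {
    ev <- sim$events[sim$events$tick == t, ]
    expect_equal(sim$counts[t + 1] - sim$counts[t],
                 sum(ev$event == "birth") - sum(ev$event == "death"))
  }
  final <- sim$snapshots[["48"]]
  # daughters sit at exactly 2 R_c from their parent, so allow float slack
  expect_gte(min_pairwise_distance(final$x, final$y),
             2 * cfg$radius * (1 - 1e-9))
  expect_true(all(final$x >= 0 & final$x <= 1000 &
                    final$y >= 0 & final$y <= 1000))
})

test_that("zero strain with calibrated parameters gives net growth", {
  cfg <- quick_config(ticks = 72, density = 100, seed = 2)
  f <- mean_fold_over_seeds(cfg, seeds = 1:10)
  expect_gt(f, 1)
})

test_that("strain bias: perpendicular cells out-survive parallel cells without rotation", {
  # the headline selective-turnover mechanism: with k_rot_c = 0 no cell ever
  # rotates, yet the population drifts perpendicular to the strain axis
  folds <- t(sapply(1:10, function(k) {
    cfg <- quick_config(ticks = 72, density = 133, seed = 600 + k,
                        strain = strain_cycle(x = c(0, 0.10)),
                        reorientation = reorientation_params(k_rot_c = 0))
    sim <- run_simulation(cfg)
    th0 <- sim$snapshots[["0"]]$theta
    thF <- sim$snapshots[["72"]]$theta
    perp0 <- sum(abs(abs(th0) - pi / 2) < pi / 6)
    par0 <- sum(abs(th0) < pi / 6)
    c(perp = sum(abs(abs(thF) - pi / 2) < pi / 6) / perp0,
      par = sum(abs(thF) < pi / 6) / par0)
  }))
  expect_gt(mean(folds[, "perp"]), mean(folds[, "par"]))
  expect_gt(mean(folds[, "perp"]), 1.2 * mean(folds[, "par"]))
})
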