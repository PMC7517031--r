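test_that("basin classification follows the sign of z", {
  cfg <- default_cfg()
  expect_equal(classify_basin(c(0.3, -0.2, 0.7), cfg), "slow")
  expect_equal(classify_basin(c(0.3, -0.2, -0.7), cfg), "fast")
  expect_equal(classify_basin(c(1, 1, 0), cfg), "boundary")
  # sign decides even from tiny offsets (the z = 0 plane is invariant)
  expect_equal(classify_basin(c(0, 0, 1e-4), cfg), "slow")
  expect_equal(classify_basin(c(0, 0, -1e-4), cfg), "fast")
})

test_that("period estimation recovers closed-form and simulated periods", {
  tt <- seq(0, 6.2, 0.002)
  circ <- data.frame(t = tt, x = cos(2 * pi * tt), y = sin(2 * pi * tt),
                     z = 0.8)
  per <- estimate_period(circ)
  expect_equal(as.numeric(per), 1, tolerance = 1e-6)
  expect_gte(attr(per, "n"), 5)
  expect_error(estimate_period(circ[tt < 0.9, ]), "crossings")
  # insensitive to the output step
  cfg <- default_cfg()
  st <- c(0.5, 0, -Z_STAR)
  p1 <- as.numeric(estimate_period(
    integrate_system(cfg, st, t_span = c(0, 30), dt_out = 0.05, tol = 1e-9)))
  p2 <- as.numeric(estimate_period(
    integrate_system(cfg, st, t_span = c(0, 30), dt_out = 0.025, tol = 1e-9)))
  expect_equal(p1, p2, tolerance = 1e-3)
})

test_that("limit-cycle characterization reproduces the attractor statistics", {
  cfg <- quick_cfg()
  slow <- limit_cycle_summary(cfg, "slow", n_trials = 3, seed = 11)
  fast <- limit_cycle_summary(cfg, "fast", n_trials = 3, seed = 12)
  # the slow cycle sits at +z* = 0.8586, the ideal fast cycle mirrors it
  expect_equal(slow$mean_z, 0.858, tolerance = 1.5e-3)
  expect_equal(fast$mean_z, -0.858, tolerance = 1.5e-3)
  expect_gt(slow$mean_z, 0)
  expect_lt(fast$mean_z, 0)
  # on-attractor z is pinned: within-trial spread is numerically zero
  expect_lt(slow$mean_within_trial_sd, 1e-6)
  expect_lt(fast$mean_within_trial_sd, 1e-6)
  # period ordering and the time-rescaling ratio (3/2 + z*)/(3/2 - z*)
  expect_gt(slow$period, fast$period)
  expect_equal(slow$period / fast$period, (1.5 + Z_STAR) / (1.5 - Z_STAR),
               tolerance = 0.01)
})

test_that("the two attractors project onto the same planar orbit", {
  # time-rescaling structure: the x-y projections of the mirrored cycles
  # coincide; sample one period of each densely for the point-set distance
  cfg <- quick_cfg()
  slow <- dense_orbit(cfg, "slow", period_guess = 17, dt = 0.003)
  fast <- dense_orbit(cfg, "fast", period_guess = 4.6, dt = 0.001)
  d <- hausdorff_xy(slow[, c("x", "y")], fast[, c("x", "y")])
  diam <- max(dist(slow[seq(1, nrow(slow), 40), c("x", "y")]))
  expect_lt(d / diam, 1e-3)
})

test_that("deviation statistic measures excursions from the attractor level", {
  flat <- data.frame(t = 0:10, x = 0, y = 0, z = 0.8586)
  expect_equal(max_z_deviation(flat, 0.8586), 0)
  cfg <- quick_cfg()
  st <- c(0.5, 0, Z_STAR)
  quiet <- integrate_system(cfg, st, t_span = c(0, 20), dt_out = 0.05,
                            tol = 1e-10)
  expect_lt(max_z_deviation(quiet, Z_STAR), 1e-6)
  gated <- integrate_system(cfg, st, protocol = gated_protocol(4, "escape"),
                            t_span = c(0, 20), dt_out = 0.05)
  expect_gte(max_z_deviation(gated, Z_STAR), 2 * Z_STAR - 0.05)
})

test_that("attractor counting finds two cycles, or fewer in degenerate regimes", {
  # default regime: two mirrored cycles with opposite z signs
  n <- count_attractors(quick_cfg(), n_samples = 10, seed = 21)
  expect_equal(as.integer(n), 2L)
  cl <- attr(n, "clusters")
  expect_setequal(cl$z_sign, c(-1, 1))
  # sub-unit z gain collapses z to 0: a single planar cycle survives
  n1 <- count_attractors(quick_cfg(g_z = 0.5), n_samples = 10, seed = 22)
  expect_equal(as.integer(n1), 1L)
  expect_equal(attr(n1, "clusters")$z_sign, 0)
  # sub-critical planar gain: the foci become attracting, no periodic orbit
  cfg0 <- quick_cfg()
  cfg0$g_xy <- 0.9  # g cos(alpha) < 1
  n0 <- count_attractors(cfg0, n_samples = 10, seed = 23)
  expect_equal(as.integer(n0), 0L)
})

test_that("trial battery reproduces the outcome matrix and is deterministic", {
  cfg <- quick_cfg(gamma = 10)
  prot <- list(constant = constant_protocol(4),
               random = random_protocol(4, switch_rate = 5),
               # period matched to the unperturbed slow cycle: still fails,
               # since the oscillation frequency shifts as z moves
               periodic = periodic_protocol(4, period = 16.6, duty = 0.5),
               gated = gated_protocol(4, "escape"))
  b1 <- run_trial_battery(cfg, prot, n_trials = 2, seed = 31, record = 25)
  b2 <- run_trial_battery(cfg, prot, n_trials = 2, seed = 31, record = 25)
  expect_identical(b1$trials, b2$trials)
  s <- b1$summary
  expect_equal(s$n_transitions[s$protocol != "gated"], rep(0, 6))
  expect_equal(s$n_transitions[s$protocol == "gated"], c(2, 2))
  # transition times recorded only for transitioned trials
  expect_true(all(is.na(b1$trials$transition_time) |
                    b1$trials$transitioned))
  expect_true(all(!b1$trials$transitioned |
                    is.finite(b1$trials$transition_time)))
  # a slower z subsystem (larger gamma) delays the gated transition
  b3 <- run_trial_battery(quick_cfg(gamma = 20),
                          list(gated = gated_protocol(4, "escape")),
                          n_trials = 2, seed = 31, record = 45)
  expect_gt(mean(b3$trials$transition_time),
            mean(b1$trials$transition_time[b1$trials$protocol == "gated"]))
})

test_that("transition detection requires a sustained sign flip", {
  tt <- seq(0, 10, 0.01)
  # graze: dips below zero for only 0.3 time units
  graze <- data.frame(t = tt, z = ifelse(tt > 5 & tt < 5.3, -0.1, 0.5))
  expect_true(is.na(birhythm:::detect_transition(graze, 1)))
  flip <- data.frame(t = tt, z = ifelse(tt > 5, -0.5, 0.5))
  expect_equal(birhythm:::detect_transition(flip, 1), 5.01, tolerance = 0.02)
})
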