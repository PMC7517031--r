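test_that("general GRU field matches hand evaluation at trivial parameters", {
  zero2 <- matrix(0, 2, 2)
  p <- gru_parameters(Us = zero2, Ur = zero2, Uh = zero2,
                      bs = c(0, 0), br = c(0, 0), bh = c(0, 0))
  # all-zero parameters: s = r = sigma(0) = 0.5, T = tanh(0) = 0
  expect_equal(gru_rhs(c(1, 0), p), c(-0.5, 0))
  # zero-bias parameters always fix the origin
  p2 <- gru_parameters(Us = diag(2), Ur = diag(2), Uh = matrix(rnorm(4), 2),
                       bs = c(0, 0), br = c(0, 0), bh = c(0, 0))
  expect_equal(gru_rhs(c(0, 0), p2), c(0, 0))
})

test_that("GRU field validates dimensions and finiteness", {
  p <- gru_parameters(Us = diag(3), Ur = diag(3), Uh = diag(3),
                      bs = numeric(3), br = numeric(3), bh = numeric(3))
  expect_error(gru_rhs(c(1, 2), p), "length")
  expect_error(gru_rhs(c(1, NaN, 0), p), "non-finite")
  expect_error(gru_parameters(Us = diag(2), Ur = diag(3), Uh = diag(3),
                              bs = numeric(3), br = numeric(3),
                              bh = numeric(3)),
               "3x3")
})

test_that("GRU rendering of the birhythmic config reproduces the explicit field", {
  for (cfg in list(default_cfg(), quick_cfg(),
                   make_birhythmic_config(gamma = 1),
                   make_birhythmic_config(alpha = pi / 6, g_xy = 2.5,
                                          g_z = 3, gamma = 7))) {
    p <- as_gru_parameters(cfg)
    set.seed(42)
    for (k in 1:25) {
      h <- runif(3, -1.4, 1.4)
      expect_lt(max(abs(gru_rhs(h, p) - birhythmic_rhs(h, cfg))), 1e-12)
    }
  }
})

test_that("explicit field matches direct arithmetic of the model equations", {
  cfg <- make_birhythmic_config(gamma = 1)
  st <- c(0.5, 0.5, 0)
  got <- birhythmic_rhs(st, cfg)
  # hand evaluation, written out term by term
  ca <- cos(pi / 5); sa <- sin(pi / 5)
  expect_equal(got[1], 1.5 * (tanh(3 * (0.5 * ca - 0.5 * sa)) - 0.5))
  expect_equal(got[2], 1.5 * (tanh(3 * (0.5 * sa + 0.5 * ca)) - 0.5))
  expect_equal(got[3], 0.5 * (tanh(1.5 * 0) - 0))
  # origin is a fixed point; the z-axis is invariant
  expect_equal(birhythmic_rhs(c(0, 0, 0), cfg), c(0, 0, 0))
  for (z in c(-1.2, -0.3, 0.7, 1.2)) {
    expect_equal(birhythmic_rhs(c(0, 0, z), cfg)[1:2], c(0, 0))
  }
})

test_that("stimulus enters only the z equation, scaled by gamma and kappa", {
  cfg <- make_birhythmic_config(gamma = 10, stim_gain = 2)
  st <- c(0.4, -0.3, 0.6)
  d0 <- birhythmic_rhs(st, cfg, stim_out = 0)
  d1 <- birhythmic_rhs(st, cfg, stim_out = 1.5)
  expect_equal(d1[1:2], d0[1:2])
  expect_equal(d1[3] - d0[3], 2 * 1.5 / 10)
})

test_that("z subsystem decouples from x and y and is odd in z", {
  cfg <- default_cfg()
  set.seed(7)
  for (k in 1:50) {
    z <- runif(1, -1.4, 1.4)
    a <- birhythmic_rhs(c(runif(1, -1.5, 1.5), runif(1, -1.5, 1.5), z), cfg)
    b <- birhythmic_rhs(c(runif(1, -1.5, 1.5), runif(1, -1.5, 1.5), z), cfg)
    expect_equal(a[3], b[3])
    neg <- birhythmic_rhs(c(0.2, 0.1, -z), cfg)
    expect_equal(neg[3], -a[3])
  }
})

test_that("planar velocity rescales with the z-dependent speed factor", {
  cfg <- default_cfg()
  set.seed(11)
  for (k in 1:20) {
    xy <- runif(2, -1.4, 1.4)
    z1 <- runif(1, -1.4, 1.4); z2 <- runif(1, -1.4, 1.4)
    d1 <- birhythmic_rhs(c(xy, z1), cfg)[1:2]
    d2 <- birhythmic_rhs(c(xy, z2), cfg)[1:2]
    ratio <- (1.5 - z1) / (1.5 - z2)
    expect_equal(d1, ratio * d2, tolerance = 1e-12)
  }
})

test_that("configuration constructor enforces the admissibility bounds", {
  expect_error(make_birhythmic_config(alpha = pi / 2), "admissible")
  expect_error(make_birhythmic_config(alpha = pi / 30), "admissible")
  expect_error(make_birhythmic_config(g_xy = 1.2),
               "not unstable")  # 1.2 cos(pi/5) < 1
  expect_error(make_birhythmic_config(gamma = -1), "gamma")
  expect_silent(validate_birhythmic_config(make_birhythmic_config()))
})

test_that("z fixed point solves z = tanh(g z) and matches a bisection oracle", {
  # no nontrivial root at sub-unit gain
  expect_identical(z_fixed_point(0.5), 0)
  expect_identical(z_fixed_point(1), 0)
  # independent bisection oracle
  bisect <- function(g) {
    lo <- 1e-6; hi <- 1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (mid - tanh(g * mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (g in c(1.5, 2, 3)) {
    zs <- z_fixed_point(g)
    expect_equal(zs, bisect(g), tolerance = 1e-10)
    expect_lt(abs(zs - tanh(g * zs)), 1e-12)
  }
  # the default gain puts the slow cycle at the measured 0.858 V level
  # (agreement at the printed precision; the exact root is 0.858560)
  expect_equal(z_fixed_point(1.5), 0.858, tolerance = 1.5e-3)
  expect_equal(z_fixed_point(3), 0.995, tolerance = 1e-3)
})

test_that("fixed points are the origin and the mirrored pair, correctly labeled", {
  cfg <- default_cfg()
  fps <- find_fixed_points(cfg)
  expect_length(fps, 3)
  states <- t(vapply(fps, `[[`, numeric(3), "state"))
  expect_true(all(states[, 1:2] == 0))
  expect_equal(sort(states[, 3]), sort(c(0, Z_STAR, -Z_STAR)),
               tolerance = 1e-9)
  labs <- vapply(fps, `[[`, character(1), "stability")
  expect_equal(labs[states[, 3] == 0], "source")
  expect_true(all(labs[states[, 3] != 0] == "saddle"))
  # mirrored points: attracting in z, unstable focus in the plane
  for (fp in fps) {
    if (fp$state[3] == 0) next
    re <- sort(Re(fp$eigenvalues))
    expect_lt(re[1], 0)
    expect_gt(re[2], 0)
    expect_gt(max(abs(Im(fp$eigenvalues))), 0)
  }
  # origin's planar expansion rate is (3/2)(g cos(alpha) - 1)
  origin <- fps[[which(states[, 3] == 0)]]
  expect_equal(max(Re(origin$eigenvalues)),
               1.5 * (3 * cos(pi / 5) - 1), tolerance = 1e-5)
  # sub-unit z gain leaves only the origin
  expect_length(find_fixed_points(make_birhythmic_config(g_z = 0.5)), 1)
})

test_that("numerical Jacobian agrees with the closed-form linearization", {
  cfg <- make_birhythmic_config(gamma = 20)
  J <- jacobian_at(c(0, 0, 0), cfg)
  ca <- cos(pi / 5); sa <- sin(pi / 5)
  expect_equal(J[1:2, 1:2],
               1.5 * (3 * matrix(c(ca, sa, -sa, ca), 2) - diag(2)),
               tolerance = 1e-6)
  expect_equal(J[3, 3], (1.5 - 1) / (2 * 20), tolerance = 1e-6)
  expect_equal(J[3, 1:2], c(0, 0))
  # z row stays decoupled away from the origin too
  J2 <- jacobian_at(c(0.3, -0.4, Z_STAR), cfg)
  expect_equal(J2[3, 1:2], c(0, 0))
})
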