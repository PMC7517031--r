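# Shared fixtures. Tests that only probe qualitative structure use a faster
# z subsystem (small gamma) to keep horizons short; quantitative checks
# against the default study conditions use default_cfg().

default_cfg <- function() make_birhythmic_config()

# gamma = 5: z time constant ~17 units, gated traversal ~9 units
quick_cfg <- function(gamma = 5, ...) make_birhythmic_config(gamma = gamma, ...)

Z_STAR <- 0.858559636604311  # positive root of z = tanh(1.5 z)

# Independent batched integrator: stacks n copies of the unstimulated system
# into one 3n-dimensional ODE with elementwise (vectorized) right-hand side,
# written out directly from the model equations. Used for property sweeps
# over many random starts.
batch_integrate <- function(cfg, X0, t_span, dt_out = 0.1) {
  n <- nrow(X0)
  ca <- cos(cfg$alpha); sa <- sin(cfg$alpha)
  f <- function(t, s, p) {
    x <- s[1:n]; y <- s[n + 1:n]; z <- s[2 * n + 1:n]
    sp <- (1 - cfg$s_bias[1]) - z
    list(c(sp * (tanh(cfg$g_xy * (x * ca - y * sa)) - x),
           sp * (tanh(cfg$g_xy * (x * sa + y * ca)) - y),
           (1 - cfg$s_bias[3]) / cfg$gamma * (tanh(cfg$g_z * z) - z)))
  }
  out <- deSolve::ode(y = c(X0[, 1], X0[, 2], X0[, 3]),
                      times = seq(t_span[1], t_span[2], by = dt_out),
                      func = f, parms = NULL, rtol = 1e-8, atol = 1e-8,
                      maxsteps = 500000)
  list(t = out[, 1],
       x = out[, 1 + 1:n, drop = FALSE],
       y = out[, 1 + n + 1:n, drop = FALSE],
       z = out[, 1 + 2 * n + 1:n, drop = FALSE])
}

# Symmetric Hausdorff distance between two 2-D point sets, chunked to keep
# the pairwise-distance blocks small
hausdorff_xy <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  directed <- function(P, Q) {
    worst <- 0
    idx <- split(seq_len(nrow(P)), ceiling(seq_len(nrow(P)) / 400))
    for (i in idx) {
      d2 <- outer(P[i, 1], Q[, 1], `-`)^2 + outer(P[i, 2], Q[, 2], `-`)^2
      worst <- max(worst, sqrt(max(apply(d2, 1, min))))
    }
    worst
  }
  max(directed(A, B), directed(B, A))
}

# One densely sampled period of the limit cycle in the given basin,
# converged onto the attractor first
dense_orbit <- function(cfg, basin, period_guess, dt) {
  z0 <- if (basin == "slow") Z_STAR else -Z_STAR
  relax <- if (basin == "slow") 120 else 35
  rel <- integrate_system(cfg, c(0.5, 0, z0), t_span = c(0, relax),
                          dt_out = relax / 4, tol = 1e-10)
  st <- as.numeric(rel[nrow(rel), c("x", "y", "z")])
  integrate_system(cfg, st, t_span = c(0, period_guess), dt_out = dt,
                   tol = 1e-10)
}
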