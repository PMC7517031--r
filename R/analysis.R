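# Attractor characterization and trial batteries.
#
# Timescale conventions: the slow limit cycle has period ~16.6 time units at
# the default parameters and the z subsystem relaxes with time constant
# ~gamma/0.3, so horizons below are expressed in multiples of gamma (for
# relaxation) or chosen to cover >= 5 slow periods (for recording).

# Deterministic seed-splitting rule: every random operation consumes a seed
# derived from the master seed and its index path. Kept below 2^31.
split_seed <- function(master, ...) {
  idx <- c(...)
  s <- master %% 2147483647
  for (k in seq_along(idx)) {
    s <- (s * 69069 + idx[k] * 10007 + k) %% 2147483647
  }
  as.integer(s)
}

# Integrate only the decoupled z equation (dz/dt is independent of x and y),
# in chunks, until |dz/dt| < dz_tol. Returns the settled z.
settle_z <- function(config, z0, dz_tol = 1e-8, max_horizon = NULL) {
  if (is.null(max_horizon)) max_horizon <- 400 * config$gamma
  zrate <- 1 - config$s_bias[3]
  invg <- 1 / config$gamma
  f <- function(t, z, p) list(invg * zrate * (tanh(config$g_z * z) - z))
  chunk <- 20 * config$gamma
  t_done <- 0
  z <- z0
  while (t_done < max_horizon) {
    out <- deSolve::ode(y = z, times = c(0, chunk), func = f, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
    z <- out[nrow(out), 2]
    t_done <- t_done + chunk
    if (abs(invg * zrate * (tanh(config$g_z * z) - z)) < dz_tol) return(z)
  }
  stop(sprintf("z did not settle within %g time units", max_horizon))
}

#' Classify the basin of attraction of an initial state
#'
#' The plane z = 0 is invariant and separates the basins, and dz/dt does not
#' depend on x or y, so the basin is decided by relaxing the decoupled z
#' subsystem until it settles (|dz/dt| < 1e-8).
#'
#' @param x0 length-3 initial state.
#' @param config a [make_birhythmic_config()] object.
#' @param delta half-width of the boundary band: states with `|z0| <= delta`
#'   are labeled `"boundary"`.
#' @return `"slow"` (z > 0 attractor), `"fast"` (z < 0), or `"boundary"`.
#' @examples
#' classify_basin(c(0.3, -0.2, 0.7), make_birhythmic_config())   # "slow"
#' @export
classify_basin <- function(x0, config, delta = 1e-6) {
  stopifnot(length(x0) == 3L, all(is.finite(x0)))
  validate_birhythmic_config(config, bounds = FALSE)
  if (abs(x0[3]) <= delta) return("boundary")
  z_end <- settle_z(config, x0[3])
  if (z_end > delta) "slow" else if (z_end < -delta) "fast" else "boundary"
}

#' Estimate the oscillation period from a trajectory
#'
#' Mean spacing of same-direction crossings of the Poincare section
#' `{y = 0, x > 0}` (upward in y). The trajectory should sit on (or near) an
#' attractor and cover at least a few cycles.
#'
#' @param traj a `birhythm_trajectory`.
#' @return The period (time units), with attributes `se` (standard error of
#'   the mean spacing) and `n` (number of spacings).
#' @examples
#' tt <- seq(0, 6, 0.002)
#' circ <- data.frame(t = tt, x = cos(2 * pi * tt), y = sin(2 * pi * tt),
#'                    z = 0.8)
#' estimate_period(circ)  # 1
#' @export
estimate_period <- function(traj) {
  cr <- detect_plane_crossings(traj, "y", 0)
  if (nrow(cr)) {
    # keep upward crossings on the x > 0 half-plane
    xi <- stats::approx(traj$t, traj$x, xout = cr$time)$y
    cr <- cr[cr$direction > 0 & xi > 0, , drop = FALSE]
  }
  if (nrow(cr) < 2) {
    stop("fewer than 2 Poincare-section crossings; record a longer trajectory")
  }
  sp <- diff(cr$time)
  per <- mean(sp)
  structure(per,
            se = if (length(sp) > 1) sd(sp) / sqrt(length(sp)) else NA_real_,
            n = length(sp))
}

#' Maximum z-excursion from a reference level
#'
#' `max |z(t) - z_ref|` over a trajectory — the scalar deviation statistic
#' used to quantify how far a stimulation protocol pushes the state away
#' from the limit cycle it started on (the limit cycles have essentially
#' constant z, so the scalar excursion is the meaningful distance).
#'
#' @param traj a `birhythm_trajectory`.
#' @param z_ref reference z level (the attractor's z coordinate).
#' @return The maximum absolute excursion, volts.
#' @export
max_z_deviation <- function(traj, z_ref) {
  stopifnot(nrow(traj) > 0, is.finite(z_ref))
  max(abs(traj$z - z_ref))
}

#' Characterize one limit cycle from randomized trials
#'
#' Reproduces the unstimulated characterization protocol: `n_trials` initial
#' states drawn uniformly from the basin box ((-1.5, 1.5)^2 x (0, 1.5) for
#' the slow cycle, (-1.5, 1.5)^2 x (-1.5, 0) for the fast), each relaxed
#' onto the attractor and then recorded; per-trial mean and standard
#' deviation of z are aggregated into the mean of trial means and the
#' standard deviation across trial means.
#'
#' @param config a [make_birhythmic_config()] object.
#' @param basin `"slow"` or `"fast"`.
#' @param n_trials number of randomized trials.
#' @param seed master seed; trial i uses the split seed `(seed, i)`.
#' @param relax relaxation horizon before recording (time units). The z time
#'   constant is about `3.3 * gamma`, so the default `50 * gamma` settles z
#'   well below measurement precision.
#' @param record recording horizon; the default covers about five slow-cycle
#'   periods.
#' @param dt_out recording sample interval.
#' @return An object of class `limit_cycle_summary`: basin label, `mean_z`
#'   (mean of trial means), `sd_across_trials`, `mean_within_trial_sd`,
#'   `period` (with standard error), the recorded x-y `orbit` of the last
#'   trial, and the per-trial table `trials`.
#' @export
limit_cycle_summary <- function(config, basin = c("slow", "fast"),
                                n_trials = 10, seed = 1,
                                relax = 50 * config$gamma, record = 85,
                                dt_out = 0.05) {
  basin <- match.arg(basin)
  stopifnot(n_trials >= 1)
  validate_birhythmic_config(config, bounds = FALSE)
  zlim <- if (basin == "slow") c(0, 1.5) else c(-1.5, 0)
  rows <- vector("list", n_trials)
  orbit <- NULL
  for (i in seq_len(n_trials)) {
    si <- split_seed(seed, i)
    x0 <- with_local_seed(si, function() {
      c(runif(2, -1.5, 1.5), runif(1, zlim[1], zlim[2]))
    })
    rel <- integrate_system(config, x0, t_span = c(0, relax),
                            dt_out = max(relax / 8, dt_out), tol = 1e-10)
    st <- as.numeric(rel[nrow(rel), c("x", "y", "z")])
    rec <- integrate_system(config, st, t_span = c(0, record),
                            dt_out = dt_out, tol = 1e-10)
    per <- estimate_period(rec)
    rows[[i]] <- data.frame(
      trial = i, seed = si,
      x0 = x0[1], y0 = x0[2], z0 = x0[3],
      mean_z = mean(rec$z), sd_z = sd(rec$z), period = as.numeric(per)
    )
    if (i == n_trials) orbit <- rec[, c("x", "y")]
  }
  trials <- do.call(rbind, rows)
  structure(
    list(basin = basin,
         mean_z = mean(trials$mean_z),
         sd_across_trials = sd(trials$mean_z),
         mean_within_trial_sd = mean(trials$sd_z),
         period = mean(trials$period),
         period_se = sd(trials$period) / sqrt(n_trials),
         orbit = orbit,
         trials = trials),
    class = "limit_cycle_summary"
  )
}

#' @export
print.limit_cycle_summary <- function(x, ...) {
  cat(sprintf("%s limit cycle (%d trials)\n", x$basin, nrow(x$trials)))
  cat(sprintf("  mean z (mean of trial means): % .6f V\n", x$mean_z))
  cat(sprintf("  sd across trial means       : %.3e V\n", x$sd_across_trials))
  cat(sprintf("  mean within-trial sd        : %.3e V\n",
              x$mean_within_trial_sd))
  cat(sprintf("  period                      : %.4f time units\n", x$period))
  invisible(x)
}

#' Count the periodic attractors by seeded random sampling
#'
#' Samples initial states uniformly from `[-1.5, 1.5]^3` (excluding a band
#' `|z| < 0.05` around the separatrix), relaxes each, records, and clusters
#' the outcomes by the sign of the mean z level and by period (within 5%).
#' Trajectories that collapse to a fixed point (x-y amplitude below 1e-3)
#' are not counted as periodic attractors.
#'
#' @param config a [make_birhythmic_config()] object.
#' @param n_samples number of random starts, >= 10.
#' @param seed master seed.
#' @param relax,record,dt_out horizons as in [limit_cycle_summary()].
#' @return The number of distinct periodic attractors found, with attribute
#'   `clusters` (a data frame with one row per cluster: z sign, mean period,
#'   cluster size).
#' @examples
#' \donttest{
#' count_attractors(make_birhythmic_config(), n_samples = 10, seed = 1)  # 2
#' }
#' @export
count_attractors <- function(config, n_samples = 20, seed = 1,
                             relax = 20 * config$gamma, record = 100,
                             dt_out = 0.05) {
  stopifnot(n_samples >= 10)
  validate_birhythmic_config(config, bounds = FALSE)
  draws <- with_local_seed(split_seed(seed, 1), function() {
    out <- matrix(NA_real_, n_samples, 3)
    for (i in seq_len(n_samples)) {
      repeat {
        v <- runif(3, -1.5, 1.5)
        if (abs(v[3]) >= 0.05) break
      }
      out[i, ] <- v
    }
    out
  })
  res <- lapply(seq_len(n_samples), function(i) {
    rel <- integrate_system(config, draws[i, ], t_span = c(0, relax),
                            dt_out = max(relax / 8, dt_out), tol = 1e-9)
    st <- as.numeric(rel[nrow(rel), c("x", "y", "z")])
    rec <- integrate_system(config, st, t_span = c(0, record),
                            dt_out = dt_out, tol = 1e-9)
    if (sd(rec$x) < 1e-3) return(NULL)  # spiraled into a sink
    mz <- mean(rec$z)
    zsign <- if (mz > 0.05) 1 else if (mz < -0.05) -1 else 0
    data.frame(z_sign = zsign, period = as.numeric(estimate_period(rec)))
  })
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res)) {
    return(structure(0L, clusters = data.frame(z_sign = numeric(0),
                                               period = numeric(0),
                                               n = integer(0))))
  }
  clusters <- list()
  for (sgn in unique(res$z_sign)) {
    pers <- sort(res$period[res$z_sign == sgn])
    cur <- pers[1]; members <- 1
    for (p in pers[-1]) {
      ref <- cur / members  # running cluster mean
      if (abs(p - ref) / ref <= 0.05) {
        cur <- cur + p; members <- members + 1
      } else {
        clusters[[length(clusters) + 1]] <-
          data.frame(z_sign = sgn, period = cur / members, n = members)
        cur <- p; members <- 1
      }
    }
    clusters[[length(clusters) + 1]] <-
      data.frame(z_sign = sgn, period = cur / members, n = members)
  }
  clusters <- do.call(rbind, clusters)
  structure(nrow(clusters), clusters = clusters)
}

# Dense one-period-plus pool of on-attractor states used to initialize
# stimulation trials at a random phase.
attractor_phase_pool <- function(config, basin, relax = 60 * config$gamma,
                                 dt = 0.01) {
  zs <- z_fixed_point(config$g_z)
  z0 <- if (basin == "slow") max(zs, 0.5) else -max(zs, 0.5)
  rel <- integrate_system(config, c(0.5, 0, z0), t_span = c(0, relax),
                          dt_out = relax / 8, tol = 1e-10)
  st <- as.numeric(rel[nrow(rel), c("x", "y", "z")])
  # one slow period is ~17 units at defaults; 25 covers any admissible alpha
  rec <- integrate_system(config, st, t_span = c(0, 25), dt_out = dt,
                          tol = 1e-10)
  per <- tryCatch(as.numeric(estimate_period(rec)), error = function(e) 25)
  rec[rec$t <= per, c("x", "y", "z")]
}

# First time at which sign(z) stays opposite to sign0 for >= sustain time
# units; NA if never. Guards against counting grazes of the separatrix.
detect_transition <- function(traj, sign0, sustain = 1) {
  opp <- sign0 * traj$z < 0
  if (!any(opp)) return(NA_real_)
  r <- rle(opp)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    dur <- traj$t[ends[k]] - traj$t[starts[k]]
    if (dur >= sustain) return(traj$t[starts[k]])
  }
  NA_real_
}

#' Run a seeded battery of stimulation trials
#'
#' For each (protocol, basin) cell, runs `n_trials` trials: the state is
#' initialized on the attractor at a seeded random phase, the protocol is
#' applied for the whole recording, and the trial reports the maximum
#' z-excursion from the attractor level and whether a transition occurred
#' (z sign opposite to the initial basin sustained for >= 1 time unit).
#' Random protocols are re-seeded per trial by the documented seed-splitting
#' rule, so the full table is reproducible bit-for-bit from the master seed.
#'
#' @param config a [make_birhythmic_config()] object.
#' @param protocols a named list of [protocols] objects.
#' @param n_trials trials per cell.
#' @param seed master seed.
#' @param record recording horizon per trial (time units). The default
#'   `1.6 * gamma` covers the gated traversal time (about `0.95 * gamma` to
#'   reach z = 0, plus settling) with margin.
#' @param dt_out recording sample interval.
#' @param basins which basins to include.
#' @return An object of class `trial_battery`: `trials` (one row per trial)
#'   and `summary` (one row per cell with transition counts and excursion
#'   statistics).
#' @export
run_trial_battery <- function(config, protocols, n_trials = 10, seed = 1,
                              record = 1.6 * config$gamma, dt_out = 0.05,
                              basins = c("slow", "fast")) {
  validate_birhythmic_config(config, bounds = FALSE)
  stopifnot(length(protocols) >= 1, n_trials >= 1)
  if (is.null(names(protocols)) || any(!nzchar(names(protocols)))) {
    names(protocols) <- vapply(protocols, function(p) p$kind, character(1))
  }
  zs <- z_fixed_point(config$g_z)
  pools <- lapply(setNames(basins, basins), function(b) {
    attractor_phase_pool(config, b)
  })
  rows <- list()
  cell <- 0L
  for (pn in names(protocols)) {
    for (b in basins) {
      cell <- cell + 1L
      pool <- pools[[b]]
      sign0 <- if (b == "slow") 1 else -1
      z_ref <- sign0 * zs
      for (j in seq_len(n_trials)) {
        ts <- split_seed(seed, cell, j)
        phase <- with_local_seed(ts, function() sample.int(nrow(pool), 1))
        x0 <- as.numeric(pool[phase, ])
        prot <- reseed_protocol(protocols[[pn]], split_seed(ts, 1))
        tr <- integrate_system(config, x0, protocol = prot,
                               t_span = c(0, record), dt_out = dt_out,
                               tol = 1e-8, basin = b)
        ttime <- detect_transition(tr, sign0)
        rows[[length(rows) + 1]] <- data.frame(
          protocol = pn, basin = b, trial = j, seed = ts,
          x0 = x0[1], y0 = x0[2], z0 = x0[3],
          max_z_deviation = max_z_deviation(tr, z_ref),
          transitioned = !is.na(ttime),
          transition_time = ttime
        )
      }
    }
  }
  trials <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(
    trials, list(trials$protocol, trials$basin), drop = TRUE),
    function(d) data.frame(
      protocol = d$protocol[1], basin = d$basin[1], n = nrow(d),
      n_transitions = sum(d$transitioned),
      mean_max_dev = mean(d$max_z_deviation),
      sd_max_dev = sd(d$max_z_deviation),
      mean_transition_time = mean(d$transition_time[d$transitioned])
    )))
  rownames(agg) <- NULL
  structure(list(trials = trials, summary = agg, config = config,
                 seed = seed, record = record),
            class = "trial_battery")
}

#' @export
print.trial_battery <- function(x, ...) {
  cat(sprintf("stimulation trial battery (seed %d, record %g units)\n",
              x$seed, x$record))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
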