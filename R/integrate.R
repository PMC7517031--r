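#' Integrate the birhythmic system
#'
#' Adaptive high-order integration (deSolve's `lsoda`) of the birhythmic
#' vector field under an optional stimulation protocol. The raw stimulus is
#' piecewise constant in time (zero-order hold): the integrator is restarted
#' at every protocol breakpoint so on/off edges are resolved exactly, while
#' the interface output `S_out = S_in x y` (with any rectification) is
#' evaluated continuously inside the right-hand side.
#'
#' @param config a [make_birhythmic_config()] object.
#' @param x0 length-3 initial state `(x, y, z)`.
#' @param protocol a [protocols] object, or `NULL` for no stimulation.
#' @param t_span length-2 time span `(t0, t1)`.
#' @param dt_out output sampling interval.
#' @param tol relative/absolute integration tolerance, in `[1e-12, 1e-3]`.
#' @param basin basin label (`"slow"`/`"fast"`) used to orient an
#'   `"escape"`-target gated protocol; inferred from `sign(x0[3])` when
#'   `NULL`.
#' @return A `birhythm_trajectory`: a data frame with columns `t`, `x`, `y`,
#'   `z`, `stim_in`, `stim_out`, carrying the configuration and protocol as
#'   attributes.
#' @examples
#' cfg <- make_birhythmic_config()
#' tr <- integrate_system(cfg, c(0.5, 0, 0.8), t_span = c(0, 5))
#' @export
integrate_system <- function(config, x0, protocol = NULL,
                             t_span = c(0, 10), dt_out = 0.02, tol = 1e-8,
                             basin = NULL) {
  validate_birhythmic_config(config, bounds = FALSE)
  stopifnot(length(x0) == 3L, all(is.finite(x0)),
            length(t_span) == 2L, all(is.finite(t_span)),
            diff(t_span) > 0, dt_out > 0,
            tol >= 1e-12, tol <= 1e-3)
  if (is.null(protocol)) protocol <- no_stim_protocol()
  if (is.null(basin)) basin <- if (x0[3] >= 0) "slow" else "fast"
  pass <- resolve_pass_sign(protocol, basin)
  drop_v <- protocol$diode_drop

  segs <- protocol_segments(protocol, t_span[1], t_span[2])
  grid <- seq(t_span[1], t_span[2], by = dt_out)
  if (tail(grid, 1) < t_span[2]) grid <- c(grid, t_span[2])
  # snap protocol breakpoints onto near-coincident grid points so the
  # integrator never sees two output times closer than ~1e-6 dt
  snap <- function(v) {
    g <- t_span[1] + round((v - t_span[1]) / dt_out) * dt_out
    ifelse(abs(g - v) < dt_out * 1e-6, g, v)
  }
  segs$t_start <- snap(segs$t_start)
  segs$t_end <- snap(segs$t_end)
  segs <- segs[segs$t_end > segs$t_start, , drop = FALSE]

  ca <- cos(config$alpha); sa <- sin(config$alpha)
  gxy <- config$g_xy; gz <- config$g_z
  off <- 1 - config$s_bias[1]
  zrate <- 1 - config$s_bias[3]
  invg <- 1 / config$gamma
  kappa <- config$stim_gain

  derivs <- function(t, h, p) {
    sp <- off - h[3]
    eff <- interface_output(p, h[1], h[2], pass, drop_v)
    list(c(sp * (tanh(gxy * (h[1] * ca - h[2] * sa)) - h[1]),
           sp * (tanh(gxy * (h[1] * sa + h[2] * ca)) - h[2]),
           invg * (zrate * (tanh(gz * h[3]) - h[3]) + kappa * eff)))
  }

  rows <- vector("list", nrow(segs))
  state <- as.numeric(x0)
  for (i in seq_len(nrow(segs))) {
    a <- segs$t_start[i]; b <- segs$t_end[i]; Sin <- segs$S_in[i]
    times <- unique(c(a, grid[grid > a & grid < b], b))
    out <- deSolve::ode(y = state, times = times, func = derivs, parms = Sin,
                        method = "lsoda", rtol = tol, atol = tol,
                        maxsteps = 500000)
    if (nrow(out) < length(times) || any(!is.finite(out))) {
      last_ok <- if (nrow(out)) out[max(which(apply(
        is.finite(out), 1, all))), 1] else a
      stop(sprintf("integration failed near t = %.6g (non-finite state or step-size collapse)",
                   last_ok))
    }
    state <- as.numeric(out[nrow(out), 2:4])
    # emit grid points in [a, b); the final segment also emits t1
    keep <- times %in% grid &
      (times < b | (i == nrow(segs) & times == b))
    om <- out[keep, , drop = FALSE]
    if (nrow(om)) {
      rows[[i]] <- data.frame(
        t = om[, 1], x = om[, 2], y = om[, 3], z = om[, 4],
        stim_in = Sin,
        stim_out = vapply(seq_len(nrow(om)), function(k) {
          interface_output(Sin, om[k, 2], om[k, 3], pass, drop_v)
        }, numeric(1))
      )
    }
  }
  traj <- do.call(rbind, rows)
  rownames(traj) <- NULL
  structure(traj, class = c("birhythm_trajectory", "data.frame"),
            config = config, protocol = protocol, basin = basin)
}

#' @export
print.birhythm_trajectory <- function(x, ...) {
  cat(sprintf("birhythmic trajectory: %d samples, t in [%.4g, %.4g]\n",
              nrow(x), x$t[1], x$t[nrow(x)]))
  cat(sprintf("  final state (% .4f, % .4f, % .4f); protocol: %s\n",
              x$x[nrow(x)], x$y[nrow(x)], x$z[nrow(x)],
              attr(x, "protocol")$kind))
  invisible(x)
}

#' Fixed-step forward-Euler reference integrator
#'
#' A deliberately simple brute-force integrator used as an independent
#' cross-check of [integrate_system()] in the test suite. Same stimulus
#' semantics (zero-order hold on protocol segments, interface evaluated at
#' the current state), first-order accurate.
#'
#' @inheritParams integrate_system
#' @param dt fixed step size, <= 1e-3.
#' @return A `birhythm_trajectory` sampled at every step.
#' @export
integrate_euler_oracle <- function(config, x0, protocol = NULL,
                                   t_span = c(0, 1), dt = 1e-4,
                                   basin = NULL) {
  validate_birhythmic_config(config, bounds = FALSE)
  stopifnot(dt <= 1e-3, dt > 0, diff(t_span) > 0)
  if (is.null(protocol)) protocol <- no_stim_protocol()
  if (is.null(basin)) basin <- if (x0[3] >= 0) "slow" else "fast"
  pass <- resolve_pass_sign(protocol, basin)
  segs <- protocol_segments(protocol, t_span[1], t_span[2])
  n <- floor(round(diff(t_span) / dt, 9))
  tt <- t_span[1] + dt * (0:n)
  seg_idx <- findInterval(tt, segs$t_start)
  Sin <- segs$S_in[seg_idx]
  H <- matrix(NA_real_, n + 1, 3)
  Sout <- numeric(n + 1)
  h <- as.numeric(x0)
  for (k in 0:n) {
    eff <- interface_output(Sin[k + 1], h[1], h[2], pass, protocol$diode_drop)
    H[k + 1, ] <- h
    Sout[k + 1] <- eff
    if (k < n) {
      dh <- birhythmic_rhs(h, config, stim_out = eff)
      h <- h + dt * dh
      if (any(!is.finite(h))) {
        stop(sprintf("Euler integration failed near t = %.6g", tt[k + 1]))
      }
    }
  }
  traj <- data.frame(t = tt, x = H[, 1], y = H[, 2], z = H[, 3],
                     stim_in = Sin, stim_out = Sout)
  structure(traj, class = c("birhythm_trajectory", "data.frame"),
            config = config, protocol = protocol, basin = basin)
}

#' Detect level crossings of one coordinate
#'
#' Linear-interpolated times at which a trajectory coordinate crosses a
#' level. Intervals are half-open `[t_i, t_{i+1})`: a sample lying exactly on
#' the level counts as a crossing with the direction of the following step.
#'
#' @param traj a `birhythm_trajectory` (or any data frame with a `t` column
#'   and the requested coordinate).
#' @param coordinate which coordinate to test: `"x"`, `"y"`, or `"z"`.
#' @param level crossing level, volts.
#' @return A data frame with columns `time` and `direction` (+1 upward, -1
#'   downward); zero rows if the coordinate never crosses.
#' @examples
#' tr <- data.frame(t = seq(0, 1, 0.001), x = 0, y = 0,
#'                  z = sin(2 * pi * seq(0, 1, 0.001)))
#' detect_plane_crossings(tr, "z", 0)
#' @export
detect_plane_crossings <- function(traj, coordinate = c("z", "x", "y"),
                                   level = 0) {
  coordinate <- match.arg(coordinate)
  stopifnot(nrow(traj) > 0)
  v <- traj[[coordinate]] - level
  t <- traj$t
  n <- length(v)
  if (n < 2) return(data.frame(time = numeric(0), direction = numeric(0)))
  a <- v[-n]; b <- v[-1]
  hit <- (a == 0 & b != 0) | (a * b < 0)
  i <- which(hit)
  if (!length(i)) return(data.frame(time = numeric(0), direction = numeric(0)))
  frac <- ifelse(a[i] == 0, 0, -a[i] / (b[i] - a[i]))
  data.frame(time = t[i] + frac * (t[i + 1] - t[i]),
             direction = ifelse(b[i] > a[i], 1, -1))
}

#' Write a trajectory to CSV
#'
#' Columns `t, x, y, z, stim_in, stim_out`, header row, 9 significant
#' digits. The file can be re-read with `read.csv`.
#'
#' @param traj a `birhythm_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)[, c("t", "x", "y", "z", "stim_in", "stim_out")]
  df[] <- lapply(df, function(col) signif(col, 9))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
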