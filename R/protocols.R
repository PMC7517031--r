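#' Stimulator interface output
#'
#' All external stimulation reaches the plant through the bilinear interface
#' `S_out = S_in * x * y`, evaluated at the instantaneous state. Because the
#' x and y components are near-quadrature sinusoids on either limit cycle,
#' x * y averages to zero over a period, so open-loop stimulation produces no
#' net drift in z.
#'
#' @param S_in raw stimulus voltage (`S_in = 0` when no stimulus is applied).
#' @param state length-3 state `(x, y, z)` at which the interface is
#'   evaluated.
#' @return The interface output `S_in * x * y`.
#' @examples
#' stimulator_output(4, c(0.5, -0.5, 0))  # -1
#' @export
stimulator_output <- function(S_in, state) {
  stopifnot(is.finite(S_in), length(state) == 3L, all(is.finite(state)))
  S_in * state[1] * state[2]
}

new_stim_protocol <- function(kind, amplitude, params = list(), seed = NULL,
                              pass_sign = 0, diode_drop = 0) {
  stopifnot(amplitude >= 0)
  structure(list(kind = kind, amplitude = amplitude, params = params,
                 seed = seed, pass_sign = pass_sign, diode_drop = diode_drop),
            class = "stim_protocol")
}

#' Stimulation protocols
#'
#' Constructors for the built-in open-loop stimulation strategies, all
#' producing a raw stimulus `S_in(t)` that is piecewise constant in time and
#' passes through the stimulator interface [stimulator_output()]:
#'
#' * `no_stim_protocol()`: `S_in = 0` always.
#' * `constant_protocol(amplitude)`: `S_in = amplitude` always.
#' * `random_protocol(amplitude, switch_rate, seed)`: a symmetric on/off
#'   telegraph process — exponential holding times with the given rate,
#'   initial phase Bernoulli(1/2) — formalizing "manually random" on/off
#'   stimulation; reproducible under a fixed seed.
#' * `periodic_protocol(amplitude, period, duty)`: square wave, on for
#'   `duty * period` at the start of each period.
#' * `gated_protocol(amplitude, target, diode_drop)`: constant stimulus, but
#'   the interface passes only the `S_out` sign that pushes z toward the
#'   target basin — negative for `"slow_to_fast"`, positive for
#'   `"fast_to_slow"` — emulating a diode placed just before the stimulation
#'   node. `target = "escape"` resolves the direction against the trial's
#'   initial basin. `diode_drop = 0` is an ideal rectifier; 0.6 V
#'   approximates a silicon diode's forward drop (the passed |S_out| is
#'   reduced by the drop, and blocked below it).
#'
#' @param amplitude stimulus voltage when on (the hardware experiments use
#'   4 V on / 0 V off).
#' @param switch_rate expected on/off switching rate per time unit.
#' @param seed integer seed for the telegraph process.
#' @param period,duty square-wave period (time units) and duty cycle in
#'   (0, 1]; `duty = 1` reduces to constant stimulation.
#' @param target transition direction the rectifier is oriented for.
#' @param diode_drop forward voltage drop of the rectifier, >= 0.
#' @return An object of class `stim_protocol`.
#' @name protocols
#' @examples
#' p <- random_protocol(4, switch_rate = 5, seed = 1)
#' g <- gated_protocol(4, target = "slow_to_fast")
NULL

#' @rdname protocols
#' @export
no_stim_protocol <- function() new_stim_protocol("none", 0)

#' @rdname protocols
#' @export
constant_protocol <- function(amplitude = 4) {
  new_stim_protocol("constant", amplitude)
}

#' @rdname protocols
#' @export
random_protocol <- function(amplitude = 4, switch_rate = 5, seed = 1) {
  stopifnot(switch_rate > 0)
  new_stim_protocol("random", amplitude,
                    params = list(switch_rate = switch_rate), seed = seed)
}

#' @rdname protocols
#' @export
periodic_protocol <- function(amplitude = 4, period = 1, duty = 0.5) {
  stopifnot(period > 0, duty > 0, duty <= 1)
  new_stim_protocol("periodic", amplitude,
                    params = list(period = period, duty = duty))
}

#' @rdname protocols
#' @export
gated_protocol <- function(amplitude = 4,
                           target = c("slow_to_fast", "fast_to_slow", "escape"),
                           diode_drop = 0) {
  target <- match.arg(target)
  stopifnot(amplitude > 0, diode_drop >= 0)
  pass <- switch(target, slow_to_fast = -1, fast_to_slow = +1, escape = NA_real_)
  new_stim_protocol("gated", amplitude, params = list(target = target),
                    pass_sign = pass, diode_drop = diode_drop)
}

#' @export
print.stim_protocol <- function(x, ...) {
  extra <- if (length(x$params)) {
    paste0(" [", paste(names(x$params), unlist(x$params), sep = "=",
                       collapse = ", "), "]")
  } else ""
  cat(sprintf("stimulation protocol: %s, amplitude %.3g V%s\n",
              x$kind, x$amplitude, extra))
  if (!identical(x$pass_sign, 0)) {
    cat(sprintf("  rectified: passes %s S_out, diode drop %.2g V\n",
                if (isTRUE(x$pass_sign < 0)) "negative" else
                  if (isTRUE(x$pass_sign > 0)) "positive" else "basin-dependent",
                x$diode_drop))
  }
  invisible(x)
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Piecewise-constant stimulus segments of a protocol
#'
#' Expands a protocol into the ordered breakpoints over `[t0, t1)` on which
#' the raw stimulus `S_in` is constant. The integrator restarts at each
#' breakpoint so stimulus discontinuities are handled exactly.
#'
#' @param protocol a `stim_protocol`.
#' @param t0,t1 time span to cover.
#' @return A data frame with columns `t_start`, `t_end`, `S_in`.
#' @keywords internal
#' @export
protocol_segments <- function(protocol, t0, t1) {
  stopifnot(inherits(protocol, "stim_protocol"), t1 > t0)
  A <- protocol$amplitude
  seg <- function(starts, vals) {
    data.frame(t_start = starts, t_end = c(starts[-1], t1), S_in = vals)
  }
  switch(protocol$kind,
    none = seg(t0, 0),
    constant = ,
    gated = seg(t0, A),
    periodic = {
      per <- protocol$params$period
      duty <- protocol$params$duty
      if (duty >= 1) return(seg(t0, A))
      k0 <- floor(t0 / per)
      k1 <- ceiling(t1 / per)
      starts <- sort(c(outer(c(0, duty * per), per * (k0:k1), `+`)))
      vals <- rep(c(A, 0), length.out = length(starts))
      keep <- starts < t1 & c(starts[-1], Inf) > t0
      starts <- pmax(starts[keep], t0)
      seg(starts, vals[keep])
    },
    random = {
      rate <- protocol$params$switch_rate
      with_local_seed(protocol$seed, function() {
        on0 <- rbinom(1, 1, 0.5)
        starts <- t0
        tt <- t0
        repeat {
          tt <- tt + rexp(1, rate)
          if (tt >= t1) break
          starts <- c(starts, tt)
        }
        vals <- A * ((on0 + seq_along(starts) - 1) %% 2)
        seg(starts, vals)
      })
    },
    stop(sprintf("unknown protocol kind '%s'", protocol$kind))
  )
}

# Resolve the rectifier pass sign for a trial started in `basin`
# ("slow"/"fast"); non-gated protocols pass everything (sign 0).
resolve_pass_sign <- function(protocol, basin) {
  if (!identical(protocol$kind, "gated")) return(0)
  if (is.na(protocol$pass_sign)) {
    if (identical(basin, "slow")) -1 else +1
  } else {
    protocol$pass_sign
  }
}

# The interface with optional rectification: raw = S_in*x*y, then keep only
# the matching sign, attenuated by the diode drop.
interface_output <- function(S_in, x, y, pass_sign, diode_drop) {
  raw <- S_in * x * y
  if (pass_sign == 0) return(raw)
  s <- sign(raw)
  if (s == pass_sign) s * max(abs(raw) - diode_drop, 0) else 0
}

# Return a copy of the protocol with a new seed (no-op for deterministic
# protocols); used by the trial battery's seed-splitting rule.
reseed_protocol <- function(protocol, seed) {
  if (identical(protocol$kind, "random")) protocol$seed <- seed
  protocol
}
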