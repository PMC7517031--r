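# Closed-loop control environment: a reset/step interface through which an
# external algorithm interacts with the plant from observations only, never
# seeing the vector field or its parameters.

#' Create a closed-loop stimulation environment
#'
#' Wraps the plant in a reset/step interface for testing stimulation
#' algorithms: the controller receives observations (a configurable channel
#' subset, optionally noisy) and supplies one raw stimulus value per step,
#' which passes through the stimulator interface `S_out = S_in x y` before
#' reaching the z equation. The controller never has access to the state
#' equations or parameters — it must discover the latent dynamics from
#' observations.
#'
#' @param config a [make_birhythmic_config()] object.
#' @param observe observation model: `"full"` (x, y, z), `"z"` (the slow
#'   coordinate only), or `"custom"` (the channels named in `channels`).
#' @param channels character subset of `c("x", "y", "z")` when
#'   `observe = "custom"`.
#' @param noise_sd standard deviation of additive Gaussian observation
#'   noise (0 = noise-free).
#' @return An object of class `stim_env`. Use [env_reset()] before stepping.
#' @examples
#' env <- stim_env(make_birhythmic_config(gamma = 5), observe = "z")
#' obs <- env_reset(env, basin = "slow", seed = 1)
#' step <- env_step(env, S_in = 4, dt = 0.1)
#' @export
stim_env <- function(config, observe = c("full", "z", "custom"),
                     channels = NULL, noise_sd = 0) {
  observe <- match.arg(observe)
  validate_birhythmic_config(config, bounds = FALSE)
  stopifnot(noise_sd >= 0)
  channels <- switch(observe,
    full = c("x", "y", "z"),
    z = "z",
    custom = {
      if (is.null(channels) || !all(channels %in% c("x", "y", "z"))) {
        stop("custom observation needs channels from c('x', 'y', 'z')")
      }
      channels
    })
  e <- new.env(parent = emptyenv())
  e$config <- config
  e$channels <- channels
  e$noise_sd <- noise_sd
  e$state <- NULL
  e$time <- NA_real_
  structure(e, class = "stim_env")
}

#' @export
print.stim_env <- function(x, ...) {
  cat(sprintf("closed-loop stimulation environment (observes %s%s)\n",
              paste(x$channels, collapse = ", "),
              if (x$noise_sd > 0) sprintf(", noise sd %g", x$noise_sd) else ""))
  if (!is.null(x$state)) {
    cat(sprintf("  t = %.4g, basin at reset: %s\n", x$time, x$basin0))
  } else {
    cat("  not reset yet\n")
  }
  invisible(x)
}

env_observe <- function(env) {
  vals <- setNames(env$state, c("x", "y", "z"))[env$channels]
  if (env$noise_sd > 0) {
    env$noise_step <- env$noise_step + 1L
    vals <- vals + with_local_seed(
      split_seed(env$reset_seed, env$noise_step),
      function() stats::rnorm(length(vals), 0, env$noise_sd))
  }
  list(time = env$time, values = vals)
}

#' Reset the environment onto an attractor
#'
#' Draws an initial state uniformly from the requested basin box
#' ((-1.5, 1.5)^2 x (0, 1.5) for slow, (-1.5, 1.5)^2 x (-1.5, 0) for fast),
#' relaxes it onto the attractor, and returns the first observation.
#'
#' @param env a [stim_env()] object.
#' @param basin `"slow"` or `"fast"`.
#' @param seed integer seed for the initial draw (and observation noise).
#' @return The initial observation: a list with `time` and named `values`.
#' @export
env_reset <- function(env, basin = c("slow", "fast"), seed = 1) {
  stopifnot(inherits(env, "stim_env"))
  basin <- match.arg(basin)
  zlim <- if (basin == "slow") c(0, 1.5) else c(-1.5, 0)
  x0 <- with_local_seed(split_seed(seed, 0), function() {
    c(runif(2, -1.5, 1.5), runif(1, zlim[1], zlim[2]))
  })
  relax <- 50 * env$config$gamma
  rel <- integrate_system(env$config, x0, t_span = c(0, relax),
                          dt_out = relax / 8, tol = 1e-10)
  env$state <- as.numeric(rel[nrow(rel), c("x", "y", "z")])
  env$time <- 0
  env$basin0 <- basin
  env$sign0 <- if (basin == "slow") 1 else -1
  env$opp_time <- 0       # accumulated time with z sign flipped
  env$reset_seed <- seed
  env$noise_step <- 0L
  env_observe(env)
}

#' Advance the environment by one control step
#'
#' Applies the controller's raw stimulus `S_in`, held constant for `dt` time
#' units, integrates the plant, and reports the next observation. `done`
#' becomes `TRUE` once the z sign has stayed opposite to the reset basin
#' continuously for at least 1 time unit (a sustained transition, not a
#' graze of the separatrix).
#'
#' @param env a reset [stim_env()] object.
#' @param S_in raw stimulus voltage for this step.
#' @param dt step duration, > 0.
#' @return A list with `observation` (as in [env_reset()]) and `done`.
#' @export
env_step <- function(env, S_in, dt) {
  stopifnot(inherits(env, "stim_env"))
  if (is.null(env$state)) stop("env_step() called before env_reset()")
  stopifnot(is.finite(S_in), dt > 0)
  prot <- new_stim_protocol("constant", abs(S_in))
  prot$amplitude <- S_in  # allow signed stimulus from a controller
  tr <- integrate_system(env$config, env$state, protocol = prot,
                         t_span = c(0, dt), dt_out = dt, tol = 1e-8,
                         basin = env$basin0)
  env$state <- as.numeric(tr[nrow(tr), c("x", "y", "z")])
  env$time <- env$time + dt
  # accumulate flipped-sign time at step resolution
  if (env$sign0 * env$state[3] < 0) {
    env$opp_time <- env$opp_time + dt
  } else {
    env$opp_time <- 0
  }
  list(observation = env_observe(env), done = env$opp_time >= 1)
}
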