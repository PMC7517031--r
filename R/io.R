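# Run configuration (JSON) and the command-style entry points used by the
# CLI script. A run configuration round-trips losslessly through JSON and
# every random operation consumes a seed split from the single master seed.

run_config_schema <- list(
  model = c("alpha", "g_xy", "g_z", "gamma", "stim_gain", "s_bias"),
  hardware = c("tolerance", "seed", "components"),
  protocol = c("kind", "amplitude", "switch_rate", "period", "duty",
               "target", "diode_drop", "seed"),
  trials = c("n_per_cell", "record", "dt_out"),
  seed = NULL,
  output = c("dir")
)

#' Default run configuration
#'
#' The defaults reproduce the standard study conditions: the default model
#' parameters, no hardware degradation, a 4 V constant protocol, 10 trials
#' per cell, and master seed 1.
#'
#' @return A list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    model = list(alpha = pi / 5, g_xy = 3, g_z = 1.5, gamma = 50,
                 stim_gain = 1, s_bias = c(-0.5, -0.5, 0.5)),
    hardware = list(tolerance = 0, seed = 1),
    protocol = list(kind = "constant", amplitude = 4),
    trials = list(n_per_cell = 10, record = 80, dt_out = 0.05),
    seed = 1
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Fails loudly: unknown keys at any level are rejected with a field-level
#' message, and the model section must satisfy the dynamical admissibility
#' bounds.
#'
#' @param rc a run-configuration list.
#' @return `rc` (classed), invisibly.
#' @export
validate_run_config <- function(rc) {
  if (!is.list(rc)) stop("run config must be a list")
  unknown <- setdiff(names(rc), names(run_config_schema))
  if (length(unknown)) {
    stop(sprintf("unknown run-config key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  for (sec in names(rc)) {
    allowed <- run_config_schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(rc[[sec]]), allowed)
    if (length(bad)) {
      stop(sprintf("unknown key(s) in '%s': %s", sec,
                   paste(bad, collapse = ", ")))
    }
  }
  rc <- modifyList(unclass(default_run_config()), rc)
  do.call(make_birhythmic_config, rc$model)  # throws on violated bounds
  protocol_from_spec(rc$protocol)            # throws on bad protocol
  stopifnot(rc$trials$n_per_cell >= 1, rc$trials$record > 0,
            rc$trials$dt_out > 0)
  invisible(structure(rc, class = "run_config"))
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_run_config` returns a validated `run_config`;
#'   `write_run_config` returns `path` invisibly.
#' @name run_config_io
#' @export
read_run_config <- function(path) {
  rc <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(rc)
}

#' @rdname run_config_io
#' @param rc a `run_config` list.
#' @export
write_run_config <- function(rc, path) {
  jsonlite::write_json(unclass(rc), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Model configuration implied by a run config, with any hardware
# component-tolerance degradation applied.
config_from_run <- function(rc) {
  cfg <- do.call(make_birhythmic_config, rc$model)
  tol <- rc$hardware$tolerance
  if (!is.null(tol) && tol > 0) {
    cfg <- perturb_components(cfg, tol, seed = rc$hardware$seed)
  }
  cfg
}

# Instantiate a protocol from its serialized spec {kind, amplitude, ...}.
protocol_from_spec <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$kind))
  a <- function(x, d) if (is.null(x)) d else x
  switch(spec$kind,
    none = no_stim_protocol(),
    constant = constant_protocol(a(spec$amplitude, 4)),
    random = random_protocol(a(spec$amplitude, 4), a(spec$switch_rate, 5),
                             a(spec$seed, 1)),
    periodic = periodic_protocol(a(spec$amplitude, 4), a(spec$period, 1),
                                 a(spec$duty, 0.5)),
    gated = gated_protocol(a(spec$amplitude, 4), a(spec$target, "escape"),
                           a(spec$diode_drop, 0)),
    stop(sprintf("unknown protocol kind '%s'", spec$kind))
  )
}

# 32-bit FNV-1a hash of the serialized config, for the run log.
config_hash <- function(rc) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(rc), auto_unbox = TRUE,
                                      digits = NA))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; keep arithmetic in doubles (< 2^53)
    h <- h - h %% 256 + bitwXor(as.integer(h %% 256), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Simulate one trajectory and write it to CSV
#'
#' Integrates the configured model under the configured protocol and writes
#' the trajectory CSV (`t, x, y, z, stim_in, stim_out`). The initial state
#' is either given explicitly or drawn on the attractor of the requested
#' basin at a seeded random phase. Config hash and seed are logged to
#' stderr; nothing is written if the configuration is invalid.
#'
#' @param rc a validated run configuration (see [default_run_config()]).
#' @param out output CSV path.
#' @param basin `"slow"` or `"fast"` (ignored when `x0` is given).
#' @param x0 optional explicit initial state.
#' @return The trajectory, invisibly; the CSV is written to `out`.
#' @export
cmd_simulate <- function(rc, out, basin = "slow", x0 = NULL) {
  rc <- validate_run_config(rc)
  cfg <- config_from_run(rc)
  prot <- protocol_from_spec(rc$protocol)
  if (is.null(x0)) {
    pool <- attractor_phase_pool(cfg, basin)
    phase <- with_local_seed(split_seed(rc$seed, 1),
                             function() sample.int(nrow(pool), 1))
    x0 <- as.numeric(pool[phase, ])
  } else {
    basin <- if (x0[3] >= 0) "slow" else "fast"
  }
  message(sprintf("simulate: config %s seed %d basin %s protocol %s",
                  config_hash(rc), rc$seed, basin, prot$kind))
  tr <- integrate_system(cfg, x0, protocol = prot,
                         t_span = c(0, rc$trials$record),
                         dt_out = rc$trials$dt_out, basin = basin)
  write_trajectory_csv(tr, out)
  invisible(tr)
}

#' Run the full stimulation experiment grid
#'
#' Mirrors the hardware experiment: for each protocol in the grid (constant,
#' random telegraph, and diode-gated, all at the configured amplitude) and
#' each basin, runs the configured number of trials and tabulates transition
#' counts and maximum z-excursions. Writes one CSV row per trial plus a JSON
#' summary.
#'
#' @param rc a validated run configuration.
#' @param out_csv per-trial table path (CSV).
#' @param out_json summary report path (JSON).
#' @return The `trial_battery`, invisibly.
#' @export
cmd_experiment <- function(rc, out_csv, out_json) {
  rc <- validate_run_config(rc)
  cfg <- config_from_run(rc)
  amp <- if (is.null(rc$protocol$amplitude)) 4 else rc$protocol$amplitude
  grid <- list(
    constant = constant_protocol(amp),
    random = random_protocol(amp, switch_rate = 5, seed = rc$seed),
    gated = gated_protocol(amp, target = "escape")
  )
  message(sprintf("experiment: config %s seed %d (%d trials/cell)",
                  config_hash(rc), rc$seed, rc$trials$n_per_cell))
  bat <- run_trial_battery(cfg, grid, n_trials = rc$trials$n_per_cell,
                           seed = rc$seed, record = rc$trials$record,
                           dt_out = rc$trials$dt_out)
  for (i in seq_len(nrow(bat$trials))) {
    message(sprintf("trial %s/%s #%d seed %d transitioned=%s",
                    bat$trials$protocol[i], bat$trials$basin[i],
                    bat$trials$trial[i], bat$trials$seed[i],
                    bat$trials$transitioned[i]))
  }
  write.csv(bat$trials, out_csv, row.names = FALSE, quote = FALSE)
  transitions <- setNames(
    lapply(split(bat$summary, bat$summary$protocol), function(d) {
      setNames(as.list(d$n_transitions), d$basin)
    }), unique(bat$summary$protocol))
  jsonlite::write_json(
    list(seed = rc$seed, config_hash = config_hash(rc),
         n_per_cell = rc$trials$n_per_cell, record = rc$trials$record,
         transitions = transitions, summary = bat$summary),
    out_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(bat)
}

#' Report the fixed points as JSON
#'
#' Prints the fixed points of the configured model with their stability
#' labels, eigenvalues, and the z-subsystem equilibrium z*.
#'
#' @param rc a validated run configuration.
#' @param out output JSON path, or `NULL` to return the report only.
#' @return The report list, invisibly.
#' @export
cmd_fixed_points <- function(rc, out = NULL) {
  rc <- validate_run_config(rc)
  cfg <- config_from_run(rc)
  fps <- find_fixed_points(cfg)
  rep <- list(
    z_star = attr(fps, "z_star"),
    fixed_points = lapply(fps, function(fp) {
      list(state = fp$state, stability = fp$stability,
           eigenvalues_re = Re(fp$eigenvalues),
           eigenvalues_im = Im(fp$eigenvalues))
    })
  )
  if (!is.null(out)) {
    jsonlite::write_json(rep, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(rep)
}
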