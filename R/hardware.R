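# Analog-hardware emulation: the op-amp/transistor tanh unit and
# component-tolerance degradation of the ideal model.

#' Analog tanh-unit component set
#'
#' Components of the op-amp + differential-pair circuit realizing the
#' hyperbolic tangent, with input-output relation
#' `V0 = -tanh(R2 / (2 R VT) * Vin)`. The defaults (R2 = 520 ohm, all
#' plain resistors R = 10 kohm, VT = 26 mV) make the input coefficient
#' exactly 1.
#'
#' @param R2,R,R3,R4,R11 resistances, ohms (R is the value shared by all
#'   otherwise-unlabeled resistors; R3, R4, R11 complete the unit but do not
#'   enter the small-signal coefficient).
#' @param VT transistor thermal voltage at room temperature, volts.
#' @param VCC,VEE supply rails, volts.
#' @return An object of class `tanh_unit_components`.
#' @examples
#' tanh_unit_gain(tanh_unit_components())  # 1
#' @export
tanh_unit_components <- function(R2 = 520, R = 10000, R3 = 1000, R4 = 1000,
                                 R11 = 11000, VT = 0.026,
                                 VCC = 15, VEE = -15) {
  for (nm in c("R2", "R", "R3", "R4", "R11")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0) {
      stop(sprintf("%s must be a positive resistance", nm))
    }
  }
  stopifnot(VT > 0, VEE < 0, VCC > 0)
  structure(list(R2 = R2, R = R, R3 = R3, R4 = R4, R11 = R11,
                 VT = VT, VCC = VCC, VEE = VEE),
            class = "tanh_unit_components")
}

#' @export
print.tanh_unit_components <- function(x, ...) {
  cat(sprintf(
    "analog tanh unit: R2 = %g ohm, R = %g ohm, VT = %g V -> k = %.6g\n",
    x$R2, x$R, x$VT, tanh_unit_gain(x)))
  invisible(x)
}

#' Input coefficient of the analog tanh unit
#'
#' `k = R2 / (2 R VT)`: the dimensionless coefficient multiplying Vin inside
#' the tanh of the unit's input-output relation.
#'
#' @param components a [tanh_unit_components()] object.
#' @return The coefficient k.
#' @export
tanh_unit_gain <- function(components) {
  stopifnot(inherits(components, "tanh_unit_components"))
  components$R2 / (2 * components$R * components$VT)
}

#' Response of the analog tanh unit
#'
#' `V0 = -tanh(k Vin)` (the unit is inverting), clipped to the op-amp
#' headroom `[VEE + 1.5, VCC - 1.5]`.
#'
#' @param Vin input voltage(s).
#' @param components a [tanh_unit_components()] object.
#' @return Output voltage(s).
#' @examples
#' tanh_unit_response(1, tanh_unit_components())  # -tanh(1) = -0.7616
#' @export
tanh_unit_response <- function(Vin, components = tanh_unit_components()) {
  stopifnot(all(is.finite(Vin)))
  k <- tanh_unit_gain(components)
  pmin(pmax(-tanh(k * Vin), components$VEE + 1.5), components$VCC - 1.5)
}

#' Degrade a configuration with component tolerances
#'
#' Emulates analog imperfection by multiplying each effective gain of the
#' model — the planar tanh gain `g_xy`, the z tanh gain `g_z`, the
#' speed-factor offset (3/2 at defaults), and the stimulation coupling
#' `stim_gain` — by independent lognormal factors with relative spread
#' `tolerance` (sdlog = tolerance), mimicking resistor-tolerance scatter.
#' Seeded and reproducible.
#'
#' @param config a [make_birhythmic_config()] object.
#' @param tolerance relative component tolerance, in `[0, 0.1]`;
#'   0 returns the configuration unchanged.
#' @param seed integer seed.
#' @return A perturbed `birhythmic_config`.
#' @examples
#' perturb_components(make_birhythmic_config(), tolerance = 0.05, seed = 1)
#' @export
perturb_components <- function(config, tolerance, seed = 1) {
  validate_birhythmic_config(config, bounds = FALSE)
  stopifnot(tolerance >= 0, tolerance <= 0.1)
  if (tolerance == 0) return(config)
  f <- with_local_seed(seed, function() rlnorm(4, 0, tolerance))
  cfg <- config
  cfg$g_xy <- config$g_xy * f[1]
  cfg$g_z <- config$g_z * f[2]
  cfg$s_bias[1] <- 1 - (1 - config$s_bias[1]) * f[3]  # offset (3/2) scaled
  cfg$s_bias[2] <- cfg$s_bias[1]
  cfg$stim_gain <- config$stim_gain * f[4]
  validate_birhythmic_config(cfg, bounds = FALSE)
  cfg
}
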