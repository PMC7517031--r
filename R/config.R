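#' Construct the birhythmic model configuration
#'
#' Bundles the parameters of the explicit 3-D birhythmic system
#' \deqn{\dot x = (3/2 - z)\,[\tanh(g_{xy}(x\cos\alpha - y\sin\alpha)) - x]}
#' \deqn{\dot y = (3/2 - z)\,[\tanh(g_{xy}(x\sin\alpha + y\cos\alpha)) - y]}
#' \deqn{\dot z = \frac{1}{\gamma}\left\{\tfrac12[\tanh(g_z z) - z] +
#'   \kappa\, S_{out}\right\}}
#' with defaults producing two mirrored limit cycles separated by the
#' invariant plane z = 0.
#'
#' @param alpha rotation angle of the planar subsystem, radians. Must lie in
#'   the admissible interval (pi/21, pi/3.8) for the planar limit cycle to
#'   exist, and satisfy `g_xy * cos(alpha) > 1` (unstable focus at the
#'   origin).
#' @param g_xy inner tanh gain of the x-y rotation block.
#' @param g_z inner tanh gain of the z subsystem. The default 3/2 places the
#'   nontrivial z equilibria at the positive/negative root of
#'   z = tanh(1.5 z), i.e. at +/- 0.8586 V. A gain of 3 (the alternative
#'   reading of the rotation-matrix construction) is accepted.
#' @param gamma time constant of the z subsystem, > 0. Larger gamma makes z
#'   slower relative to the x-y flow and attractor transitions harder. The
#'   default 50 keeps z roughly 50x slower than the planar flow; the
#'   circuit-component value 1e6 is accepted but impractical at default
#'   horizons.
#' @param stim_gain coupling gain kappa of the stimulator output into the z
#'   equation (set by circuit resistors in a hardware realization; exposed
#'   here as a dimensionless knob).
#' @param s_bias linear update-gate bias vector (bs). The default
#'   `c(-0.5, -0.5, 0.5)` yields gate complements 1 - s = (3/2 - z, 3/2 - z,
#'   1/2) on the simulation box.
#'
#' @return An object of class `birhythmic_config` (a validated list).
#' @examples
#' cfg <- make_birhythmic_config()
#' cfg$alpha == pi / 5
#' @seealso [birhythmic_rhs()], [as_gru_parameters()], [find_fixed_points()]
#' @export
make_birhythmic_config <- function(alpha = pi / 5,
                                   g_xy = 3,
                                   g_z = 3 / 2,
                                   gamma = 50,
                                   stim_gain = 1,
                                   s_bias = c(-0.5, -0.5, 0.5)) {
  cfg <- structure(
    list(alpha = alpha, g_xy = g_xy, g_z = g_z, gamma = gamma,
         stim_gain = stim_gain, s_bias = s_bias),
    class = "birhythmic_config"
  )
  validate_birhythmic_config(cfg)
  cfg
}

#' Validate a birhythmic configuration
#'
#' Checks structural validity (finite scalar fields, `gamma > 0`,
#' `g_z > 0`, a strictly positive planar speed factor on the simulation box
#' |z| < 1.5) and, when `bounds = TRUE`, the dynamical admissibility bounds:
#' alpha in (pi/21, pi/3.8) and `g_xy * cos(alpha) > 1` (the conditions for
#' the planar limit cycle). Analysis functions validate structure only, so
#' out-of-bounds regimes — e.g. a sub-critical planar gain, under which the
#' periodic attractors disappear — can still be explored by modifying a
#' constructed configuration.
#'
#' @param cfg object to validate.
#' @param bounds also enforce the limit-cycle admissibility bounds.
#' @return `cfg`, invisibly, if valid; otherwise an error naming the violated
#'   bound.
#' @export
validate_birhythmic_config <- function(cfg, bounds = TRUE) {
  if (!inherits(cfg, "birhythmic_config")) {
    stop("not a 'birhythmic_config' object")
  }
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  for (f in c("alpha", "g_xy", "g_z", "gamma", "stim_gain")) {
    if (!num1(cfg[[f]])) stop(sprintf("field '%s' must be a finite scalar", f))
  }
  if (!is.numeric(cfg$s_bias) || length(cfg$s_bias) != 3L ||
      any(!is.finite(cfg$s_bias))) {
    stop("field 's_bias' must be a finite length-3 numeric vector")
  }
  if (bounds) {
    if (cfg$alpha <= pi / 21 || cfg$alpha >= pi / 3.8) {
      stop(sprintf(
        "alpha = %.4f outside the admissible interval (pi/21, pi/3.8) = (%.4f, %.4f)",
        cfg$alpha, pi / 21, pi / 3.8
      ))
    }
    if (cfg$g_xy * cos(cfg$alpha) <= 1) {
      stop(sprintf(
        "g_xy * cos(alpha) = %.4f <= 1: origin focus is not unstable, no planar limit cycle",
        cfg$g_xy * cos(cfg$alpha)
      ))
    }
    # speed factor (1 - s_bias[1]) - z must stay positive for z < 1.5 (open)
    if (1 - cfg$s_bias[1] < 1.5 - 1e-12) {
      stop(sprintf(
        "speed factor (%.3f - z) is not strictly positive for |z| < 1.5",
        1 - cfg$s_bias[1]
      ))
    }
  }
  if (cfg$gamma <= 0) stop("gamma must be > 0")
  if (cfg$g_z <= 0) stop("g_z must be > 0")
  # speed must at least stay positive on the attractor range |z| <= 1
  if (1 - cfg$s_bias[1] <= 1) {
    stop(sprintf("speed factor (%.3f - z) vanishes on the attractor range",
                 1 - cfg$s_bias[1]))
  }
  invisible(cfg)
}

#' @export
print.birhythmic_config <- function(x, ...) {
  cat("birhythmic ct-GRU configuration\n")
  cat(sprintf("  alpha     : %.6f rad (pi/%.3g)\n", x$alpha, pi / x$alpha))
  cat(sprintf("  g_xy, g_z : %.4g, %.4g\n", x$g_xy, x$g_z))
  cat(sprintf("  gamma     : %.4g   stim_gain: %.4g\n", x$gamma, x$stim_gain))
  cat(sprintf("  s_bias    : (%s)\n", paste(format(x$s_bias), collapse = ", ")))
  zs <- z_fixed_point(x$g_z)
  if (zs > 0) {
    cat(sprintf("  z*        : %.6f (slow cycle at +z*, fast at -z*)\n", zs))
  } else {
    cat("  z*        : 0 (z subsystem collapses; planar cycle only)\n")
  }
  invisible(x)
}

#' Construct general ct-GRU parameters
#'
#' The general autonomous continuous-time GRU flow is
#' \deqn{\dot h = (1 - s) \odot (T - h),\quad
#'       s = \sigma(U_s h + b_s),\quad r = \sigma(U_r h + b_r),\quad
#'       T = \tanh(U_h (r \odot h) + b_h),}
#' with an optional linear update gate `s = U_s h + b_s` (`gate_mode =
#' "linear"`), which is the form used by the birhythmic instantiation so that
#' the gate directly sets the flow speed.
#'
#' @param Us,Ur,Uh d x d gain matrices.
#' @param bs,br,bh length-d bias vectors.
#' @param gate_mode `"sigmoid"` (logistic gate) or `"linear"`.
#' @return An object of class `gru_parameters`.
#' @seealso [gru_rhs()], [as_gru_parameters()]
#' @export
gru_parameters <- function(Us, Ur, Uh, bs, br, bh,
                           gate_mode = c("sigmoid", "linear")) {
  gate_mode <- match.arg(gate_mode)
  d <- length(bs)
  for (nm in c("Us", "Ur", "Uh")) {
    m <- get(nm)
    if (!is.matrix(m) || any(dim(m) != c(d, d))) {
      stop(sprintf("%s must be a %dx%d matrix", nm, d, d))
    }
  }
  for (nm in c("bs", "br", "bh")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != d) {
      stop(sprintf("%s must be a length-%d numeric vector", nm, d))
    }
  }
  structure(list(d = d, Us = Us, Ur = Ur, Uh = Uh,
                 bs = bs, br = br, bh = bh, gate_mode = gate_mode),
            class = "gru_parameters")
}

#' Render a birhythmic configuration as general GRU parameters
#'
#' Produces the d = 3 parameter set whose [gru_rhs()] equals
#' [birhythmic_rhs()] at every state (with zero stimulus): `Ur = br = bh = 0`
#' and a linear update gate with `Us = rbind(c(0,0,1), c(0,0,1), c(0,0,0))`.
#' With a zero reset gate the GRU drive is `T = tanh(Uh h / 2)` (the gate
#' rests at sigma(0) = 1/2), so the inner gains appear doubled in the
#' matrix: `Uh = 2 * blockdiag(g_xy R(alpha), g_z)`. The z gate bias folds
#' the time constant in as `bs_z = 1 - (1 - s_bias[3]) / gamma`, which
#' reduces to the canonical `bs = (-0.5, -0.5, 0.5)` when `gamma = 1`.
#'
#' @param cfg a [make_birhythmic_config()] object.
#' @return A `gru_parameters` object with `gate_mode = "linear"`.
#' @export
as_gru_parameters <- function(cfg) {
  validate_birhythmic_config(cfg)
  R <- matrix(c(cos(cfg$alpha), sin(cfg$alpha), 0,
                -sin(cfg$alpha), cos(cfg$alpha), 0,
                0, 0, 0), nrow = 3)
  Uh <- 2 * cfg$g_xy * R
  Uh[3, 3] <- 2 * cfg$g_z
  Us <- rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 0))
  bs <- c(cfg$s_bias[1], cfg$s_bias[2],
          1 - (1 - cfg$s_bias[3]) / cfg$gamma)
  zero <- matrix(0, 3, 3)
  gru_parameters(Us = Us, Ur = zero, Uh = Uh,
                 bs = bs, br = rep(0, 3), bh = rep(0, 3),
                 gate_mode = "linear")
}
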