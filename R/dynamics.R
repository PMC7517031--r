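#' General ct-GRU vector field
#'
#' Evaluates `dh/dt = (1 - s) * (T - h)` with update gate
#' `s = sigma(Us h + bs)` (or linear `s = Us h + bs`), reset gate
#' `r = sigma(Ur h + br)`, and drive `T = tanh(Uh (r * h) + bh)`.
#'
#' @param h numeric state vector of length `params$d`.
#' @param params a [gru_parameters()] object.
#' @return The derivative vector, same length as `h`.
#' @examples
#' p <- gru_parameters(Us = diag(0, 2), Ur = diag(0, 2), Uh = diag(0, 2),
#'                     bs = c(0, 0), br = c(0, 0), bh = c(0, 0))
#' gru_rhs(c(1, 0), p)  # (-0.5, 0): sigma(0) = 0.5, tanh(0) = 0
#' @export
gru_rhs <- function(h, params) {
  if (!inherits(params, "gru_parameters")) {
    stop("params must be a 'gru_parameters' object")
  }
  if (length(h) != params$d) {
    stop(sprintf("state has length %d, parameters are for d = %d",
                 length(h), params$d))
  }
  if (any(!is.finite(h))) stop("non-finite state")
  sigma <- function(v) 1 / (1 + exp(-v))
  s <- drop(params$Us %*% h) + params$bs
  if (params$gate_mode == "sigmoid") s <- sigma(s)
  r <- sigma(drop(params$Ur %*% h) + params$br)
  Tdrive <- tanh(drop(params$Uh %*% (r * h)) + params$bh)
  (1 - s) * (Tdrive - h)
}

#' Birhythmic vector field
#'
#' The explicit x, y, z system: the planar rotation block runs at speed
#' `(3/2 - z)` and the slow z subsystem (time constant `gamma`) receives the
#' stimulator output additively,
#' `dz/dt = (1/gamma) * (0.5 * (tanh(g_z z) - z) + stim_gain * stim_out)`.
#'
#' @param state numeric length-3 state `(x, y, z)`.
#' @param config a [make_birhythmic_config()] object.
#' @param stim_out stimulator-circuit output voltage reaching the z
#'   integrator (0 when unstimulated). This is the post-interface value
#'   `S_in * x * y`, not the raw stimulus.
#' @return Length-3 derivative `(dx/dt, dy/dt, dz/dt)`.
#' @examples
#' cfg <- make_birhythmic_config()
#' birhythmic_rhs(c(0, 0, 0), cfg)  # origin is a fixed point
#' @export
birhythmic_rhs <- function(state, config, stim_out = 0) {
  stopifnot(length(state) == 3L, is.finite(stim_out))
  if (any(!is.finite(state))) stop("non-finite state")
  x <- state[1]; y <- state[2]; z <- state[3]
  speed <- (1 - config$s_bias[1]) - z
  ca <- cos(config$alpha); sa <- sin(config$alpha)
  dx <- speed * (tanh(config$g_xy * (x * ca - y * sa)) - x)
  dy <- speed * (tanh(config$g_xy * (x * sa + y * ca)) - y)
  dz <- (1 / config$gamma) *
    ((1 - config$s_bias[3]) * (tanh(config$g_z * z) - z) +
       config$stim_gain * stim_out)
  c(dx, dy, dz)
}

#' Nontrivial equilibrium of the z subsystem
#'
#' Returns the unique nonnegative root of `z = tanh(g_z * z)`. For
#' `g_z <= 1` the slope of tanh at the origin never exceeds 1 and the only
#' root is 0; for `g_z > 1` the positive root is found by bracketed
#' root-finding to residual `< 1e-12`. The two limit cycles sit at
#' z = +z* (slow) and z = -z* (fast); for the default gain 3/2,
#' z* = 0.8586.
#'
#' @param g_z inner tanh gain of the z subsystem, > 0.
#' @return The nonnegative root (0 if none).
#' @examples
#' z_fixed_point(1.5)  # 0.8586
#' z_fixed_point(0.5)  # 0
#' @export
z_fixed_point <- function(g_z) {
  stopifnot(is.numeric(g_z), length(g_z) == 1L, g_z > 0)
  if (g_z <= 1) return(0)
  f <- function(z) z - tanh(g_z * z)
  # root lies in (0, 1]: tanh < 1 everywhere and f(1) > 0 for finite g_z;
  # start the bracket above the origin root's basin
  lo <- 1e-8
  while (f(lo) >= 0) lo <- lo * 10  # f < 0 just above 0 when g_z > 1
  r <- uniroot(f, c(lo, 1 + 1e-9), tol = 1e-15)
  if (abs(f(r$root)) > 1e-12) stop("z fixed-point root-finding did not converge")
  r$root
}

#' Numerical Jacobian of the birhythmic field
#'
#' Central finite differences (step 1e-6) of [birhythmic_rhs()] with zero
#' stimulus. At the origin the x-y block equals
#' `(3/2) * (g_xy * R(alpha) - I)` and `d(zdot)/dz = (g_z - 1) / (2 gamma)`.
#'
#' @param state length-3 state at which to linearize.
#' @param config a [make_birhythmic_config()] object.
#' @param h finite-difference step.
#' @return A 3 x 3 matrix.
#' @export
jacobian_at <- function(state, config, h = 1e-6) {
  stopifnot(length(state) == 3L)
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    e <- numeric(3); e[j] <- h
    J[, j] <- (birhythmic_rhs(state + e, config) -
                 birhythmic_rhs(state - e, config)) / (2 * h)
  }
  J
}

#' Locate and classify the fixed points
#'
#' The z subsystem decouples, and for an unstable planar focus
#' (`g_xy * cos(alpha) > 1`) the only planar equilibrium is the origin, so
#' the fixed points are `(0,0,0)` and, when `g_z > 1`, `(0,0,+/-z*)`. Each is
#' labeled from the eigenvalues of its Jacobian: the origin is fully
#' unstable; the two mirrored points are saddle-foci (attracting in z,
#' unstable focus in the x-y plane) — they anchor the two limit cycles.
#'
#' @param config a [make_birhythmic_config()] object.
#' @return An object of class `fixed_points`: a list of entries with fields
#'   `state`, `stability` (`"source"`, `"saddle"`, or `"sink"`), and
#'   `eigenvalues`.
#' @examples
#' fps <- find_fixed_points(make_birhythmic_config())
#' length(fps)  # 3
#' @export
find_fixed_points <- function(config) {
  validate_birhythmic_config(config)
  zs <- z_fixed_point(config$g_z)
  zvals <- if (zs > 0) c(0, zs, -zs) else 0
  fps <- lapply(zvals, function(zv) {
    st <- c(0, 0, zv)
    ev <- eigen(jacobian_at(st, config), only.values = TRUE)$values
    re <- Re(ev)
    lab <- if (all(re > 0)) "source" else if (all(re < 0)) "sink" else "saddle"
    list(state = st, stability = lab, eigenvalues = ev)
  })
  structure(fps, class = "fixed_points", z_star = zs)
}

#' @export
print.fixed_points <- function(x, ...) {
  cat(sprintf("%d fixed point(s); z* = %.6f\n", length(x), attr(x, "z_star")))
  for (fp in x) {
    cat(sprintf("  (% .4f, % .4f, % .4f)  %-6s  Re(eig) = %s\n",
                fp$state[1], fp$state[2], fp$state[3], fp$stability,
                paste(sprintf("% .4f", Re(fp$eigenvalues)), collapse = " ")))
  }
  invisible(x)
}
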