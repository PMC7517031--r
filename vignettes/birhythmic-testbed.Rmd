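---
title: "A birhythmic ct-GRU oscillator as a closed-loop neurostimulation testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A birhythmic ct-GRU oscillator as a closed-loop neurostimulation testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birhythm)
```

## Motivation

A recurring hypothesis in neurostimulation is that some pathological brain
states are attractors of a multistable dynamical system, and that therapy
amounts to perturbing the system out of the pathological basin of
attraction. Open-loop strategies (constant, random, or periodic pulses) are
easy to deliver but may be structurally unable to induce such transitions
when the stimulation pathway is state-dependent. A useful testbed for
closed-loop stimulation algorithms is therefore a plant that (i) has two
attractors distinguishable from observations, (ii) accepts stimulation only
through a nonlinear, state-dependent interface that defeats open-loop
strategies, and (iii) is simple enough that the existence of a successful
strategy can be proven constructively.

This package implements such a plant in software: a three-dimensional
continuous-time gated recurrent unit (ct-GRU) with two stable limit cycles
of different periods, a bilinear stimulation interface, baseline open-loop
protocols, one provably successful gated protocol, and a reset/step
environment for learning algorithms.

## The model

The general autonomous ct-GRU flow is

$$\dot h = (1 - s)\odot(T - h),\qquad
  s = \sigma(U_s h + b_s),\quad
  r = \sigma(U_r h + b_r),\quad
  T = \tanh(U_h (r \odot h) + b_h),$$

with state $h \in \mathbb{R}^d$. Because $1-s > 0$, the update gate never
moves the zeros of the right-hand side: it only rescales the speed of the
flow. This is the key to birhythmicity here. The specific instantiation
(d = 3, $U_r = b_r = b_h = 0$, linear update gate) reads, written out in
coordinates:

$$\dot x = \left(\tfrac32 - z\right)\left[\tanh(g_{xy}(x\cos\alpha - y\sin\alpha)) - x\right]$$
$$\dot y = \left(\tfrac32 - z\right)\left[\tanh(g_{xy}(x\sin\alpha + y\cos\alpha)) - y\right]$$
$$\dot z = \frac{1}{\gamma}\left\{\tfrac12\left[\tanh(g_z z) - z\right] + \kappa\, S_{\mathrm{out}}\right\}$$

The planar block is a rotation-plus-saturation field: for
$g_{xy}\cos\alpha > 1$ the origin is an unstable focus and the plane carries
a single attracting limit cycle. The $z$ equation is decoupled from $x$ and
$y$; for $g_z > 1$ it has equilibria at $0$ and $\pm z^*$, where $z^*$ is
the positive root of $z = \tanh(g_z z)$. The full system therefore carries
two limit cycles — one at $z = +z^*$, one at $z = -z^*$ — mirrored across
the invariant plane $z = 0$, which is the basin boundary. Since the planar
speed factor is $(3/2 - z)$, the upper cycle runs slower than the lower one
with period ratio

$$\frac{T_{\mathrm{slow}}}{T_{\mathrm{fast}}} = \frac{3/2 + z^*}{3/2 - z^*} \approx 3.68
\qquad (g_z = 3/2,\; z^* = 0.8586).$$

```{r}
cfg <- make_birhythmic_config()
cfg
find_fixed_points(cfg)
```

The three fixed points all lie on the z-axis: the origin is fully unstable,
and $(0,0,\pm z^*)$ are saddle-foci — attracting in $z$, unstable foci in
the plane — which anchor the two cycles.

### Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `alpha` | $\pi/5$ | rad | planar rotation angle; admissible in $(\pi/21, \pi/3.8)$ |
| `g_xy` | 3 | — | planar tanh gain; needs $g_{xy}\cos\alpha > 1$ |
| `g_z` | 3/2 | — | z-subsystem tanh gain; $g_z > 1$ gives the mirrored pair |
| `gamma` | 50 | — | z time constant; larger = slower z = harder transitions |
| `stim_gain` | 1 | — | coupling $\kappa$ of stimulator output into $\dot z$ |
| `s_bias` | $(-0.5, -0.5, 0.5)$ | — | linear update-gate bias |

Two of these deserve comment.

**The z gain.** With $g_z = 3/2$ the nontrivial z equilibrium is
$z^* = 0.858560$, matching the 0.858 V level measured on the analog
realization of this system at the printed 3-decimal precision (the exact
root rounds to 0.859; the hardware measurement carries an across-trial
standard deviation of $5.8\times10^{-3}$ V, far above that difference). A
gain of 3 — the value that appears when the gain is read off the
rotation-matrix construction before the resting reset gate is folded in —
is accepted and puts the cycles at $\pm 0.995$.

**The time constant.** The hardware realization sets $\gamma$ through an
integrator capacitor and uses a component-unit value of $10^6$; in
dimensionless simulation time we expose $\gamma$ directly as the difficulty
knob. The default $\gamma = 50$ makes the z subsystem roughly 50 times
slower than the planar flow (z relaxation time constant
$\approx 3.3\gamma$ versus a planar period of 16.6 time units on the slow
cycle), which reproduces the qualitative regime of the hardware
experiments: open-loop stimulation produces bounded z excursions of order
0.1 V while the gated protocol needs tens of time units — several
oscillation periods — to traverse to the separatrix. $\gamma = 10^6$ is
accepted but impractical at default horizons.

### The GRU rendering

`as_gru_parameters()` returns the general-GRU parameter set whose
`gru_rhs()` equals `birhythmic_rhs()` to machine precision at every state.
Two algebraic details are easy to miss. First, with $U_r = b_r = 0$ the
reset gate rests at $\sigma(0) = 1/2$, so the drive is
$T = \tanh(U_h h / 2)$ and the matrix must carry doubled gains,
$U_h = 2\,\mathrm{blockdiag}(g_{xy}R(\alpha),\, g_z)$. Second, the
canonical gate bias $b_s = (-0.5, -0.5, 0.5)$ corresponds to $\gamma = 1$;
for general $\gamma$ the z-gate bias is folded as
$b_{s,z} = 1 - (1 - 0.5)/\gamma$, keeping the identity exact.

```{r}
p <- as_gru_parameters(cfg)
h <- c(0.1, 0, 0.9)
max(abs(gru_rhs(h, p) - birhythmic_rhs(h, cfg)))
```

## The stimulation interface

All stimulation passes through the bilinear stimulator relation

$$S_{\mathrm{out}}(t) = S_{\mathrm{in}}(t)\, x(t)\, y(t),$$

summed into $\dot z$. On either cycle, $x$ and $y$ are near-quadrature
oscillations, so $x y$ is zero-mean over a period: constant, random, and
periodic $S_{\mathrm{in}}$ inject zero net drift into $z$, only bounded
ripple. A stimulus applied at a random time is equally likely to push $z$
up or down. Transitioning deliberately requires applying stimulus only when
$x y$ has the helpful sign — negative to descend from the slow cycle,
positive to ascend from the fast one — which is exactly what a rectifying
diode placed before the stimulation node achieves. And because the
oscillation frequency itself depends on $z$, the helpful time windows shift
continuously as stimulation progresses, so no fixed periodic schedule can
stay aligned with them.

The built-in protocols formalize the hardware experiments:

* `constant_protocol(4)` — 4 V held on;
* `random_protocol(4, switch_rate, seed)` — the "manually random" on/off
  stimulus, formalized as a symmetric exponential telegraph process
  (holding times exponential with the given rate, initial phase
  Bernoulli(1/2)); the hardware experiments do not define the law, and the
  telegraph process is the natural memoryless choice;
* `periodic_protocol(4, period, duty)` — square wave;
* `gated_protocol(4, target, diode_drop)` — constant stimulus with the
  interface rectified in the target direction. `diode_drop = 0` is an
  ideal rectifier (default); 0.6 V approximates a small-signal silicon
  diode. The hardware names the part but not its model, and the outcome is
  insensitive to the choice.

A transition is scored only when the sign of $z$ stays opposite to the
initial basin continuously for at least 1 time unit, so grazes of the
separatrix do not count.

```{r, eval = FALSE}
bat <- run_trial_battery(
  cfg,
  list(constant = constant_protocol(4),
       random   = random_protocol(4, switch_rate = 5),
       gated    = gated_protocol(4, "escape")),
  n_trials = 10, seed = 1)
bat$summary
```

With the default conditions this reproduces the outcome matrix of the
hardware study: 0/10 transitions per basin for constant and random
stimulation (maximum z excursions of order 0.03–0.12), 10/10 for the gated
protocol in both directions.

## The closed-loop environment

`stim_env()` wraps the plant in a reset/step interface for external
algorithms. The controller sees only observations — by default a channel
subset with optional additive Gaussian noise — never the vector field, its
parameters, or the interface law, mirroring the situation of a real
stimulator that must discover the latent dynamics from data. `env_reset()`
draws an initial state uniformly from the requested basin box
($(-1.5,1.5)^2 \times (0,1.5)$ for slow, $(-1.5,1.5)^2 \times (-1.5,0)$ for
fast), relaxes onto the attractor, and returns the first observation;
`env_step()` applies one zero-order-held stimulus value and reports
`done` when a sustained transition has occurred. A stdin/stdout line
protocol (`inst/cli/birhythm.R env-serve`) exposes the same interface to
controllers in any language.

## Horizons and the experimental protocols

The hardware study characterized each cycle from ten trials per basin
(5 s relaxation, 5 s recording) and ran stimulation trials recorded for
5 s each. Those wall-clock figures are tied to the circuit's component
timescales; in dimensionless time the equivalent choices must be expressed
relative to the model's own periods, and the defaults here are:

* **limit-cycle characterization** (`limit_cycle_summary`): relaxation
  $50\gamma$ time units (≈ 15 z time constants, settling z far below
  measurement precision), recording 85 units (≈ 5 slow periods);
* **stimulation trials** (`run_trial_battery`): initial states placed on
  the attractor at a seeded random phase, recording $1.6\gamma$ units,
  which covers the gated traversal (crossing at ≈ $1.1\gamma$) plus the
  sustained-flip confirmation with margin;
* **attractor census** (`count_attractors`): relaxation $20\gamma$,
  recording 100 units, clustering by z sign and period within 5%.

A literal "5 time units" would cover less than a third of one slow period
and is unusable for period estimation at any $\gamma$; the scaled horizons
preserve the intent of the protocol (several periods of settled data)
rather than its letter.

## Numerical choices

* Integration is deSolve's `lsoda` with `rtol = atol` (default $10^{-8}$,
  tests of quantitative levels use $10^{-10}$). Protocols are expanded
  into piecewise-constant segments and the integrator is restarted at each
  breakpoint, so stimulus edges are exact, while $S_{\mathrm{out}} =
  S_{\mathrm{in}} x y$ (and any rectification) is evaluated continuously
  inside the right-hand side. Breakpoints within $10^{-6}\,\mathrm{d}t$ of
  an output grid point are snapped onto it to avoid degenerate steps.
* A fixed-step forward-Euler integrator with identical stimulus semantics
  serves as an independent cross-check in the test suite (agreement within
  $10^{-3}$ at $\mathrm{d}t = 10^{-5}$ over unit horizons, with first-order
  convergence).
* $z^*$ is found by bracketed root-finding (`uniroot`) to residual
  $< 10^{-12}$; for $g_z \le 1$ the slope condition shows 0 is the only
  root and no search is run.
* Periods are estimated as the mean spacing of same-direction crossings of
  the Poincaré section $\{y = 0, x > 0\}$, with crossing times linearly
  interpolated; intervals are half-open, and a sample exactly on the
  section counts with the direction of the following step.
* Jacobians are central finite differences with step $10^{-6}$, agreeing
  with the closed-form linearizations at the fixed points to $10^{-6}$.
* Basin classification exploits the exact decoupling of $\dot z$ from
  $x, y$: only the scalar z equation is relaxed (to $|\dot z| < 10^{-8}$),
  with states within $10^{-6}$ of the invariant plane labeled `boundary`.
* Every random draw consumes a seed split deterministically from the
  master seed (a documented multiply-add rule kept below $2^{31}$), and the
  caller's RNG state is always restored, so all tables are reproducible
  bit-for-bit.

## Hardware emulation

The analog realization builds its tanh nonlinearities from an op-amp and a
transistor differential pair with input-output relation
$V_0 = -\tanh\!\big(\tfrac{R_2}{2 R V_T} V_{\mathrm{in}}\big)$; with
$R_2 = 520\,\Omega$, $R = 10\,\mathrm{k}\Omega$ and thermal voltage
$V_T \approx 26$ mV the coefficient is exactly 1. `tanh_unit_gain()` and
`tanh_unit_response()` model this unit (inverting, clipped to a
conventional 1.5 V op-amp headroom below the rails — an assumption, not a
measured figure).

`perturb_components()` degrades the ideal model toward circuit-like
behavior by multiplying each effective gain ($g_{xy}$, $g_z$, the 3/2
speed offset, $\kappa$) by independent lognormal factors with relative
spread equal to the component tolerance. This is a generic parameter-level
jitter, not a fitted error curve of a specific unit: at 5% tolerance the
slow-cycle level scatters around 0.8586 while the two-attractor structure
survives, which is the qualitative behavior the emulation is meant to
supply.

## What the simulations do and do not show

The simulated plant is the idealized, perfectly symmetric model. Passing
its tests demonstrates the dynamical claims — birhythmicity, the basin
structure, the immunity of the interface to open-loop stimulation, the
existence of the gated solution — under exact arithmetic and clean
observations. It does not reproduce several features of the physical
realization: the measured asymmetry between the cycles (fast-cycle level
−0.907 V against the ideal $-z^*$ = −0.8586, attributed to hardware
imperfection), recording quantization, amplifier saturation during large
stimuli, or the absolute excursion voltages of the stimulation trials,
which depend on the unpublished effective gain from the stimulator into
the z integrator ($\kappa$ is therefore exposed as a parameter rather than
guessed; the outcome matrix is robust over at least $\kappa \in
[0.2, 5]$). The admissible interval enforced for $\alpha$,
$(\pi/21, \pi/3.8)$, is a sufficient working range, not a claim about the
exact bifurcation boundary.

## Problem sizes

The shipped test suite runs the full default-condition battery (10 trials
per cell, 80-unit recordings, $\gamma = 50$) plus structure checks at
$\gamma$ between 5 and 20, a 1000-start sign-conservation sweep, and
dense-orbit comparisons at $10^{-3}$ resolution; the whole suite completes
in a few minutes on one core.
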