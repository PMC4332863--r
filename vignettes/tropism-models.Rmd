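---
title: "Modeling photo-gravi-proprioceptive shoot tropism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling photo-gravi-proprioceptive shoot tropism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tropism)
```

## The model family

A growing shoot (a coleoptile, a hypocotyl, an inflorescence stem) reorients
by differential growth. Its planar shape is reduced to the median line,
parameterized by arc length $s$ from the clamped base ($s = 0$) to the apex
($s = L$), with local orientation $A(s,t)$ measured from the upward vertical
and local curvature $C(s,t) = \partial A / \partial s$. Three sensing
channels drive the change of curvature:

* **graviception** pulls the local orientation toward the gravitropic
  set-point angle (the vertical for ortho-gravitropic organs), with
  sensitivity $\beta$;
* **photoception** pulls the orientation toward the light direction $A_P$,
  with sensitivity $\nu$ — perceived either locally at every position, or
  only at the apex with the signal relayed basipetally;
* **proprioception** senses the organ's own curvature and drives
  straightening, with sensitivity $\gamma$.

The four linear variants combine these channels ($A^a = A(L,t)$ is the
apical angle; the rate is zero below the growth zone, $s < L - L_{gz}$):

| variant | curvature rate $\partial C/\partial t$ | sensing |
|---|---|---|
| `AC`   | $-\beta A - \gamma C$ | local gravi + proprio |
| `AaC`  | $-\nu (A^a - A_P) - \gamma C$ | apical photo + proprio |
| `ARC`  | $-\beta A - \nu (A - A_P) - \gamma C$ | local photo-gravi-proprio |
| `ARaC` | $-\beta A - \nu (A^a - A_P) - \gamma C$ | apical photo, local gravi |

The angular sensing terms are small-angle linearizations of the Lambert
cosine dependence of perceived irradiance on the incidence angle; they are
first-order accurate below initial tilts of 90°, and the `sine_law` option
keeps the full sine dependence to reproduce the documented breakdown beyond
90°.

Three dimensionless numbers control everything
(`derived_numbers()`): the graviproprioceptive number $B = \beta L_{gz} /
\gamma$, the photoproprioceptive number $D = \nu L_{gz} / \gamma$, and the
photograviceptive number $M = \beta / \nu = B / D$. Under combined cues the
apex aligns with the photogravitropic set-point angle

$$A_R = \frac{A_P}{1 + M},$$

which interpolates between the light direction ($M \to 0$) and the vertical
($M \to \infty$). The convergence time scale is $T_c = 1/(\gamma + \nu
L_{gz})$ and the curved zone at steady state has extent $L_c = L/(B + D)$.

```{r}
p <- tropic_params(beta = 1.5, gamma = 1, nu = 0.7, A0 = 0.6, A_P = 1.1)
derived_numbers(p)
```

## Numerical design

**State and coupling.** The curvature field is the dynamical state; the
angle field is *recomputed* from it at every integrator stage by cumulative
trapezoid integration from the clamped base ($A(0,t) = A_0$). Evolving a
single field prevents drift between $A$ and $C$, and makes the discrete
system exactly linear time-invariant in the curvature vector.

**Two independent integrators.** The default stepper is classical RK4 with
a fixed step, $dt = 0.05/(\gamma + (\beta+\nu)L_{gz})$ unless overridden;
an exact matrix-exponential stepper (`method = "expm"`) exploits the LTI
structure and serves as an independent oracle — the test suite holds the
two to agree to $10^{-8}$ and verifies the fourth-order convergence of RK4
against it. A curvature-magnitude audit turns runaway steps into an
explicit solver error advising a smaller `dt`.

**Degenerate regimes are results, not exceptions.** With $\gamma = 0$ the
purely local models oscillate indefinitely; `detect_steady_state()` returns
a first-class `not_converged` status, and `steady_state()` refuses with an
explanatory error. The steady-state detector uses the rate criterion
$\max_s |\partial C/\partial t| < \mathrm{tol} \cdot (\gamma + \nu L_{gz})
\cdot \max(|A_0 - A_R|, \varepsilon)$; the rate scale $\gamma + \nu L_{gz}$
reduces to $\gamma$ for the local models and remains positive for apical
photoception without proprioception, which genuinely converges (the
movement stops when the apex reaches the light direction) and must not be
misclassified by a $\gamma$-proportional threshold.

**Growth zone.** The responsive-zone mask is applied as $s \ge L - L_{gz}$
(closed at the basal boundary), so the default $L_{gz} = L$ leaves the
whole organ responsive, including the base node — consistent with the
closed-form steady states, which carry nonzero basal curvature. The base
*angle* is clamped ($A(0,t) = A_0$) but the basal curvature is free to
evolve: the initial condition $C(s,0) = 0$ holds at $t=0$ only. The printed
closed forms (transients, steady states, limit shapes) are derived without
the mask, so `steady_state()` and `aac_transient()` require $L_{gz} = L$
and reject partial growth zones rather than silently returning a formula
that no longer solves the equations.

**Signal propagation.** The apical models treat the basipetal signal as
instantaneous. `simulate_with_propagation()` relaxes this with a linear
apex-to-base delay profile — position $s$ perceives $A(L,\, t - T_B (L -
s)/L)$ and nothing before the signal first arrives. The delay kernel is a
modeling choice (the alternative, a uniform lag, is less physical for a
transported signal); with $T_B = 0$ the code path is identical to the
instantaneous stepper, and deviations grow monotonically with $T_B / T_c$.

## Inferring the control numbers from equilibrium data

At photogravitropic equilibrium the measured tip angle identifies $M$
record by record, $M = A_P / \mathrm{tip} - 1$ (`M_from_equilibrium()`),
with explicit markers instead of exceptions: a vertical tip is an
infinite-$M$ marker, a tip beyond the light direction is flagged invalid.
Records with initial tilts beyond 90° are excluded with a reason code — the
linearized model is documented not to hold there — and the bookkeeping
guarantees `n_used + n_excluded = n_records`.

The intensity dependence $M(I)$ is fitted in two competing forms: the
Stevens power law $M = a I^{b}$ (a straight line in log–log space) and the
Weber–Fechner logarithmic law $M = c + d \log I$ (straight in semi-log
space). The exponent is stored *signed*; brighter light strengthens
photosensing, so empirical exponents are negative with magnitude around
0.4. Lines are fitted by **orthogonal regression** (total least squares
with unit error-variance ratio in the transformed coordinates), solved from
the eigen-decomposition of the 2×2 second-moment matrix; ordinary least
squares is available for comparison. Since $R^2$ has no canonical
definition for an orthogonal fit, the package reports
$1 - (\text{perpendicular residual sum})/(\text{total variance about the
centroid})$, and this formula is echoed into every JSON fit report. The two
laws are compared by per-record RMS perpendicular residual in each law's
own fit space; this is a model-selection heuristic, exact for noiseless
data (the matching law has zero residual) and documented as such.

`master_curve_collapse()` tests the model's strongest prediction — that
$M(I)$ is independent of the initial tilt — by comparing per-tilt-group
fits with a pooled fit; the data are "collapsed" when the pooled per-record
residual is at most 1.2× the mean grouped residual. The 1.2 threshold is a
package calibration choice (configurable and recorded in the report): it
comfortably passes shared-law data at the default noise level and fails
groups generated with exponents −0.2 vs −0.6.

Morphometric estimators close the loop: `estimate_B_from_dark_shape()`
fits $A(s) = A_0 e^{-Bs/L}$ to a dark gravitropic steady shape by nonlinear
least squares, with the amplitude profiled out analytically so the estimate
does not hinge on the single (noisy) basal node; `estimate_D()` then uses
$D = B/M$. At zero noise all estimators return the generating values to
solver tolerance ($\le 10^{-6}$).

## What the synthetic data emulate — and what they do not

`generate_pgea_dataset()` emulates the classical tilted-coleoptile
equilibrium design: initial tilts of 0°, 10°, 30°, 90° and 120° (the
120° rows exist to exercise the exclusion logic), light held perpendicular
to the initial orientation ($A_P = A_0 + \pi/2$), a fluence-rate grid
spanning five decades, and 15 replicates per condition. Protocol `PROT1`
records equilibrium tip angles across the full grid; `PROT2` emulates the
compensation experiment, inverting the true law for the intensity at which
the organ holds its tilt. Measurement noise is Gaussian on the *tip angle*
(where goniometer error lives), not on $M$; the default σ = 2° is a
calibration choice, flagged as such, since the original experiments do not
report their error magnitude. The generator records its seed and the true
law in every output.

The generator does **not** emulate: photomorphogenetic interference (the
inner leaf piercing an illuminated coleoptile and taking over the
dynamics), elongation and its destabilizing effect on tropic movement,
self-weight bending, non-planar light fields, or equilibrium angles read
before true steady state. Passing recovery tests on these synthetic data
therefore demonstrates the *inference pipeline's* correctness, not the
model's adequacy for any particular real organ.

```{r}
d <- generate_pgea_dataset(generator_spec(A0 = c(0, 10, 30) * pi / 180,
                                          seed = 42))
fit_intensity_law(d, "stevens_power")
```

## Problem sizes and tolerances

Default grids are 201 arc-length nodes (401 where a derivative example
needs the extra resolution), time steps of $T_c/100$ or finer for
closed-form comparisons, and at most a few hundred stored time slices per
run. At these sizes the documented tolerances are: $10^{-4}$ relative
sup-norm against the apical-photoception closed-form transient, $10^{-3}$
sup-norm for convergence of simulated trajectories to closed-form steady
states, $10^{-12}$ for the rotation equivalence between the local
photo-gravitropic and pure gravitropic trajectories (an algebraic identity,
limited only by round-off), and exact sign symmetry (bitwise) of mirrored
trajectories, which holds because every floating-point operation in the
right-hand sides and the integrator is odd under negation. The Monte-Carlo
calibration of the $B$ estimator (σ = 0.01 rad on 201 nodes, $B = 4$) keeps
the estimate within ±0.1 in well over 95% of 100 seeds.

## Known limitations

* The closed forms, and hence `steady_state()`/`aac_transient()`, cover the
  fully responsive organ only; with a partial growth zone, use the
  simulator and `detect_steady_state()`.
* The linearized sensing terms are quantitatively wrong for tilts beyond
  90°; the sine-law mode reproduces the qualitative behavior but no closed
  forms exist for it.
* The model neglects elongation, self-weight bending, and non-planar or
  spatially varying light fields; `GSA` (non-vertical gravitropic set
  points) is exposed but untested against data from non-orthogravitropic
  organs.
* The comparison of Stevens vs Weber–Fechner residuals across their
  different fit spaces is a heuristic; with strong noise the discrimination
  should be read qualitatively.
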