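---
title: "A dynamic-threshold model of load encoding by campaniform sensilla"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic-threshold model of load encoding by campaniform sensilla}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(campaniform)
library(dplyr)
```

## The model and its assumptions

Campaniform sensilla encode forces acting on an insect leg as strains in
the cuticle. The tibial receptors form two subgroups of opposite
directional sensitivity: one fires to increasing bending force, the
other to force decrements — most vigorously when the leg is unloaded
completely. This package implements a descriptive (not mechanistic)
model of that encoding: a rectified discharge function

$$y = \max\bigl[\,0,\; a\,(u - x) + c\,u + d\,\bigr]$$

driven by the applied force $u$ (mN) and a *dynamic threshold* $x$
obeying

$$\tau\,\dot{x} = \operatorname{sign}(u - x)\,|u - x|^{\,b}.$$

The threshold is a nonlinearly low-pass-filtered copy of the force: it
is driven toward $u$, moving quickly when far away and slowly when
close. The adaptive term $a(u-x)$ produces phasic, rate-sensitive
firing; the tonic term $cu + d$ produces sustained level-dependent
firing; the rectification clips negative drive to silence. None of the
constants maps onto an identified mechanical or electrochemical process
— the model earns its keep through its emergent behavior:

* an approximate power law between ramp rate and peak discharge
  (exponent near $1/b$ for the unloading response from zero offset);
* suppression of off-responses by sustained offset loads, approximately
  linear in the offset with slope near $-c$ once the threshold has
  adapted to the baseline;
* threshold "creep": during a hold $x$ keeps drifting toward the hold
  force, so longer holds produce larger off-responses — the same
  saturating shape as viscoelastic creep in the cuticle.

The two subgroups share one model form. The unloading-sensitive
(*antagonist*) subgroup is simulated with its own parameter set and
`input_sign = -1`, i.e. it sees the negated bending force. Whether the
biological input is truly the negated force or a distinct strain
variable is not established; the negation is this package's convention,
chosen because it reproduces the reciprocal firing pattern with a single
model form.

## Parameters

| constant | units | default | role |
|---|---|---|---|
| `a` | Hz/mN | 60 | phasic gain on $u - x$ |
| `b` | — | 1.2 | adaptation nonlinearity; $b=1$ exponential, $b<1$ finite-time convergence, $b>1$ power-law tail |
| `c` | Hz/mN | 10 | tonic gain |
| `d` | Hz | −1 | constant offset (negative values give a true firing threshold) |
| `tau` | s | 0.4 | threshold time scale |

The defaults are a demonstration tuning chosen to produce
phasic-plus-tonic on-responses, duration-dependent off-responses and
offset suppression on desk-scale protocols; they are documented as
non-canonical, since the tunings behind published species-specific
simulations are not public. With $b = 1.2$ the threshold relaxes with a
power-law tail, so creep remains visible over hold durations of
0.25–4 s given $\tau = 0.4$ s.

The initial threshold defaults to `x0 = 0` (fully unloaded rest). The
experiment drivers instead start each trial *adapted to its baseline*
(`x0 = "adapted"`), because an offset-series trial models a receptor
that has carried its offset load long before the test ramp arrives;
without this the residual relaxation from zero would leak into the
epoch metrics.

## Numerical integration

The threshold equation is integrated with classical RK4 on the stimulus
grid, treating the force as linear between samples. Three refinements
matter:

* **Adaptive sub-stepping.** The sub-step is bounded by a 10% change of
  the force–threshold gap *and* by the local linearized contraction
  rate $\lambda = b\,|u-x|^{b-1}/\tau$ (sub-step $\le 0.1/\lambda$).
  The second bound is what keeps the $b = 1$ case accurate to better
  than $10^{-6}$ relative error against the closed form.
* **Stiff fallback.** For $b < 1$ the gap has infinite stiffness at
  zero, and a ramp restarting from an absorbed threshold would demand
  unboundedly small steps. When the accuracy rule would require more
  than 64 sub-steps per sample, the integrator switches to the exact
  constant-force relaxation toward the frozen end-of-substep force —
  unconditionally stable, exact on flat segments, with a committed lag
  error below the per-sample force increment.
* **Absorption clamp.** When $|u - x| < 10^{-9}$ mN the threshold is
  snapped onto the force ($\operatorname{sign}(0)\,|0|^b$ is taken as
  0), avoiding sign chatter at the fixed point; within a
  constant-force segment the update never overshoots the fixed point.

These choices preserve two exact structural properties that the test
suite asserts at machine precision: odd symmetry
($x(t; -u, -x_0) = -x(t; u, x_0)$) and invariance under joint rescaling
of $\tau$ and the time axis.

## Stimulus conventions

All generators sample piecewise-linear force polylines on a uniform
grid (default `dt` = 1 ms, which resolves the fastest ramps used
anywhere in the package). Ramps are specified by *rate* (mN/s), the
paper-standard framing for rate-sensitivity work; durations are
derived. Grid samples at or beyond a plateau corner take the plateau
value exactly, so epoch segmentation is unambiguous and the plateau is
reached exactly even when the corner falls between samples. Staircase
plateau durations default to 1 s (a free choice; no canonical value
exists). White-noise and sinusoidal stimuli are deliberately absent.

## Cuticle viscoelasticity

The experiments motivating the model implicate viscoelastic creep in
the leg cuticle, but no constitutive equation is established for it.
The package uses the *standard linear solid* (Zener) model — the
minimal element exhibiting both stress relaxation under constant
displacement and bounded creep under constant force:

$$\mathrm{disp}(t) = F_0\left[\frac{1}{k_0} +
  \frac{1}{k_1}\bigl(1 - e^{-t/\tau_c}\bigr)\right],
  \qquad
  F(t) = d_0\left[k_{eq} + (k_0 - k_{eq})\,e^{-t/\tau_r}\right].$$

Defaults ($k_0 = 10$, $k_1 = 20$ mN per length unit,
$\tau_c = \tau_r = 1.5$ s) make creep clearly visible over the
0.25–4 s holds the duration experiments use. One documented deviation
from a strict Zener element: the creep and relaxation time constants
are independent fields, so asymmetric measurements can be fitted. For
arbitrary force histories the displacement is computed by an
exponential recursion that is exact for piecewise-linear forces. The
package asserts only a *shape* relation between mechanical creep and
the model's threshold creep — both monotone and saturating in hold
duration — because the quantitative mapping (which runs through the
unknown cuticle stiffness) is unresolved.

## Response metrics

`force_rate()` is a plain central difference with no smoothing —
matching how rate of force change is computed from recorded force in
this literature. `segment_epochs()` classifies samples by comparing
dF/dt against `rate_eps`, defaulting to 5% of the protocol's nominal
ramp rate: robust plateau/ramp separation without filtering, at the
cost of a one-sample ambiguity at plateau corners (the tests assert
boundary agreement at the sampling resolution). The off-response is
measured over the fall epoch only by default; an optional post-fall
window exists because real off-discharges can outlast the ramp, but it
defaults to 0 so that summaries are comparable across protocols.
`slope_fit()` reports r² as the squared Pearson correlation of observed
versus fitted values, the convention used when such plots are annotated
with r². `relative_gain()` divides by the firing at the minimal offset,
making the gain 1 there and scale-invariant.

## Spike-train fixtures

`poisson_spikes()` realizes an inhomogeneous Poisson process by
thinning against the peak rate, with one seeded RNG stream per train.
This is a fixture generator for exercising the analysis path on
recording-like data with known ground truth, *not* a claim about the
discharge statistics of these afferents (which are considerably more
regular); an optional absolute dead time is available and defaults to
0 because no ISI statistics are established for these units. The
binned rate reconstruction is unbiased on full bins; the final partial
bin, if any, underestimates.

## Parameter fitting

`fit_params()` minimizes the mean squared rate error over
$(a, b, c, d, \tau)$ within generous physical bounds
($a, c \in [0, 10^3]$ Hz/mN, $d \in [-100, 100]$ Hz,
$\tau \in [10^{-3}, 10^2]$ s, $b \in [0.1, 5]$) using multi-start
L-BFGS-B; restarts perturb the start multiplicatively from a seeded
stream, so fits are deterministic given the seed. The objective is on
rates rather than spike times because the model's output *is* a rate.

A single ramp does not identify the model: the tonic gain and offset
trade off along a near-flat valley (only $c\,u_{hold} + d$ is pinned).
The joint battery in `protocol_battery()` resolves all five constants:
an offset series with long holds (steady-state samples at three force
levels separate $c$ from $d$), a duration series (pins $b$ and $\tau$
through the creep time course), and a rate series (constrains $a$).
The battery deliberately keeps amplitudes near 1 mN: recovery is
assessed under noise scaled to the battery's *peak* rate, and a battery
whose peak is dominated by one large fast ramp makes the 1 Hz constant
$d$ unrecoverable in relative terms. The recovery study fits the
loading-sensitive subgroup, which fires over most of the trace; the
unloading-sensitive subgroup is rectified silent outside fall epochs
and therefore carries much less information per sample.

## What the synthetic data do and do not show

The generators reproduce the *protocol structure* of the motivating
experiments: trapezoidal ramp-and-hold at offsets, five-step
staircases, duration series over 0.25–4 s, and rate sweeps spanning at
least 1.5 decades; the offset examples use the standard 0/2.9/5.4 mN
series and the 0.85 mN, 8.5 mN/s test ramp. They do not emulate: measurement noise in the force
channel, long-term adaptation across repeated trials, animal-to-animal
variability in cuticle sclerotization, or the true ISI statistics of
the afferents. Passing tests therefore demonstrate that the model and
analysis pipeline behave as specified under clean, known-truth
conditions — not that the demonstration tuning quantitatively matches
any particular animal. The experimental slopes reported for real
preparations depend on undeposited recordings and unpublished tunings
and are deliberately not asserted anywhere in the package.

## Problem sizes

The test and acceptance workloads use 1 kHz sampling for single-trial
simulations, 2 ms sampling for the fitting battery, 20 seeded trials
for the noisy recovery study (2 restarts each), 100 seeded trains for
the spike round trip, and 200 randomized protocol/parameter cases for
the rectification and symmetry sweeps. These sizes give stable
statistics for every assertion while keeping a full run at desk scale.

## Known limitations

* The mapping from mechanical creep (length units) to threshold creep
  (mN) is left as a monotone shape relation; predicting discharges
  from measured cuticle stiffness would require extending the model to
  separate cuticle mechanics from transduction.
* Units of the discharge are nominal impulses/s; absolute firing rates
  depend on the unpublished tunings.
* The antagonist's negated-force input is a convention, not an
  established mechanism.
* No biophysics: channel gating, receptor currents and strain fields
  are out of scope by design.

```{r demo}
ex <- experiment_offset_series()
ex$metrics |>
  filter(subgroup == "antagonist") |>
  select(offset_mN, off_mean_hz, dx_creep_mN)
```
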