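---
title: "Decomposing duct resistance and fitting the valve sigmoid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing duct resistance and fitting the valve sigmoid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ductflow)
```

## The model

`ductflow` analyses steady pressure–flow measurements on ex vivo lymphatic
duct segments containing a single valve. The bench applies a staircase of
total pressure gradients $\Delta p_{total}$ (typically 0–10 cmH$_2$O in
1-cmH$_2$O increments) and records the steady volumetric flow $Q$ and the
segment's outer diameter $D_{out}$ at each step. The mounted segment plus
its rigid connectors is treated as a lumped series circuit,

$$\Delta p_{total} = (R_{conn} + R_{vessel} + R_{valve})\,Q = R_{total}\,Q,$$

so that the pressure budget splits exactly as
$\Delta p_{total} = \Delta p_{conn} + \Delta p_{vessel} + \Delta p_{valve}$.
The three resistances are obtained per pressure step:

* $R_{total} = \Delta p_{total}/Q$ directly from the measurements (the
  0-cmH$_2$O step, where this is $0/0$, is excluded from all fits but kept
  in the raw data);
* $R_{vessel} = 128\mu L/(\pi D^4)$, Poiseuille's law at the mounted length
  $L$ and the step's inner diameter $D$;
* $R_{valve} = R_{total} - (R_{conn} + R_{vessel})$ by subtraction, and
  likewise $\Delta p_{valve} = \Delta p_{total} - (R_{conn}+R_{vessel})Q$.

$R_{conn}$, the constant resistance of the rigid tubing and cannulae, is
calibrated once by perfusing a rigid phantom tube of known geometry: the
slope of its linear pressure–flow relation is the total setup resistance,
from which the phantom's own (computable) Poiseuille resistance is
subtracted.

The valve's resistance to forward flow is modelled as a logistic function
of the gradient across the valve,

$$R^m_{valve}(\Delta p_{valve}) = R_{vl} +
  \frac{R_{vh}}{1 + e^{s\,\Delta p_{valve}}},$$

with $R_{vl} > 0$ the open-valve plateau, $R_{vl}+R_{vh}$ the maximal
(near-closed) resistance and $s > 0$ the transition steepness. The
valve-opening threshold — the gradient at which the resistance has fallen
to within 5 % of $R_{vl}$ — has the closed form

$$\Delta p^t_{valve} = \frac{1}{s}\ln\!\frac{R_{vh}}{0.05\,R_{vl}}.$$

This closed form drops a $-1$ inside the logarithm relative to the exact
inversion of the sigmoid; the term is negligible whenever
$R_{vh} \gg 0.05 R_{vl}$, which holds by many orders of magnitude for every
specimen considered. The test suite checks the closed form against a
bisection solve of the exact equation to $10^{-4}$ cmH$_2$O.

An auxiliary exponential map
$\Delta p^m_{valve} = P_0 e^{A\,\Delta p_{total}}$ with $P_0 > 0$ is always
fitted to the decomposed valve gradients; it guarantees positive, smoothly
increasing gradient values and is reported with every fit.

## Units and conventions

All quantities are carried in bench units — cmH$_2$O, mL/min, mm, cP —
with resistances in cmH$_2$O·min/mL. Conversion to SI occurs only inside
the Poiseuille computation (1 cmH$_2$O = 98.0665 Pa, 1 cP = $10^{-3}$ Pa·s,
1 mL/min = $10^{-6}/60$ m$^3$/s), and a round-trip through SI reproduces a
resistance to $10^{-12}$ relative.

The inner diameter defaults to the thickness-corrected convention
$D = D_{out} - t$, where $t$ is the histology-derived wall thickness. The
geometric annulus relation $D = D_{out} - 2t$ is available via
`convention = "geometric"` on `inner_diameter()` and
`decompose_resistance()`; the single-$t$ form is the default because it is
the convention the reference parameter values were derived under, and switching
conventions changes $R_{vessel}$ (hence $R_{valve}$) materially for
thin-walled ducts whose lumen is only a few times the wall thickness.

Negative computed $R_{valve}$ values (possible in noisy data when the
valve contributes less than the measurement error) are kept, not floored,
so the fit sees the raw data; they trigger an auditable warning.

## Fitting choices

The phantom line is ordinary least squares with a free intercept; only the
slope is used downstream, the intercept being a diagnostic for offset
errors in the pressure head. The zero-pressure/zero-flow point is a valid
observation for the rigid phantom and anchors the line at the origin.

The sigmoid and the exponential map are fitted by Nelder–Mead minimisation
of summed squared residuals. Three numerical decisions matter:

* **Log-parameterisation.** $(R_{vl}, R_{vh}, s)$ are optimised as
  $(\log R_{vl}, \log R_{vh}, \log s)$, and $P_0$ as $\log P_0$. This
  enforces the positivity bounds without a constrained optimiser, and is
  also a conditioning necessity: fitted $R_{vh}$ spans roughly
  $10^2$–$10^{10}$ across specimens.
* **Multistart.** The residual surface has local minima when the data
  barely sample the high-resistance branch (only one or two steps sit in
  the transition). The deterministic, scale-aware start
  ($R_{vl} \leftarrow \min R_{valve}$,
  $R_{vh} \leftarrow \max R_{valve} - \min R_{valve}$,
  $s \leftarrow 10/\mathrm{range}(\Delta p_{valve})$) is complemented by
  four jittered starts drawn from a fixed seed; the best objective wins.
  Each Nelder–Mead run is restarted once from its optimum to rebuild a
  possibly collapsed simplex.
* **Objective.** The default is unweighted squared residuals on the
  resistance values — the default behaviour of the standard fitting tools
  in this field. An optional `objective = "log"` mode fits log-residuals,
  which weighs the open plateau and the near-closed branch evenly when
  $R_{vh}$ dwarfs $R_{vl}$; it is useful when the low plateau, not the
  transition, is the quantity of interest.

The sigmoid is evaluated through the logistic CDF
(`plogis`), so $e^{s\,\Delta p}$ never overflows even at
$|s\,\Delta p| \gg 700$.

## Which valve gradients feed the sigmoid fit

A genuinely open design question is whether the sigmoid should be fitted
against the *decomposed* per-step valve gradients (the subtraction values,
carrying measurement noise) or against the *smoothed* gradients from the
exponential map. `ductflow` defaults to the decomposed gradients
(`dp_valve_input = "observed"`) and offers the smoothed route
(`"mapped"`) as an option, for a measured reason: the true
$\Delta p_{valve}$-vs-$\Delta p_{total}$ curve of a series circuit is not
exponential — it rises steeply across the valve transition and then grows
linearly once the valve is open. Forcing it through $P_0e^{A\Delta p}$
biases precisely the transition-region points that identify $R_{vh}$ and
$s$. On noise-free synthetic data the observed route recovers all three
parameters to $\sim 10^{-9}$ relative and the threshold to $\sim 10^{-11}$
cmH$_2$O, while the mapped route leaves threshold errors of
0.08–0.39 cmH$_2$O that no fitting effort can remove, because they are
model error, not noise. Flow validation follows the same logic: the
headline $R^2_{flow}$ evaluates the fitted sigmoid at the decomposed
gradients, and the map-based prediction (the strict reading of the
validation equation) is reported alongside as `r_squared_flow_map`.

## The synthetic bench

Real bench data live in an external deposit; the package instead ships a
generator whose ground truth is known exactly, so every pipeline stage is
testable end to end. The generator emulates the protocol's stated world:

* the 0–10 cmH$_2$O staircase in 1-cmH$_2$O steps;
* an outer diameter following the saturating law
  $D_{out}(\Delta p) = d_{min} + (d_{max}-d_{min})\,
  \Delta p/(\Delta p + p_{1/2})$ with defaults $d_{min} = 1.5$ mm,
  $d_{max} = 3.5$ mm, $p_{1/2} = 2$ cmH$_2$O — a rectangular hyperbola
  chosen once to reproduce the qualitative rapid-distension-then-plateau
  behaviour of thin-walled ducts (no quantitative diameter–pressure law is
  published for this preparation);
* flow as the self-consistent solution of the implicit circuit equation
  $Q\,(R_{conn} + R_{vessel}(D) + R_{valve}(\Delta p_{valve}(Q))) =
  \Delta p_{total}$, solved by bisection (the residual is strictly
  increasing in $Q$, so the bracket
  $[0, \Delta p/(R_{conn}+R_{vessel}+R_{vl})]$ always works) to an
  absolute pressure residual of $10^{-10}$ cmH$_2$O;
* multiplicative Gaussian measurement noise, defaults 2 % on flow and 1 %
  on diameter — a declared assumption, since only qualitative variability
  is reported for the bench; noise applies to the *recorded* values while
  the physics uses the noise-free diameter, and non-physical draws are
  redrawn (capped at 100 attempts).

All randomness flows from one explicit seed through an RNG-preserving
helper, so equal configurations are bit-identical and the generator never
disturbs the caller's RNG stream.

What a green synthetic test establishes: that decomposition, calibration,
fitting and prediction are mutually consistent and recover known truth
under the stated noise. What it does not establish: that real duct data
satisfy the sigmoid model, that bench noise is multiplicative Gaussian, or
that the diameter law matches any particular specimen.

## Statistical conventions

The threshold summary reports the mean and the *population* standard
deviation (normalising by $n$, not $n-1$) across segments; with the five
published parameter sets this reproduces the printed 0.84 ± 0.42 cmH$_2$O,
whereas the sample convention would give 0.46. $R^2$ is the standard
$1 - SS_{res}/SS_{tot}$ about the data mean, reported as computed (it may
be negative for a model worse than the mean).

## Limitations

The pipeline is strictly steady-state and forward-flow: no retrograde
gradients, no dynamic (periodic-inlet) valve resistance, no active wall
contraction, and no leakage modelling (the setup is assumed
non-permeable). Parameter uncertainty is not quantified — the fits return
point estimates only. The
exponential pressure map is descriptive, not mechanistic, and should not
be extrapolated beyond the measured pressure range.
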