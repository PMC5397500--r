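---
title: "Methods: population-based fruit growth modelling and harvest optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-based fruit growth modelling and harvest optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popharvest)
```

This vignette documents the models implemented in `popharvest`, the
assumptions behind them, the numerical and design choices that were
genuinely open, and what the package's synthetic-data tests do and do not
demonstrate about real field data.

## 1. The per-fruit kinetic model

A fruit is described by two coupled states on its own developmental clock
("biological age", days): mass $M$ (g) and hue angle $H$ (degrees).

$$\frac{dM}{dt} = k_m M \ln\frac{M_{max}}{M}, \qquad M(0) = M_{max}e^{-C}$$

$$\frac{dH}{dt} = -(H - H_{min})\,k_h(M), \qquad H(0) = H_0$$

$$k_h(M) = \frac{k_h^{max}}{\bigl(1 + (M_{max}-M)/M_{max}\bigr)^{s}}$$

Mass follows Gompertz growth; hue decays exponentially toward its ripe
value $H_{min}$, but the decay rate is gated by a *biological switch*: for
large $s$, $k_h$ is a factor $2^{-s}$ below $k_h^{max}$ while the fruit is
still growing and rises steeply to $k_h^{max}$ as $M \to M_{max}$. The
switch is an empirical surrogate for the climacteric (ethylene-driven)
onset of ripening; no mechanistic hormone model is attempted.

Assumptions inherited from this structure:

* colour cannot revert (hue is monotone non-increasing, bounded in
  $[H_{min}, H_0]$);
* mass is monotone non-decreasing toward a fruit-specific ceiling;
* all fruit of a season share $(C, k_m, k_h^{max}, H_0, H_{min}, s)$;
  fruit-to-fruit variation enters *only* through $M_{max}$ and a time
  shift $\Delta t$ mapping the experimental clock (days since flower
  labelling) to biological age, $t_{age} = t_{exp} + \Delta t$.

Raw measurements are converted at the boundary: caliper diameter to mass
via a constant-density sphere (873 kg/m^3 by default, a value measured to
be stable across the whole size range of this cultivar), and CIELAB
$(a^*, b^*)$ to hue. The textbook $\arctan(b^*/a^*)$ is ambiguous for
green fruit ($a^* < 0$), so the package uses the two-argument arctangent
folded onto $[0, 180]$ degrees, which treats $(a,b)$ and $(-a,-b)$ as the
same hue, exactly as the single-argument ratio does.

**Units.** Internally grams and days everywhere; converters
(`mass_from_diameter()` returns kg, matching its formula's SI inputs) sit
at the I/O edges.

### Numerical treatment

`simulate_fruit()` integrates the two-state system with an adaptive
explicit Runge–Kutta pair (`deSolve`, `ode45`, rtol $10^{-8}$, atol
$10^{-10}$). Once triggered, the hue time constant is short
($1/k_h^{max} \approx 0.04$ d for the winter fit), so the maximum step is
capped at 0.1 d to resolve the switch; the problem is not stiff enough to
warrant an implicit solver.

Both states also admit (semi-)closed forms, which the package exploits
heavily:

* mass: $M(t) = M_{max}\exp(-C e^{-k_m t})$;
* hue: the colour equation is linear in $H$ given $M(t)$, so
  $H(t) = H_{min} + (H_0 - H_{min})e^{-K(t)}$ with
  $K(t) = \int_0^t k_h(M(u))\,du$.

Because $k_h$ depends on $M$ only through the relative mass
$M/M_{max} = \exp(-Ce^{-k_m t})$, the kernel of $K$ is *identical for
every fruit of a season*: one trapezoidal quadrature of $k_h$ (step
0.05 d, configurable) serves an entire cohort, turning a 10,000-fruit
population simulation into a vectorized interpolation. The ODE and
semi-analytic paths agree to $10^{-6}$ relative in mass and $\sim10^{-4}$
degrees in hue; the closed forms double as independent oracles in the test
suite.

## 2. Joint calibration

`calibrate()` estimates the shared parameters and every fruit's
$(M_{max}, \Delta t)$ from on-plant time series by least squares on the
*combined normalized* residuals: pooled mass and pooled hue are each
standardized (mean 0, sd 1) so the two channels carry equal weight
regardless of scale. $R^2$ is reported as $1 - RSS/TSS$ on that combined
normalized response (uncentered conventions make no difference here since
the standardized response has mean zero).

### Identifiability: the gauge constraint

The model is exactly invariant under
$C \to C e^{k_m\delta},\ \Delta t_i \to \Delta t_i - \delta$ (a rigid
shift of everyone's clock). Without a constraint the mean biological shift
is meaningless. The package's convention: **$C$ is always frozen** —
either at a user-supplied value (recovery studies fix it at the generating
value) or at an initial pooled estimate obtained with all shifts at zero —
and $\Delta t$ absorbs all per-fruit timing. This makes the cohort mean of
$\Delta t$ a well-defined, testable quantity.

### Optimization scheme

The objective is separable: given the shared parameters, each fruit's
$(M_{max}, \Delta t)$ subproblem is an independent two-parameter
least-squares fit. The optimizer alternates

1. an inner sweep of per-fruit Levenberg–Marquardt fits
   (`minpack.lm::nls.lm`, bounds $M_{max} > 0$,
   $\Delta t \in [-30, 30]$ d), and
2. an outer Levenberg–Marquardt update of the free shared parameters,

until the combined RSS improves by less than $10^{-8}$ relative or 50
outer iterations are reached. The `converged` flag reports which
criterion stopped the run; in practice the cap usually binds while the
remaining drift sits in the weakly identified switch pair
($k_h^{max}, s$) and is immaterial for the other parameters.

Plain alternation from naive starts can fall into poor optima (the switch
parameters then absorb timing misfit), so the alternation is warm-started
in stages:

* **mass stage** — $k_m$ by a profiled one-dimensional search, with
  per-fruit parameters refit from the mass channel alone at each
  candidate;
* **colour stage** — $(k_h^{max}, H_0, H_{min}, s)$ from the hue channel
  with per-fruit parameters held fixed, run twice around a *colour-break
  realignment*: each fruit's $\Delta t$ may be re-anchored so that its
  observed hue break (first drop 5 degrees below $H_0$, linearly
  interpolated) coincides with the model's break age, adopted only when
  it lowers that fruit's hue residuals;
* **joint stage** — the alternation proper, whose first inner sweep also
  tries the colour-break start against the mass-based one and keeps the
  better optimum per fruit.

The realignment exists because a fruit whose mass data are uninformative
(very small fruit, masses at the noise floor) would otherwise let
$\Delta t$ wander to a bound and contaminate the shared colour
parameters; the hue series pins its clock instead.

Standard errors for the free shared parameters come from the Jacobian of
the normalized residuals at the optimum with the per-fruit estimates
treated as known — they are *approximate* (the per-fruit uncertainty is
not propagated) and intended for reporting scale, not formal inference.
No hierarchical (random-effects) likelihood is attempted: the approach is
deliberately fixed-effects-per-fruit least squares.

Initial guesses: $M_{max,i} = 1.05 \times$ the fruit's largest observed
mass, $\Delta t_i = 0$, $H_0$/$H_{min}$ from the pooled hue extremes,
$k_h^{max} = 10$/d, $s = 40$. Fruit with fewer than four observations are
excluded and reported.

## 3. Population simulation

`fit_population_distribution()` matches the marginal means and standard
deviations of the calibrated $(M_{max}, \Delta t)$ set and records their
sample correlation. Defaults, chosen because no parametric family is
canonical here: a zero-truncated normal for $M_{max}$ (a moment-matched
lognormal is available and reproduces the right skew typical of estimated
size distributions), a normal for $\Delta t$, and independence — the
calibrated estimates of the two show no correlation for this cultivar. A
Gaussian copula links them when a correlation is requested.
`sample_population()` is a pure function of (distribution, $N$, seed) and
restores the caller's RNG state.

Ripening stages RS1 (mature green) through RS6 (red ripe) are hue bands;
intervals are half-open with the lower bound included, so a fruit exactly
on an edge belongs to the stage above that edge. Only the overripe
("waste") threshold of 54° is an established reference value; the default
edges 95/85/75/65/58/54 are package conventions spanning the green-to-red
range and should be replaced by a local grading chart where one exists
(`ripening_scheme()` takes arbitrary edges). Every conclusion that
depends on band widths — notably which fixed harvest interval wins —
should be read as conditional on the scheme.

## 4. The price model

Wholesale value is modelled on batch composition with a mixture design:
the six stage fractions sum to one, so the regression has *no intercept*,
and only the three interactions between the most distant maturity classes
(RS1·RS6, RS2·RS6, RS1·RS5) are included — the hypothesis being that
mixing very unripe with very ripe fruit depresses the price beyond the
linear blend. Although described as non-linear in the original survey
analysis, the model is linear in its coefficients and is fitted by
ordinary least squares; with a balanced panel (every rater prices every
mixture) the coefficients from the full data equal those from per-mixture
means.

Prices are min–max normalized to $[0,1]$ within each rater and season
before fitting, which makes raters with different absolute price levels
comparable and anchors a pure mature-green batch at 0. For a no-intercept
model the headline $R^2$ is the uncentered one ($1 - RSS/\sum y^2$); the
centered value is reported alongside. Predictions are not clipped:
out-of-range values are flagged, not altered.

Two caveats are worth stating plainly. First, the interaction columns take
only tiny values in the 13-mixture design (products of 0.01–0.04), so
their coefficients have large leverage — small perturbations of the
responses move them substantially, and they should not be over-read.
Second, for the same reason the fitted quadratic surface extrapolates
poorly far outside the design region: for green-dominated batches
(RS1 share exceeding the RS6 share by $\gtrsim 0.3$) the negative
interactions can make "adding green fruit" *raise* the predicted price.
Harvested batches targeted by realistic strategies sit well inside the
calibrated region.

## 5. Harvest strategies and accounting

`apply_harvest_strategy()` walks the schedule in order. On each date,
fruit whose current stage is targeted are removed at their current mass;
overripe fruit are removed as waste (mass counted, value zero) — by
default, because leaving rotting fruit on the vine would silently shrink
the waste statistics; `remove_waste = FALSE` restores the
leave-them-hanging variant. Decisions use the state at the exact harvest
date; there is no look-ahead. The saleable composition of an event spans
all six stages (a single harvest sells its green fruit at their
near-zero marginal price rather than discarding them), the event value is
normalized price/kg × saleable kg, and cumulative value is the plain sum
over events — no discounting, no labour or transport costs, no feedback
of crop load on the remaining fruit. Mass accounting is closed by
construction: saleable + waste + fruit left at the window end equals
every fruit's mass evaluated at its own removal (or end) date, and the
test suite verifies this against an independent replay to $10^{-9}$
relative.

`single_harvest_sweep()` evaluates a whole-crop harvest at every grid day
of a window and reports the value, saleable-mass and waste series;
`compare_strategies()` ranks arbitrary strategy lists on a common
simulated population, reporting absolute and best-normalized values, the
number of non-empty harvests, and the per-event breakdown.

## 6. The synthetic campaigns

`gen_fruit_observations()` emulates the reference field protocol: flowers
labelled in three cohorts 5 d apart; measurements every 3 d during growth
and every 2 d during ripening (the cadence switches at the fruit's own
colour break); monitoring per fruit until its noise-free hue falls below
56°, i.e. 2° above the waste threshold; independent Gaussian noise of
2 g on mass and 1° on hue. The noise levels are package defaults — the
original campaigns report no measurement-error model — sized to a caliper
plus colorimeter protocol; both are configurable. Reference cohort sizes
are 342 (winter) and 370 (summer) fruit.

What passing the recovery tests shows: with the stated cadence and noise,
the estimation machinery returns the season parameters to within a few
per cent and per-fruit parameters correlating > 0.95 with truth — i.e.
the pipeline is self-consistent at realistic signal-to-noise. What it
does not show: robustness to everything real data add — drift in shared
parameters across the season, non-Gaussian and serially correlated
measurement error, missed visits, fruit lost to damage, and model
misspecification of the switch shape. The generator shares the package's
trajectory evaluator (mass closed form, hue quadrature), so recovery
tests exercise estimation, not the integrator; the integrator is tested
separately against the closed forms and an independent quadrature oracle.

Problem sizes used in the shipped tests and acceptance script — cohorts
of 342/370 fruit for calibration checks, 10,000-fruit populations on a
daily 80-day grid for harvest economics — match the reference study; the
whole suite runs in well under a minute thanks to the shared-kernel
evaluation.

## 7. Known limitations

* The switch parameters $(k_h^{max}, s)$ are weakly identified by 2–3 d
  sampling: hue spends little time mid-transition, so wide ranges of the
  pair fit almost equally well. Their standard errors say as much; the
  recovery tolerance for them is 25% relative where other parameters get
  per-cent-level checks.
* $\Delta t$ is only as meaningful as the gauge convention behind it;
  comparing mean shifts across fits requires the same frozen $C$.
* Stage-scheme dependence (Section 3) and price-surface extrapolation
  (Section 4) bound the economic conclusions.
* Seasons are modelled as disjoint parameter sets; no temperature or
  other covariate links them.
* Absolute harvest-window dates are presentation-relative (the
  experimental clock starts at labelling); optima should be compared
  within a simulation, not across differently anchored ones.
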