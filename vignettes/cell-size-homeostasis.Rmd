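---
title: "Stochastic hybrid models of cell size homeostasis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic hybrid models of cell size homeostasis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellsizer)
```

## The model

Single cells grow and divide; size is kept near a set point by coupling the
division decision to size. `cellsizer` models one cell lineage as a
stochastic hybrid system (SHS, also a piecewise-deterministic Markov
process): between events the size $s(t)$ grows deterministically and
exponentially,
$$\frac{ds}{dt} = \mu s,$$
while division fires stochastically with size-dependent hazard $k s^\alpha$
— the probability of dividing in $(t, t+dt]$ is $k s^\alpha dt$. At a
division the size resets to $\beta s$, where the partition fraction
$\beta \in (0,1)$ is drawn fresh each time from a beta distribution with
mean $\langle\beta\rangle$ and noise $CV^2_\beta$ (`partition_law()`); the
point mass at $\langle\beta\rangle$ is the zero-noise limit. Exactly one
daughter is followed per division — there is no population tree.

The exponent $\alpha$ is the log-sensitivity of the division rate to size:

* $\alpha = 0$: size-independent timing (classical Poisson divisions) — not
  homeostatic (below);
* $\alpha = 1$: the *adder* — a constant size increment
  $\Delta \sim \mathrm{Exp}(\mu/k)$ is added per cycle regardless of birth
  size;
* $\alpha \to \infty$: the *sizer* — division at the threshold
  $k^{1/\alpha}$.

The quantities of interest are the stationary lineage moments
$\bar{\langle s^p\rangle} = \lim_{t\to\infty}\langle s(t)^p\rangle$ and the
derived noise $CV^2_s$ (variance over squared mean) and skewness.

## Exact moments and where closure enters

**Adder ($\alpha = 1$).** Applying the SHS generator to $\log s$ and to
$s^p$ gives closed equations at stationarity:
$$\bar{\langle s\rangle} = -\frac{\mu}{k\,\langle\log\beta\rangle},\qquad
\bar{\langle s^{p+1}\rangle} =
\frac{p\,\mu\,\bar{\langle s^p\rangle}}{k\,(1-\langle\beta^p\rangle)},\qquad
CV^2_s = -1 + \frac{\langle\log\beta\rangle}{\langle\beta\rangle - 1}.$$
The noise depends on the partition law alone. For a beta-distributed
$\beta$, $\langle\log\beta\rangle = \psi(z) - \psi(z/\langle\beta\rangle)$
with $z = (1 - \langle\beta\rangle(1+CV^2_\beta))/CV^2_\beta$; the package
evaluates this digamma form exactly (`mean_log_beta()`) and power moments
$\langle\beta^p\rangle$ by log-gamma differences so that irrational orders
(needed for general $\alpha$) lose no precision. For deterministic halving,
$CV^2_s = \log 4 - 1 \approx 0.386$ and the skewness — the standard third
standardized moment computed from the exact first three moments — is
$\approx 1.68$.

**General $\alpha$.** The transform $y = s^\alpha$ is again an adder-type
SHS (growth $\alpha\mu$, hazard $ky$, reset $\beta^\alpha$), so all
$y$-moments are exact (`powerlaw_y_moments()`). For $\alpha = 1/q$ with
integer $q$ this yields exact size moments,
$\bar{\langle s\rangle} = \bar{\langle y^q\rangle}$,
$\bar{\langle s^2\rangle} = \bar{\langle y^{2q}\rangle}$
(`powerlaw_exact_rational()`). For $\alpha > 1$ the size-moment hierarchy
does not close; `powerlaw_closure()` uses derivative matching — the
moment products that are exact for a lognormal — giving
$$CV^2_s \approx -1 + \left(
  \frac{\langle\log\beta\rangle}{\langle\beta\rangle-1}\right)^{1/\alpha},$$
decreasing in $\alpha$. The closure systematically *underestimates* the
simulated noise (the stationary law is not exactly lognormal); the test
suite asserts exactly this one-sided behaviour rather than a false
equality.

**Multi-step cell cycle.** Splitting the cycle into $M$ stages with
size-proportional transition hazards $k_i s$ (division from stage $M$)
keeps the system exactly solvable: per-stage moments obey a linear
recursion around the cycle, which `multistep_moments()` iterates for
arbitrary rates; for equal rates $k_i = kM$,
$$CV^2_s = -1 + \frac{1 + M + \langle\beta\rangle(M-1)}{2M}\,
\frac{\langle\log\beta\rangle}{\langle\beta\rangle-1},$$
which decreases monotonically from $\log 4 - 1$ at $M=1$ to the floor
$-1 + \tfrac{1+\langle\beta\rangle}{2}\,
\tfrac{\langle\log\beta\rangle}{\langle\beta\rangle-1} \approx 0.0397$
(deterministic halving) as $M \to \infty$ — about a ten-fold noise
reduction, with the partitioning-noise contribution attenuated to $3/4$ of
its single-step value. We validated the recursion against an independent
pair-sum form of the second moment and against the closed equal-rate
formula to $10^{-12}$.

The small-noise form implemented in `adder_cv2_approx()`,
$CV^2_s \approx \log 4 - 1 + CV^2_\beta/(1-CV^2_\beta)$, was chosen over
the superficially similar grouping $(\log 4 + CV^2_\beta)/(1-CV^2_\beta) - 1$
on three internal-consistency grounds: it agrees with the exact digamma
value to $\sim 6\times10^{-3}$ at $CV^2_\beta = 0.1$ (versus $0.15$ for
the alternative), it has the correct unit slope at zero partitioning
noise, and it is exactly the $M = 1$ case of the multi-step small-noise
decomposition.

**No homeostasis without size sensing ($\alpha = 0$).** With a constant
hazard the mean can only be held flat by exact balance,
$k = \mu/(1-\langle\beta\rangle)$ (`alpha0_balanced_rate()`), but the
second moment then still grows as $e^{rt}$ with
$r = \mu((1-\langle\beta\rangle)^2 + \mathrm{Var}\,\beta)/
(1-\langle\beta\rangle) > 0$ for *every* valid partition law
(`alpha0_second_moment_exponent()`): the size variance diverges, so active
size sensing is necessary. Because the $\alpha = 0$ moment system closes
at every order we use the analytic exponential solutions directly
(`alpha0_moments()`) rather than a numerical integrator.

## Exact simulation

`simulate_lineage()` is an event-driven simulator with *no* discretization
error. Along an exponential ramp the integrated hazard inverts in closed
form, so event times are sampled exactly:
$$\Delta t = \frac{1}{\alpha\mu}\log\!\left(1 +
  \frac{\alpha\mu(-\log u)}{k s_0^\alpha}\right), \qquad u \sim U(0,1),$$
(`next_event_time()`); equivalently, for the adder the division size
satisfies $s_d = s_b + \mathrm{Exp}(\mu/k)$ draw by draw. Multi-step
lineages interleave the $M-1$ stage transitions (hazard $k_i s$, size
continuous) with the division reset. All randomness derives from the
configured seed; `ensemble_snapshot()` gives each of its independent
lineages a sub-seed drawn deterministically from the master seed, so
results do not depend on evaluation order.

Stationary statistics are estimated two ways, mirroring the two natural
experimental protocols:

* **ergodic time averages** along one long lineage
  (`time_average_moments()`), the default: $\frac{1}{T}\int s(t)^p dt$
  evaluated with the exact per-segment primitive
  $(s_{\text{end}}^p - s_{\text{start}}^p)/(p\mu)$, never a time grid.
  Standard errors come from batch means over 50 contiguous time blocks
  (override via `n_batches`), which absorbs lineage autocorrelation;
* **ensemble snapshots** across many lineages at a fixed time
  (`ensemble_snapshot()`).

At stationarity the two agree, and the tests check both against the exact
formulas. Time averages are time-weighted integrals rather than samples at
event times because the stationary moments are expectations over the
continuous-time process; sampling only at division events would give the
(different) division-size distribution.

## Parameter estimation

The abstract promise of the moment formulas is inverse use: reading model
parameters off an observed size distribution. Because the formulas *are*
the contribution, estimation is by method of moments with exact inversion,
not likelihood:

* `fit_adder()`: solve the exact noise formula for $CV^2_\beta$ by
  one-dimensional root finding (the digamma expression is strictly
  increasing in $CV^2_\beta$), then the mean for $\mu/k$. Samples with
  $CV^2_s < \log 4 - 1$ are *infeasible* under $M=1$ and flagged as such
  rather than silently clipped.
* `fit_multistep()`: exhaustive grid over the integer stage count $M$
  (a stage count is not a continuous parameter), solving for $CV^2_\beta$
  and $\mu/k$ at each $M$, then selecting $M$ by an auxiliary moment: the
  Erlang prediction $CV^2_\Delta = 1/M$ if added sizes are available, the
  newborn-noise prediction otherwise. With sizes alone $(M, CV^2_\beta)$
  trade off along the noise formula; the fitter returns the whole feasible
  ridge with a warning instead of picking an arbitrary point.

$\langle\beta\rangle$ defaults to $1/2$ (daughter chosen at random);
sample noise uses the unbiased variance estimator. Seeded round-trip tests
(simulate, then fit) recover $M$, $CV^2_\beta$ within 30%, and $\mu/k$
within 2% at $10^5$ cycles.

## Defaults, problem sizes and numerical choices

* Generator/simulation defaults: $s_0 = 1$, burn-in 100 cycles, 50
  batches; canonical parameter points $\mu = k = 1$,
  $\langle\beta\rangle = 1/2$ with $CV^2_\beta \in \{0, 0.02, 0.05\}$, and
  $M = 5$ for the staged fixture — representative of adder-like bacteria
  where added-size noise is well below the single-step prediction.
* Test and validation runs use $10^4$–$10^5$ division cycles per lineage
  and a few thousand lineages per ensemble; at these sizes batch-means
  standard errors are a fraction of a percent of the target values, and
  every simulation-vs-formula comparison is made at $\pm 3$ standard
  errors.
* Degenerate partitioning ($CV^2_\beta = 0$) is a point-mass branch, not a
  limiting beta, avoiding digamma evaluations at infinite shapes.
* The beta feasibility bound
  $CV^2_\beta < (1-\langle\beta\rangle)/\langle\beta\rangle$ is enforced
  at construction (fail fast), not at use.
* Sensitivities at $CV^2_\beta = 0$ are computed with step $10^{-6}$ using
  the one-sided-domain centered difference $(f(2h) - f(0))/(2h)$, since
  negative $CV^2_\beta$ has no beta representation; at $h = 10^{-6}$ the
  truncation and cancellation errors are both $\sim 10^{-5}$ (a smaller
  step makes the digamma difference cancellation-limited).
* The small-noise approximation warns (rather than errors) above
  $CV^2_\beta = 0.2$, where its error grows beyond $\sim 10^{-2}$.

## What the synthetic data does and does not emulate

Simulated lineages reproduce the model's own assumptions: exact
exponential single-cell growth with a constant rate, power-law (or staged
linear) division hazards, instantaneous divisions, and i.i.d.
beta-partitioning. Real single-cell data additionally carry growth-rate
fluctuations within and across cycles, measurement noise, mother-daughter
correlations beyond $\beta$, and population-sampling (tree) biases —
none of which are modelled here. Passing tests therefore demonstrate
internal correctness of the formulas and simulator, not that any organism
follows this model; the estimation layer inherits the same caveat, and its
fits to real data should be read as method-of-moments projections onto
this model class.

## Known limitations

* Transient (time-dependent) moments are provided only for $\alpha = 0$,
  where the hierarchy closes; for $\alpha \ge 1$ only stationary moments
  are available.
* Only beta or point-mass partitioning; arbitrary partitioning densities
  are not supported.
* The closure for $\alpha > 1$ is the derivative-matching scheme only, and
  is biased low; no alternative closures are implemented.
* Whole-population (both-daughter) trees and non-exponential growth laws
  are out of scope.
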