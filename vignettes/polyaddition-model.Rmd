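---
title: "The polyaddition model: assumptions, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The polyaddition model: assumptions, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyadd)
```

## The model and its assumptions

`polyadd` models a solution of functionally identical monomer units,
each carrying one A and one B terminus, that link reversibly into
linear chains: A + B ⇌ AB with association rate constant $k_+$
(L mol$^{-1}$ s$^{-1}$) and dissociation rate $k_-$ (s$^{-1}$). Two
assumptions carry the whole structure:

1. **Well-mixed solution** — reactants move and collide independently
   of their size and polymerization state.
2. **State-independent rates** — $k_+$ and $k_-$ do not depend on
   whether a terminus belongs to a monomer or a long chain, nor on the
   position of a bond within a chain.

Under these assumptions every potential inter-monomer bond site has the
same occupation probability $p$, and the chain-length distribution is
geometric (Flory–Schulz) at all times — not only at equilibrium. The
distribution's single parameter $p$ carries all the dynamics; its
equilibrium value $P_b$ is set either kinetically, through
$\kappa = k_-/k_+$ (units of concentration: the bimolecular association
makes the equilibrium constant dimensional), or thermodynamically,
through the Boltzmann two-state occupation at bond free energy
$\Delta G_b$.

Everything the package computes is conditional on these assumptions.
Real oligomerization chemistry violates them in known ways — secondary
structure shields interior bonds from hydrolysis, cyclization removes
termini, surfaces and compartments break the well-mixed picture — and
such effects are exactly what a measured deviation from the model's
predictions (for example, a genuine steady-state length inversion)
would indicate. None of them are modeled here.

## Parameters, units, defaults

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `U` | mol/L | 1 | total monomer-unit concentration (conserved) |
| `kminus` | 1/s | 1e-6 | bond hydrolysis rate; representative of phosphodiester hydrolysis at pH ≈ 3, 85 °C |
| `kplus` | L/(mol s) | 7.4e-5 | association rate; the default pairs with `kminus` to give an 89% steady-state bonding probability |
| `dG` | kcal/mol | -1.5 | bond free energy; alternative parameterization of `kplus` |
| `T` | K | 358.15 (85 °C) | temperature; the CLI accepts °C and converts by +273.15 |
| `m0` | g/mol | — | monomer molar mass, only needed for mass distributions |
| `d` | — | 100 (CLI) | truncation length; capped at 2000 unless overridden (O(d²) right-hand side) |

The gas constant is fixed at $R = 1.987204\times10^{-3}$
kcal mol$^{-1}$ K$^{-1}$; all energies are kcal/mol and all
concentrations mol/L by convention — the package deliberately has no
unit-conversion layer.

One note on the default pair (`kplus`, `kminus`): $k_+ =
7.4\times10^{-5}$ corresponds to the free-energy route
$\Delta G_b = -1.5$ kcal/mol at 85 °C only after rounding the implied
bonding probability to 0.89; carrying the probability at full precision
gives $7.6\times10^{-5}$. The package treats the rate pair as the
primary default and the free energy as illustrative.

## Dynamics: the closed form and its branches

The bonding probability obeys the Riccati equation
$\dot p = k_+ U (1-p)^2 - k_- p$. With $\bar\kappa = \kappa/(2U)$ and
$\Delta = \sqrt{\bar\kappa(2+\bar\kappa)}$ the steady state is
$P_b = 1 + \bar\kappa - \Delta$ and the exact solution is hyperbolic:

* $p_0 > P_b$: $p(t) = 1+\bar\kappa-\Delta\tanh(\Delta k_+ U t + c)$
  with $c = \mathrm{artanh}((1+\bar\kappa-p_0)/\Delta)$;
* $p_0 < P_b$ (the usual all-monomer start): the artanh argument
  exceeds 1 and the solution continues analytically on the cotanh
  branch, $c = \mathrm{arcoth}((1+\bar\kappa-p_0)/\Delta)$;
* $k_- = 0$: the algebra degenerates to
  $p(t) = 1 - (1/(1-p_0) + k_+ U t)^{-1}$.

Branch selection keys on $\mathrm{sign}(p_0 - P_b)$ with tolerance
$10^{-12}$ (within tolerance the solution is constant). Hyperbolic
arguments are clamped at 350 to avoid overflow; beyond the clamp the
asymptote $P_b$ is returned exactly, which is also the correct limit to
double precision.

For the number-average degree of polymerization $\bar X_n = 1/(1-p)$,
the chain rule on the equation above gives
$\mathrm{d}\bar X_n/\mathrm{d}t = k_+ U - k_-\bar X_n(\bar X_n - 1)$.
A form with initial slope $2k_+U$ instead of $k_+U$ is sometimes quoted
for step-growth systems; `dXn_dt()` implements the factor-1 form
because it is the exact chain-rule image of the bonding dynamics used
everywhere else in the package, so $\bar X_n(t) = 1/(1-p(t))$ satisfies
it identically.

## Truncated simulation

The infinite reaction family $P_i + P_j \rightleftharpoons P_{i+j}$ is
truncated by **excluding reactions whose product exceeds $d$**, not by
deleting over-long chains after the fact. The distinction matters: the
exclusion scheme conserves monomer-unit mass exactly (each remaining
reaction does), whereas post-hoc deletion leaks mass every time a chain
grows past $d$ and decays toward the empty state. The test suite keeps
a small deletion-scheme integration as a documented counterexample of
that decay.

Numerical choices:

* **Solver** — `deSolve::ode` with `lsoda` (adaptive, switches to BDF
  when stiff; the system is mildly stiff at large $d$ and small
  $\bar\kappa$), default `rtol = 1e-8`, `atol = 1e-12 * U`, and a
  hand-derived analytic Jacobian (dense $d\times d$), which removes the
  $O(d)$ numeric-differencing right-hand-side calls per Jacobian
  refresh.
* **Output grid** — logarithmically spaced: the relaxation rate scale
  is $\Delta k_+ U$ (≈ $1.2\times10^5$ s characteristic time at the
  defaults), and trajectories span decades.
* **Steady-state detection** — integrate in expanding chunks until
  $\|\dot x\|_2 \le \mathrm{tol}\, k_+ U \|x\|_2$ (default
  $\mathrm{tol}=10^{-10}$) or until 100 relaxation times, whichever
  comes first; non-convergence warns and reports the achieved
  residual.
* **Flory–Schulz initial conditions on a finite grid** are renormalized
  by proportional scaling of all components so the grid carries total
  mass exactly $U$ (a choice — nothing canonical dictates how to place
  an infinite-tail distribution on a finite grid; proportional scaling
  preserves the geometric ratios).
* **$d$ cap** — 2000 by default purely for cost; `allow_large = TRUE`
  overrides.

## The truncation-error lower bound

A mass-conserving simulation at truncation $d$ produces a vector
supported on lengths $\le d$ with total mass $U$. The closest such
vector to the true distribution (in $\ell_2$) is the orthogonal
projection that (a) zeroes the tail and (b) restores the tail's mass
$M_y = U(1+d(1-p))p^d$ by the minimum-norm correction
$\delta x_k = k M_y / S_d$, $S_d = \sum_{k\le d}k^2 = d(d+1)(2d+1)/6$.
The distance to that projection,

$$E(p,d) = p^d\sqrt{1 + \frac{(1+d(1-p))^2(1-p^2)}{S_d\,(1-p)^4}} > p^d,$$

is therefore a floor under the relative error of *any*
mass-conserving truncation — independent of solver, tolerance, or
time step. Two reading notes:

* $E$ is the ratio of **unsquared** $\ell_2$ norms,
  $\|\hat n - n\|_2/\|n\|_2$: this is the only reading under which the
  closed form above is homogeneous of the right degree, and the one
  used when inverting for $d$.
* It is a **lower** bound only. No choice of $d$ guarantees achieving
  it; in practice solver precision flattens the achieved error floor at
  large $d$, which is hardware- and method-dependent and therefore not
  modeled.

`min_d_lax()` inverts the lax bound $p^d$ by the logarithm threshold
$\log_{P_b} E^*$ and reports it **rounded to the nearest integer**
(with the unrounded real value alongside); `min_d_full()` inverts the
full $E$ by doubling plus bisection, valid because $E$ is strictly
decreasing in $d$. At $P_b$ implied by $\Delta G_b = -3.5$ kcal/mol and
85 °C, the two give 632 and 700 for a 1% target.

## Interpreting experiments

A chromatographic "mass spectrum" — signal proportional to the total
mass at each chain length — has its peak at $k^* = -1/\ln p$, so a
peak position alone estimates $p$ (`method = "argmax"`; ties break
toward the smaller length, conservative toward shorter polymers). The
argmax estimator quantizes $p$ to $e^{-1/k}$ for integer $k$, so a
weighted least-squares alternative is provided:
$\log(m(k)/k) = \mathrm{const} + (k-1)\log p$ is linear in $k$, and a
signal-weighted regression estimates $\log p$ as its slope. At
equilibrium $p \to P_b$, which converts to a bond free energy at the
measurement temperature, and a second free energy at a reference
temperature separates $\Delta H_b$ from $\Delta S_b$ and locates
$T_c = \Delta H_b/\Delta S_b$. The reference value and temperature are
user-supplied arguments, not constants: comparing measurements made at
different temperatures to a standard-state value is a first
approximation, and the package does not endorse it beyond exposing the
arithmetic.

The synthetic-spectrum generator is the forward model of this chain:
exact $m(k)$ over lengths $1..k_{max}$ with multiplicative Gaussian
noise of chosen coefficient of variation (peak areas scale with signal,
hence multiplicative), clipped at $-0.99$ to keep signals positive.
What it deliberately does **not** emulate: baseline drift, peak
overlap and mis-binning of lengths, detector nonlinearity, and
composition effects in mixed-base chemistry. Passing the recovery tests
therefore shows the estimators are correct and reasonably
noise-robust under the model's own noise — not that they are robust to
real chromatographic artifacts.

The population sampler draws i.i.d. geometric lengths (support
$1, 2, \dots$, success probability $1-p$) for ground-truth molecule
populations.

## Degenerate inputs and edge conventions

* `p = 1` is rejected everywhere (infinite mean length); `p = 0` is
  legal for distributions but an error for `mass_mode()` — the mode is
  undefined in a monomer-dominated solution and callers must handle
  that case explicitly rather than receive an arbitrary 0 or 1.
* `kminus = 0` is a legal irreversible limit for dynamics
  ($P_b = 1$, algebraic relaxation) but an error for
  `rate_from_thermo()`, which cannot infer $k_+$ from it.
* `dS = 0` with `dH ≠ 0` is a degenerate regime — favorability fixed
  by the enthalpy sign, no critical temperature.
* Distribution vectors default to the smallest $k_{max}$ whose
  neglected tail mass is below $10^{-12} U$, capped at $10^6$.

## Problem sizes in the shipped tests

The test suite exercises the simulator at $d \le 100$ with the default
rate constants (trajectories to $10^7$ s, well past steady state),
checks the right-hand side against explicit reaction enumeration at
$d \le 8$, validates steady states against detailed-balance closed
forms at $d \le 10$ and the quadratic dimer equilibrium at $d = 2$,
and runs the noisy-spectrum recovery over 100 seeds at 5% noise.
These sizes were chosen to make every oracle comparison sharp (all
comparisons sit at tolerances between $10^{-6}$ and $10^{-14}$) while
keeping the whole suite interactive.

## Known limitations

* No stochastic (jump-process) simulation: the deterministic
  mass-action limit is the model; a Gillespie-style sampler would be a
  useful cross-validation oracle but is not part of the package.
* No upper bound on truncation error — the theory here gives a floor,
  not a guarantee.
* No fitting of $(k_+, k_-)$ to time-course data; only forward
  evaluation and algebraic inversion are provided.
* Monomers are functionally identical: no base identity, sequence
  composition, or copolymer statistics.
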