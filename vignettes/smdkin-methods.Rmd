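---
title: "Free-energy and kinetic analysis of stepwise transformations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy and kinetic analysis of stepwise transformations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdkin)
```

## Scope and model

`smdkin` analyses stepwise chemical transformations whose elementary steps
are characterised by two free energies each: the activation free energy
$\Delta G^\ddagger$ (transition state above the step's own reactant level)
and the reaction free energy $\Delta G$ (product above reactant), both in
kcal mol$^{-1}$ at a common temperature. Its motivating application is the
water- and formic-acid-assisted conversion of adenine to guanine, which
proceeds through hydrolytic deamination (adenine to hypoxanthine),
oxidation (hypoxanthine to xanthine) and amination (xanthine to guanine),
each a two-step mechanism, in gas and aqueous solution phases. The bundled
table `ag_energetics()` carries the reference step energetics of that
system at 298.15 K.

Three computational layers sit on top of such tables:

1. **Transition-state-theory kinetics** (`annotate_steps()` and friends)
   derives, per step,
   $$K = e^{-\Delta G/RT}, \qquad
     k_f = \frac{k_B T}{h} e^{-\Delta G^\ddagger/RT}, \qquad
     k_r = \frac{k_B T}{h} e^{-(\Delta G^\ddagger - \Delta G)/RT}, \qquad
     \tau = 1/k_r .$$
   The transmission coefficient is fixed at 1 and no tunneling or
   variational correction is applied. All exponents are assembled in log
   space and exponentiated last, so barriers up to $|\Delta G| \approx
   200$ kcal mol$^{-1}$ (rates and lifetimes spanning roughly
   $10^{-55}$–$10^{+44}$) are handled without overflow.

2. **Profile composition** (`compose_profile()`, `pathway_global()`)
   chains steps into processes and processes into a pathway. A profile of
   $n$ steps has $2n+1$ strictly alternating stationary/transition levels,
   each cumulative relative to the initial reactants. The activation free
   energy of a composed segment is defined as the *maximum cumulative
   transition level* and its reaction free energy as the final stationary
   level; the transition state achieving that maximum is the
   rate-determining step (ties broken by earliest occurrence, for
   deterministic output). This cumulative-maximum rule reproduces the
   published global barriers of the adenine-to-guanine pathway, 74.15
   (gas) and 72.88 (solution) kcal mol$^{-1}$, exactly, with TS4 (the
   rupture of the formate–base linkage during oxidation) rate-determining
   in both phases. Process-level kinetics are recomputed from the composed
   $\Delta G^\ddagger/\Delta G$ rather than combined from step rate
   constants: no steady-state or pre-equilibrium kinetic model is implied.

3. **Jarzynski estimation** (`jarzynski_dG()`, `cumulant2_dG()`,
   `bootstrap_ci()`) converts an ensemble of nonequilibrium work values
   $W_i$ from repeated steered pulls into a Gibbs free-energy difference
   $$\Delta G = -RT \ln \frac{1}{N}\sum_i e^{-W_i/RT},$$
   evaluated through log-sum-exp for stability. The second-cumulant
   estimator $\bar W - s_W^2/(2RT)$ (unbiased variance) is exact for
   Gaussian work and serves as a near-equilibrium diagnostic; divergence
   of the two estimators signals either strong dissipation or a
   far-from-Gaussian tail.

## Constants and units

$R = 1.9872041\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$;
$k_B = 1.380649\times10^{-23}$ J K$^{-1}$ and
$h = 6.62607015\times10^{-34}$ J s (2019 exact SI values); the Coulomb
prefactor is the AMBER convention 332.0636 kcal Å mol$^{-1}$ e$^{-2}$.
The default temperature is 298.15 K everywhere, overridable per call.
Engine units are kcal mol$^{-1}$, Å, amu, fs, K; friction in ps$^{-1}$.

## The published tables and their internal inconsistencies

The free energies are treated as the primary data and $K$, $k$, $\tau$ as
derived, because the reference tables declare them derived by exactly the
formulas above. Propagating the tables' 0.01 kcal mol$^{-1}$ rounding
through $e^{\Delta G/RT}$ gives a relative tolerance of about 2%; the
package's reproduction checks allow 5% for $K$ and 15% for $k$ and $\tau$.
Recomputing every row shows that a minority of published derived values
are *internally inconsistent with their own row's free energies* well
beyond that tolerance: one lifetime appears to carry an exponent typo
(printed $10^{+33}$ where the formula gives $10^{+23}$), one step's rate
constant equals the cumulative-barrier rate of its parent process rather
than its own, one process's activation energy disagrees with the
composition of its printed steps, and the gas-phase global reaction energy
(4.07) differs from the sum of its process values (4.47). These rows are
flagged (`K_ok`, `k_ok`, `tau_ok` in `ag_energetics()`), excluded from the
reproduction checks, and never silently corrected: the package reports
what the free energies imply and keeps the discrepancy visible.

## The toy pulling engine

The steered-dynamics layer is a deliberately small classical engine whose
purpose is to exercise the full pull → work → Jarzynski → kinetics chain
against analytic ground truth on one CPU; it does not attempt to reproduce
the reference system's QM/MM energetics, which enter only through the
tables. Systems are a few atoms with pairwise LJ(12-6-1) interactions
$A_{ij}/r^{12} - B_{ij}/r^6 + C q_i q_j / r$ (direct sums, no cutoff, no
periodicity, bonded pairs excluded), harmonic bonds and angles, optional
per-axis positional restraints, and optionally frozen atoms.

Reaction coordinates are interatomic distances $d(a,b)$ or distance
differences $d(a,b) - d(a,c)$, the two families used to steer the
reference simulations (e.g. the nucleophilic-attack distance and the
proton donor/acceptor difference coordinates). A harmonic restraint
$\tfrac{k}{2}(\xi - \lambda(t))^2$ with strictly linear schedule
$\lambda(t)$ drags the coordinate; the work increment per step is
$-k(\xi - \lambda_{\text{mid}})\,\Delta\lambda$ with $\lambda$ evaluated
at the midpoint of each schedule segment. The midpoint rule is
second-order accurate and *exact* for a static system, which pins the
discretization in the frozen-particle tests.

The integrator is the BAOAB Langevin splitting, chosen because it is
standard, stable, exact for harmonic configurational sampling, and reduces
identically to velocity Verlet when $\gamma = 0$ and $T = 0$ — the limit
used for the energy-conservation and ODE-oracle tests. Replica $r$ of an
ensemble runs under seed $s + r$ derived from the master seed $s$; all
randomness is confined to these explicitly seeded streams and the global
RNG state is restored afterwards.

Default integrator settings (all overridable): $dt = 0.5$ fs, safely
below the fastest period of the bundled benchmarks (~33 fs); friction 1
ps$^{-1}$ for generic runs; restraint stiffness chosen per protocol.

## Analytic benchmarks

`gen_pull_benchmark()` builds two systems whose end-state free-energy
difference is known independently of any dynamics:

* **flat** — a single particle with no internal potential, tethered to the
  pulling axis by stiff transverse positional restraints. Because the
  restrained partition function is then independent of the restraint
  centre, $\Delta F = 0$ between any endpoints, and the entire measured
  work is dissipation. This benchmark drives the second-law and
  pulling-speed tests (slower schedules dissipate measurably less).

* **two_state** — a mobile particle between two fixed LJ anchors of
  different well depth (defaults: $\varepsilon$ = 2.0 and 1.0 kcal
  mol$^{-1}$, $r_{\min}$ = 2.5 Å, separation 7 Å), giving an asymmetric
  double well along the axis with a barrier of ~1.3 kcal mol$^{-1}$.
  The transverse tethers (1000 kcal mol$^{-1}$ Å$^{-2}$) make the motion
  effectively one-dimensional, so the exact restrained free energy
  $F(\lambda) = -RT\ln\int e^{-[U(x)+\frac{k}{2}(x-\lambda)^2]/RT}\,dx$
  is computable by 10$^4$-point trapezoidal quadrature. The residual
  transverse LJ coupling perturbs $\Delta F$ by well under 0.02 kcal
  mol$^{-1}$, far below the statistical resolution of a 200-pull
  ensemble; this is the one stated approximation of the oracle.

The default two-state protocol (6000 pulling steps of 0.5 fs after 1000
equilibration steps, spring 100 kcal mol$^{-1}$ Å$^{-2}$, friction 5
ps$^{-1}$) keeps the mean dissipated work near 0.2 kcal mol$^{-1}$,
comfortably inside the regime where the exponential estimator with a few
hundred pulls is reliable.

## What the synthetic data do and do not show

The Gaussian work generator emulates the near-equilibrium regime of
repeated steered pulls, where the Jarzynski average has the closed form
$\mu - \sigma^2/(2RT)$; the validation at $\sigma^2 = 2RT$ (implied
bias of exactly 1 kcal mol$^{-1}$) checks the estimator, not any real
work distribution. Real QM/MM pulling work on a reacting system is
neither Gaussian nor near-equilibrium in general, the reference study
reports neither pull counts nor speeds nor error bars, and no attempt is
made to regenerate the published tables from simulation. Passing tests
therefore demonstrate the correctness of the estimator mechanics and of
the engine's statistical mechanics on systems with computable truth — not
the accuracy of the published free energies themselves.

## Numerical choices and degenerate inputs

* Composed profile values are kept at full precision internally and
  rounded only at output, since the published tables' own rounding already
  produces visible inconsistencies.
* Negative activation energies and negative reverse barriers (possible
  with composed, rounded inputs) warn but do not error.
* Equal-height transition states: the earliest wins.
* Zero-size degenerate inputs: an empty step table annotates to an empty
  table; an empty step list or process list is a domain error.
* The percentile bootstrap (default $B = 1000$) is used instead of BCa
  for simplicity and determinism; a degenerate work sample yields a
  zero-width interval.
* Integration failure (any coordinate beyond $10^6$ Å) aborts with the
  failing step, and ensembles propagate the failing replica index.

## Validation problem sizes

The test-suite and acceptance checks run, by design, at desk scale:
$10^6$-sample Gaussian ensembles for the closed-form recovery (absolute
error below 0.05 kcal mol$^{-1}$); $10^4$ microcanonical steps for energy
conservation (relative drift below $10^{-4}$); $5\times10^5$ thermostatted
steps with friction 20 ps$^{-1}$ for equipartition (mean kinetic energy
per degree of freedom within 5% of $RT/2$; the strong coupling shortens
the kinetic-energy autocorrelation so the statistical error of the check
is a fraction of its tolerance); and 200-pull ensembles for the two-state
benchmark, whose bootstrap interval brackets the quadrature value.

## Known limitations

No periodic boundaries, Ewald summation, constraint algorithms, water
models or bonded-topology perception: systems are specified explicitly.
Kinetics are pure Eyring TST with unit transmission; no Crooks/BAR
bidirectional estimation, weighted-histogram analysis or stiff-spring PMF
deconvolution. Pathway composition takes the user's step ordering as
given; alternative routes (e.g. the B- and D-variants of deamination and
amination) are composed by passing their rows rather than enumerated
automatically.
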