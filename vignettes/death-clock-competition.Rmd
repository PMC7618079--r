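---
title: "Death-clock models of emergent cell competition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Death-clock models of emergent cell competition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deathclock)
```

This vignette documents the modelling assumptions behind `deathclock`, the
estimators it uses, the numerical and design choices that were genuinely
open, and what the accompanying tests do and do not establish.

## The death-clock framework

The framework couples two cellular processes. The **cell cycle** is
autonomous: at birth a cell draws a G1 duration $t^\ast$ from a family
$\mathcal{C}$ with support on $[0,\infty)$ and mean $t_{G1}$ (exponential
by default; a degenerate "fixed" family is provided for deterministic
cycles), then spends a fixed $t_{G2}$ in G2 — shorthand for the lumped
S/G2/M phases — and divides. The **death clock** is non-autonomous: it
integrates the extracellular death signal, $\dot\tau = f(t) \ge 0$, from
$\tau = 0$ at birth, and apoptosis triggers when $\tau$ reaches the
threshold $T_\dagger$ while the cell is in G1. Cells in G2 are committed
to division: their clock keeps integrating but cannot kill them, and it is
discarded at division because both daughters are fresh births.

Two conventions resolve edge cases the framework itself leaves open:

* the survival condition is strict ($\tau(t^\ast) < T_\dagger$), so a
  clock that exactly reaches the threshold kills; this makes survival and
  apoptosis complementary events;
* a death that coincides exactly with the G1-to-G2 transition resolves to
  death ("death wins"); in the fixed-step vertex engine, a cell is
  vulnerable in the step during which it leaves G1.

Death signals are represented as piecewise-constant functions
(`signal_primitive()`). This is exact, not an approximation: in both
simulators the signal only changes at discrete events, so the integrated
signal is piecewise linear and threshold crossings have closed forms. For
a prescribed signal, the survival probability is
$\theta = \Psi(F^{-1}(T_\dagger))$, where $F$ is the integrated signal,
$F^{-1}$ its pseudoinverse (first-passage time, $+\infty$ if the signal
never accumulates to the threshold), and $\Psi$ the G1-duration CDF.

## The G2 death signal and its dimensionless parameters

In the G2 death-signal model a cell receives $f = c\,g$, with $g$ the
fraction of its neighbours in G2 phase: proliferation itself is the source
of killing. Two dimensionless numbers per type determine everything:
$\beta = t_{G1}/t_G$ and $\eta = T_\dagger/(c\,t_G)$. The signal strength
$c$ is a free scale absorbed by $\eta$; configurations therefore default
to $c = 1$, and `expand_dimensionless()` / `nondimensionalise()` map
exactly between the two parameterisations.

The closed forms implemented in `homotypic_lambda()`,
`heterotypic_xi()`, `asymptotic_survival()`, `classify_regime()` and
`tolerance_emission()` all assume the exponential cycle family and the
**ergodic, well-mixed approximation**: the fraction of cells in G2 at any
instant is replaced by the mean G2 fraction of the cycle ($1-\beta$
homotypically, the abundance-weighted $\langle 1-\beta\rangle$ in mixed
populations). The generic-$\Psi$ route is exposed through
`homotypic_lambda_general()` and `survival_probability()` for other
families.

Regime classification follows a fixed hierarchy: homotypic viability
($\lambda > 1/2$ in this analytic layer, against the $\ge 1/2$ convention
used for empirical frequencies — both conventions are kept deliberately in
their respective layers); the winner by relative tolerance $\eta/\beta$;
loser elimination by the asymptotic $\xi^\infty_{L|W}$ against $1/2$; and
the loser-side homotypic survival difference for the
neutral/indirect/incomplete distinctions. Analytic boundaries (exact
equalities) are detected with an absolute tolerance of $10^{-12}$ and
mapped to the boundary regimes; the classifiers refuse to compare types
with different total cycle durations unless overridden, because the
winner/loser ordering presumes equal generation times. The
tolerance–emission reformulation is implemented independently
(`regime_from_tolerance_emission()`) and the two routes are required to
agree exactly on a parameter grid in the test suite.

## The well-mixed engine

`run_wellmixed()` is exactly event-driven. Between events every cell's
signal fraction $g$ (the share of the *other* cells in G2) is constant, so
the next event is the minimum over cells of the G1 exit time, the division
time, and the clock-crossing time $(T_\dagger-\tau)/(c\,g)$; clocks then
advance linearly. Ties are processed in (time, cell id) order with cell
ids assigned monotonically at birth, making runs bit-reproducible given
the seed. A fixed-step integrator (`run_wellmixed_fixedstep()`) exists
solely as a cross-check; the test suite verifies that its event counts
converge to the event-driven log as the step shrinks.

Two initial conditions are supported. `"newborn"` starts every cell at age
zero (simplest, but synchronises the population: no signal at all until
the first G1 exits). `"staggered"` samples each initial cell's phase from
the stationary cycle occupancy (G2 with probability $1-\beta$, uniform
residual) and backdates births accordingly; initial G1 cells keep a fresh
exponential draw (memoryless) and a zero clock. Staggered initialisation
is used for all quantitative comparisons; the clock-at-zero approximation
for initial cells affects only the first generation.

### Estimating survival frequencies

The empirical viability statistic is the survival frequency
$\#\text{divisions}/(\#\text{divisions}+\#\text{deaths})$. For *viability
classification* (which side of $1/2$) the package uses whole-run
frequencies — robust, and unbiased exactly where it matters, near
stationarity.

For *quantitative* comparison against the closed forms, whole-run
frequencies carry two systematic artefacts that the ergodic theory does
not model: a growing population develops a young-biased age structure
(excess G1 occupancy, hence a weaker signal and inflated survival), and a
collapsing population ends with a handful of isolated survivors receiving
no signal at all. The package therefore provides a **cohort estimator**
(`cohort_survival_frequency()`): the fates of cells that start G1 with a
zero clock inside a large, freshly stationary population — the initial G1
cells plus cells (re)born before a cutoff, taken as one cycle time. This
is a direct Monte-Carlo of the survival probability under near-ergodic
conditions. Daughters in fresh id slots whose birth times the log does not
carry are dropped; their co-daughters (which reuse the mother's slot) are
statistically exchangeable, so the omission is unbiased. Residual
deviations of order $0.03$ remain at strong growth rates; they are a
property of the model–theory gap, not of the estimator, and the
theory-versus-simulation tests size their event counts (about 500–900 per
point, binomial $3\,\mathrm{SE} \approx 0.06$) to the resolution at which
the ergodic approximation is meaningful.

Problem sizes used by the tests and the acceptance script: 450 cells over
4 cycle times per grid point for the homotypic grid; 100 + 100 cells to 25
cycle times (capped at 1500 fate events) for each heterotypic
classification run; 300 + 300 cells for the on-curve difference checks.

## The vertex-based engine

`run_vertex()` implements the standard 2D vertex model: polygonal cells,
energy
$E=\sum_\alpha \tfrac{K_\alpha}{2}(S_\alpha - S^0_\alpha)^2
 + \sum_\alpha \tfrac{\Gamma_\alpha}{2}L_\alpha^2
 + \sum_{\langle ij\rangle} \Lambda_{ij}\ell_{ij}$,
overdamped dynamics $\mu \dot r_i = F_i$ with $F_i = -\nabla_i E$, explicit
Euler steps of $dt = 0.05$, T1 swaps on interior edges shorter than 0.1,
and T2 extrusion of cells below area 0.01. The negative gradient is a
deliberate choice: the positive sign sometimes written for the equation of
motion would make every equilibrium repulsive; with the negative sign,
free relaxation descends the energy, which the tests verify directly
against central finite differences ($<10^{-6}$ relative error) and as
monotone energy descent.

Line tensions are resolved per edge type ($\Lambda_{AA}, \Lambda_{AB},
\Lambda_{BB}$); boundary edges default to the corresponding homotypic
tension ($\Lambda_A = \Lambda_{AA}$, $\Lambda_B = \Lambda_{BB}$) since the
sweep bounds constrain only the three interior tensions — both are
overridable. After a T1 the new edge is set to 1.05 times the threshold, a
conventional expansion factor chosen to avoid immediate re-triggering;
the factor is configurable and no result in the package is sensitive to
it. Two rare degenerate configurations are handled conservatively: a T1
whose flanking cell wraps around *both* edge endpoints is skipped (the
shrinking region is resolved by T2 instead), and a T2 collapse that
pinches a wrapped neighbour through the new vertex keeps that neighbour's
main lobe. Cell division bisects the mother through its centroid at a
uniformly random orientation (the division axis is otherwise
unconstrained; orientations that would produce degenerate polygons are
redrawn, bounded retries), conserving area exactly and inserting the new
vertices into the adjacent cells so the mesh stays conforming.

Cycle and death-clock events are checked once per mechanical step — the
mechanics already force a fixed step, so an event-driven treatment would
buy nothing. The local G2 signal is the fraction of *edge-adjacent*
neighbours in G2; dying cells are excluded from numerator and denominator,
never divide, but keep exerting forces until extruded. Apoptosis shrinks
the cell's target area to zero so that it contracts and is removed by T2;
the death is logged at the trigger, not at extrusion. In the purely
mechanical model (death clock off) T2 extrusions of live cells are the
passive death mode and are logged as deaths.

Initial tissues are hexagonal patches (36 cells by default, matching the
sweep protocol of two 36-cell homotypic runs plus one 18 + 18 heterotypic
run), with `"random"` (uniform placement, exact equal split) or
`"segregated"` (two contiguous half-tissues) type arrangements. Initial
ages and phases are unspecified in the source protocol; the engine
defaults to newborn and offers the same staggered option as the well-mixed
engine, which the quantitative runs use.

The vertex viability runs in the tests use a cycle time of $t_G = 100$
with simulation time 250 — about 2.5 generations from 36 cells, enough to
produce on the order of a hundred fate events, which cleanly separates the
viable ($\lambda = 0.86$) from the nonviable ($\lambda = 0.18$) test
points. Vertex survival frequencies agree with the well-mixed theory only
qualitatively: local neighbourhoods are small and spatially correlated, so
the borders are blurred relative to the well-mixed case — this is a
finding, not a defect, and the tests assert only the side of $1/2$.

## Sweep machinery

`oa_lhs_sample()` builds a strength-2 orthogonal array over the prime
field GF($q$) — runs indexed by $(a,b) \in \mathrm{GF}(q)^2$, columns $a$,
$b$, $a + mb$ — and refines it into a Latin hypercube by assigning, within
each coarse level of each column, a random permutation of the $q$ fine
bins. Every factor pair then covers each $q \times q$ cell exactly once
and every 1D projection has one point per $q^2$ bin; both properties are
tested exhaustively at $q = 3, 5$ and by sampling at $q = 53$. The
13-factor mechanical design uses $q = 53$, giving $53^2 = 2809$ parameter
sets; 53 is the unique prime whose square matches that design size.
Remaining engine constants (friction, thresholds, timestep, 36-cell
initial patch, simulation time 250) follow the defaults tabulated for the
mechanical model.

`run_sweep()` executes the two-homotypic-plus-one-heterotypic trio per
set, classifies outcomes into the viability matrix, and records failures
(excluded from tabulation, mirroring the treatment of errored parameter
sets in the reference sweep). The full $2809 \times 3$ vertex sweep is
cluster-scale and is not re-run here; the shipped
`inst/extdata/mechanical_sweep_viability_counts.csv` holds the tabulated
outcome counts of that sweep, and the package recomputes all aggregate
statistics from that table. A seeded 20-set smoke sweep through the
well-mixed engine exercises the machinery end-to-end at desk scale.

The significance protocol for flagged competitive sets
(`significance_test()`) is the package's own specification (the original
protocol is not public): four one-sided exact binomial tests on pooled
division/death counts — both homotypic frequencies above $1/2$, winner
heterotypic above, loser heterotypic below — Bonferroni-corrected at the
family level. It is conservative by construction; `targeted_retest()`
applies it to replicate runs, optionally with segregated initial
conditions.

## What the synthetic conditions do and do not show

The simulators generate their own populations; no external data enters.
The study conditions emulate idealised co-cultures: equal total cycle
times between types, instantaneous well-mixed coupling (or strict
edge-adjacency in the vertex case), a single scalar death signal, and
apoptosis as a hard threshold. Passing tests therefore establish internal
consistency — simulation matches the analytic theory where the theory's
assumptions hold, and the classifiers agree across independent
formulations — not that any real tissue follows these rules. Known
limitations: no diffusible-ligand or mechanical-compression signals, no
difference in generation times between competitors, free (non-periodic)
tissue boundaries, and vertex rearrangement edge cases resolved by
pragmatic local surgery rather than an exhaustive case analysis.
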