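---
title: "A mechanistic model of targeted radionuclide therapy of disseminated blood cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic model of targeted radionuclide therapy of disseminated blood cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trtsim)
```

## The model

Targeted radionuclide therapy (TRT) treats disseminated cancer by
injecting cancer-specific antibodies conjugated to radioactive
nuclides. The motivating system is a disseminated multiple myeloma
mouse model treated with an alpha-emitter (actinium-225) conjugated to
an anti-CD38 antibody. Treatment efficacy is limited by toxicity:
decays of nuclides circulating in blood irradiate well-perfused
proliferating tissue, above all bone marrow, so cumulative *decays in
blood* are the model's toxicity currency.

`trtsim` integrates a deterministic ODE system with nine dynamic
variables plus four bookkeeping integrals:

* `a`, `b` — plasma concentrations of *active* (nuclide-carrying) and
  *inert* (unlabeled or decayed) antibodies, nM;
* `p` — plasma concentration of active antibody fragments released
  from dead cancer cells, nM;
* `N`, `D` — viable and damaged cancer cells, in units of 1e7 cells;
* `f_FN`, `f_AN` — fractions of free and active receptors on viable
  cells; `f_FD`, `f_AD` — the same on damaged cells;
* cumulative decays in blood, on viable-cell receptors and on
  damaged-cell receptors (pmol), and cumulative newborn cells.

Antibodies bind irreversibly to free receptors at rate `k_on`; intact
antibodies clear at rate `kappa_c`, fragments at the faster
`kappa_p`. Viable cells proliferate at rate `rho`; damaged cells stop
proliferating and die at rate `omega`, releasing their bound
antibodies back to plasma as fragments. Radiation damage converts
viable into damaged cells at the rate

```
RD = alpha * ( k_s * lambda*gamma*f_AN/nu
             + (1 - k_s) * lambda*gamma*(f_AN*N + f_AD*D)/(nu*(N + D))
             + k_f * lambda*(a + p) )
```

whose three terms are *self-damage* (decays on a cell's own
receptors), *cross-fire* (decays on neighboring cells' receptors,
averaged over the lesion) and decays of unanchored nuclides in plasma.
The weight `k_s` encodes the emitted particle range relative to cell
packing: short-range emitters in sparse tissue damage mostly the cell
that binds them (`k_s` near 1), long-range emitters in dense tissue
spread their dose (`k_s` near 0).

Units are days, ml, pmol and nM throughout, with cell counts in units
of 1e7 cells, so every default in `trt_parameters()` is usable
verbatim: e.g. `gamma = 2.1` pmol of receptors per 1e7 cells is about
126,000 receptors per cell (`receptors_per_cell(2.1)`), and the lethal
blood-decay amount `A_bl_cr = 0.0175` pmol corresponds to about 230
nCi of 225Ac (`activity_nCi_from_pmol(0.0175)`).

### Assumptions worth keeping in mind

One-step decay (justified for 225Ac, whose half-life dominates its
daughters'); irreversible binding (high-affinity, rapidly internalized
antibodies); a well-mixed plasma/bone-marrow compartment; a
homogeneous cancer-cell population with equal receptor counts and
radiosensitivity; damage proportional to dose and irreparable (the
alpha-particle double-strand-break regime); no therapeutic effect of
the antibody itself; no binding to normal cells. Heterogeneous
radiosensitivity, antibody recycling and organ-level dosimetry are out
of scope.

## Numerical treatment

Injections are instantaneous jumps of `a` and `b` (by `A/V` and
`eta*A/V`): the system is integrated piecewise between injection times
and never sees delta functions. The integrator is `deSolve`'s
stiffness-switching `lsoda`/`lsodar` driving a compiled-C vector
field, with default tolerances `rtol = 1e-8`, `atol = 1e-12` — tight
enough to resolve both the binding phase (rates near 70/day) and
viable-cell minima near the cure threshold of `1e-9` (0.01 cell).

Three numerical choices deserve mention:

* **The damaged-cell receptor equations have an `N/D` transfer term
  that is singular at `D = 0`.** Internally the package integrates the
  absolute receptor pools `uFD = D*f_FD` and `uAD = D*f_AD`, whose
  equations are regular everywhere; fractions are recovered by
  division where `D > 1e-12` and reported at their conventional
  initial values (`f_FD = 1`, `f_AD = 0`) while no damaged cells
  exist. This removes the singularity exactly rather than by an
  epsilon.
* **Extinction.** Once a population is extinct the solver's state can
  dither at the absolute-tolerance floor, including tiny negative
  values that would otherwise grow exponentially through the
  proliferation term. Every state component is clamped to be
  non-negative where it enters the vector field.
* **Terminal events.** The lethal-burden crossing `N + D = C_d` is a
  terminal root by default — past host death the model's unbounded
  regrowth has no meaning. Trials additionally stop at the lethal
  blood-decay crossing. The minimum of `N` is taken on a dense output
  grid (20 points/day by default) and refined with a local spline in
  `log N`.

### Cure, death and censoring

Cell counts are continuous, so "cure" is a threshold convention: a
trajectory whose viable-cell minimum falls below `N_cur` = 0.01 cell
is curative. In trials this threshold is also an *extinction*
declaration: the continuous model will regrow a cancer from 1e-14
cells given a year, and counting such a crossing of `C_d` as a death
would be an artifact, so cured mice are censored alive at the horizon.
A mouse dies when its burden `N + D` reaches `C_d` = 1e11 cells or its
cumulative blood decays reach `A_bl_cr`, whichever comes first. A dose
can be curative and lethally toxic at the same time; dose-search
routines keep integrating past the toxicity threshold for exactly
that reason.

## Closed-form analytics

For a single pure bolus that binds quickly and nearly completely
(injected antibodies well below the binding capacity `gamma*N0`), the
minimal surviving fraction `Nm/N0` has closed forms in
`x = alpha*A/(nu*N0)` (deposited energy per unit cancer mass) and
`r = rho/lambda`:

* cross-fire only: `(x/r)^r * exp(2r - x)`
  (`surviving_fraction_crossfire()`);
* self-damage only: `(x/r)^(r/(1+r)) * exp((r-x)/(1+r))`
  (`surviving_fraction_selfdamage()`).

Both tend to the classical instantaneous-irradiation survival
`exp(-x)` as `rho -> 0`. Self-damage needs more dose because the
nuclide density on viable cells falls as `exp(-(lambda+rho)t)` — decay
plus dilution over newborn cells — whereas cross-fire efficacy falls
only as `exp(-lambda t)`, the slowest possible decline. The tests
check both forms against the ODE within 5% in log-survival in this
validity regime; the agreement degrades for small doses (minimum
reached while binding still matters) exactly as expected.

The toxicity side has a matching decomposition: a nuclide's
probability of decaying in plasma is
`lambda/(lambda + kappa_c + k_on*gamma*N0/V)` while intact, plus
`omega*lambda/((lambda+omega)(lambda+kappa_p))` via the
fragment route (`blood_decay_fraction()`). At the basic parameters
about 97% of blood decays come from fragments. Worst-casing these
branches over the physiologic parameter ranges gives capacity-dependent
*maximal safe doses* (`max_safe_dose()`): about 362 nCi at zero
binding capacity and about 1763 nCi as capacity grows large. Between
the limits the bound part of a dose is the capacity share
`min(1, gamma*N0/((eta+1)A))` — a deliberate simplification that is
exact in both limits, monotone in capacity, and conservative in
ordering (the unbound branch is always the worse one); the in-between
values are bounds, not sharp optima.

## Dose design

`find_minimal_curative_dose()` bisects the monotone-decreasing
`N_min(A)` to the dose where the minimum touches `N_cur` (relative
tolerance 1e-4, cure assessed on a 365-day horizon, bracket expanded
geometrically and divergence — e.g. `k_f = 0` past receptor
saturation — reported rather than silently capped). At the basic
parameters with pure drug this gives about 76 radioconjugates per
initial cell for cross-fire-only and about 272 for self-damage-only
damage, far below the ~126,000 receptors per cell: receptor occupancy
is not the limit, the nuclide-to-antibody ratio is.

`estimate_binding_capacity()` inverts the binding-phase plasma decay
rate `k_obs = lambda + kappa_c + k_on*gamma*N0/V` fitted by ordinary
least squares on log-concentration of a small diagnostic dose. The
default sampling times of `generate_pk_fixture()` span the first hour
after injection: the binding phase (decay scale ~70/day) is well
resolved there, while the receptor pool grown by proliferation is
still within a fraction of a percent of its initial value, keeping the
estimate essentially unbiased; sampling over a tenth of a day would
already bias the capacity upward by about 1.5% at the basic
proliferation rate. The window is configurable.

`personalized_dose()` implements the capacity-keyed rule: inject
`1.5*gamma*N0 + 3` pmol of antibodies (the 3 pmol compensates for slow
binding at small capacity), i.e. an active dose of
`(1.5*gamma*N0 + 3)/(eta+1)`, capped by the worst-case safe dose for
that capacity.

## Virtual populations and trials

`sample_population()` draws each varied parameter (`kappa_c, kappa_p,
gamma, V, rho, omega, alpha, k_f, N0`) independently and log-uniformly
from its physiologic range — the ranges span up to two orders of
magnitude, which makes a uniform draw concentrate on the top decade;
`k_s`, bounded in [0, 1], is drawn uniformly. `lambda_decay`, `k_on`,
`nu` and `eta` stay fixed. The exact sampling law behind the published
391 nCi maximum tolerated dose is not recoverable; log-uniform
sampling reproduces it within a few percent, and the package's own
test asserts that value only loosely (±15%) for the same reason.

`run_trial()` simulates every mouse under a strategy (fixed dose,
capacity-personalized, per-mouse optimized, or a multi-dose schedule
family), with endpoint roots found by the solver and daily survival
and toxicity curves assembled from the outcomes.
`find_max_tolerated_dose()` bisects (0.5 nCi resolution) for the
largest uniform dose with no toxicity-related death, screening mice in
order of increasing binding capacity so failing levels reject early.
`optimize_single_dose_per_mouse()` probes cure feasibility on a dose
grid spanning the mouse's individual toxicity limit — near the limit a
curative dose can still lose the race against blood-decay
accumulation, so probing only the limit would misclassify curable
mice — and returns the smallest curing dose, or the
survival-maximizing dose (grid plus golden-section) when no safe dose
cures.

## Multi-dose schedules

The idealized auxiliary model
(`idealized_saturation_dynamics()`) assumes injected antibodies bind
instantly and hold total receptor occupancy constant; the active
occupancy is then at most `1/(eta+1)` and the anchored-decay kill rate
is the constant `alpha*lambda*gamma/(nu*(eta+1))` regardless of `k_s`.
Long-term curability requires this rate to exceed `rho` — necessary,
not sufficient, because inert antibodies accumulate on receptors
during prolonged treatment. The model also yields the continuous
dosing rate that maintains saturation, which
`discretize_schedule()` converts into boluses conserving total
activity.

Universal schedule families (`schedule_family()`) are parametrized by
a capacity-tailored first dose (`c1*gamma*N0 + c0` pmol of
antibodies), follow-up doses a fraction `c2` of the first at interval
`tau`, `K` doses total; every bolus and the cumulative total respect
the capacity's worst-case safe dose.
`optimize_universal_schedule()` searches a coarse grid over
`(c1, c2, tau, K)` maximizing one-year survival on one `k_s` stratum
of a training population. The `k_s` strata boundaries (0.2 and 0.6)
are a configurable convention. This grid search is a deliberately
simple surrogate for a full schedule optimization: the package asserts
*ordering* properties of its output — multi-dosing never loses to the
one-size-fits-all maximum tolerated dose, the largest survival gain
arises in the high-`k_s` group (receptor saturation redirects later
doses to still-viable, receptor-producing cells), low-`k_s` schedules
prefer longer intervals, and optimized families carry over to an
independent test population — rather than any particular optimum.

## What the synthetic data do and do not show

All inputs are synthetic: virtual mice are parameter draws, and
diagnostic PK curves are model trajectories with multiplicative
log-normal noise. Passing tests therefore demonstrate internal
consistency of the model, its closed forms and its optimization
machinery under the published parameter ranges — not fit to any
animal. Real data would add inter-cell heterogeneity (radiosensitivity
falling with dose), antibody recycling receptors competing for drug,
correlated parameters, and measurement schedules constrained by blood
sampling, none of which the generator emulates.

## Problem sizes and reproducibility

The test suite and the acceptance script use populations of 150–1000
mice, 200-draw curative-dose sweeps, and schedule grids of a few dozen
candidates; these sizes give Monte-Carlo errors of a few percent on
survival fractions, matching the assertion slacks used. Every
stochastic path is seeded, and seeded routines restore the caller's
RNG state. `scripts/acceptance.R --seed S --out f.json` recomputes the
headline quantities from scratch; only the virtual-population draw
depends on the seed.

## Known limitations

Homogeneous cancer-cell population (the model's own fitting heritage
suggests radiosensitivity heterogeneity matters); single-nuclide
one-step decay; no organ dosimetry beyond the blood-decay budget; the
between-limits safe-dose interpolation is a bound, not a sharp
constraint; the schedule optimizer is a coarse grid, so its optima are
family-level, not schedule-level; and the 391 nCi-class population
figures inherit the uncertainty of the sampling law noted above.
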