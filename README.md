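# microturn

Spatial birth-death modelling of microglial population turnover.

Microglia — the brain's resident immune cells — maintain a near-constant
density throughout adult life, yet chronic in vivo imaging shows the
population is anything but static: cells divide at ~0.79% per day and die at
~1.23% per day (resident) / ~2.40% per day (newly born), with proliferation
spatially (≤200 µm) and temporally (days) coupled to cell death.
`microturn` is for quantitative biologists who want to simulate and analyse
that regime:

* **`synthetic population`** — a daily-resolution spatial birth–death
  simulator of a tissue-resident population (9 fields of view of
  317 × 317 × 160 µm with ~74 cells each by default), with an optional
  *local replacement* coupling mode in which each death transiently boosts
  the division propensity of its nearest neighbours, calibrated so expected
  births equal expected deaths; plus pulse labeling and an
  apoptosis-blocked (Bcl2-like) crowding scenario.
* **`pulse-chase kinetics`** — closed forms linking a labeling index to the
  cycling fraction (`F = index / s`), cell-cycle length (`Tc = onset / s`),
  whole-population renewal time (`X = 100·Tc/F`), lifetime renewal cycles,
  and apoptotic depletion times.
* **`longitudinal tracking stats`** — per-day proliferation/death rate
  estimators on cell-days at risk with resident/newborn strata, twin-pair
  dispersion profiles and nearest-neighbour spacing.
* **`spatiotemporal coupling`** — before/during/after vicinity fractions
  around each death, nearest-proliferating vs nearest-resident distances
  with neighbour ranks, a day-shuffle permutation null, and an exact
  Wilcoxon signed-rank test.
* **`pipeline`** — a `microturn_cli()` command-line interface
  (`simulate | pulse-chase | rates | coupling | reproduce | recover`) and a
  self-contained reproduction suite.

## Worked example

The renewal-time algebra, from a 0.69% labeling index and a 16-hr doubling
onset:

```r
library(microturn)
est <- renewal_time(estimate_cycle_length(16, 0.5),
                    as.numeric(cycling_fraction(0.69, 0.5)))
est
#> <kinetic_estimates> Tc = 32 hr, F = 1.38%
#>   renewal time X = 2318.84 hr (trunc 2318 hr, ~96 days)
renewal_cycles(21, est$renewal_time_hr_trunc)
#> [1] 6
```

A population of cells in a cycle of length *Tc* = 32 hr with *F* = 1.38% of
cells cycling renews itself once every 2,318 hr (~96 days) — about 6
complete renewals in a 21-month lifespan.

A coupled simulation and its analysis:

```r
cfg <- simulation_config(coupling_mode = "local_replacement", seed = 2)
snaps <- render_snapshots(simulate_population(cfg))

proliferation_rate(snaps)
#> <rate_estimate> divided events, stratum 'all'
#>   pooled 1.508 %/day; median 1.424 (IQR 1.337-1.636) across 9 FOVs
#>   211 events / 13988 cell-days (1074 cells)
death_rate(snaps, "newborn")
#> <rate_estimate> died events, stratum 'newborn'
#>   pooled 2.545 %/day; median 2.236 (IQR 2.119-2.769) across 9 FOVs
#>   68 events / 2672 cell-days (408 cells)

an <- coupling_analysis(snaps, coupling_config(seed = 2))
an$temporal
#> <temporal_coupling> 1247 vicinity events: before 40.2%, during 12.9%, after 46.9% (asymmetry 0.077)
an$distances
#> <coupling_result> 219 deaths (219 with a division in window)
#>   nearest proliferating: median 63.87 um (IQR 42.15-94.67)
#>   nearest resident:      median 29.96 um (IQR 20.16-41.07)
#>   median neighbor rank of nearest division: 4.0
#>   paired signed-rank: W+ = 16106, p = 5.8e-30 (normal approximation, n = 180)
an$permutation
#> <permutation_null> observed asymmetry 0.077, p = 0.001998 (1000 permutations)
```

In coupled mode the division rate rises above the 0.79%/day base (deaths
trigger replacement divisions, balancing the ~1.5%/day overall death rate),
proliferation in a dying cell's vicinity is enriched *after* the death
(46.9% vs 40.2%; permutation p ≈ 0.002), and the nearest proliferating cell
sits about twice as far away as the nearest resident cell. In `"uncoupled"`
mode the estimators recover the generating hazards themselves:
`run_recovery_suite(simulation_config(), n_seeds = 24, seed = 1)` returns
means 0.81 / 1.23 / 2.44 %/day against expectations 0.79 / 1.23 / 2.40,
each within two Monte-Carlo standard errors.

From the command line:

```sh
Rscript -e 'microturn::microturn_cli(commandArgs(TRUE))' simulate --seed 1 --out snapshots.csv
Rscript -e 'microturn::microturn_cli(commandArgs(TRUE))' rates --in snapshots.csv --out rates.json --format json
Rscript -e 'microturn::microturn_cli(commandArgs(TRUE))' reproduce
```

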