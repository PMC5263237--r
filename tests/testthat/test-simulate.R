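test_that("zero hazards give a frozen population with no events", {
  cfg <- simulation_config(n_fov = 2, initial_cells_per_fov = 30,
                           division_hazard = 0, resident_death_hazard = 0,
                           newborn_death_hazard = 0, n_days = 10, seed = 5)
  snaps <- render_snapshots(simulate_population(cfg))
  expect_true(all(snaps$event == "none"))
  expect_equal(nrow(snaps), 2 * 30 * 10)
  n_by_day <- table(snaps$day)
  expect_true(all(n_by_day == 60))
})

test_that("structural invariants hold on a busy simulation", {
  cfg <- simulation_config(n_fov = 2, division_hazard = 0.05,
                           resident_death_hazard = 0.03, n_days = 12, seed = 21)
  sim <- simulate_population(cfg)
  for (ts in sim) {
    s <- ts$snapshots
    expect_equal(sum(s$day == 0), cfg$initial_cells_per_fov)
    expect_false(any(duplicated(paste(s$day, s$cell_id))))
    dims <- cfg$volume_dims
    expect_true(all(s$x_um >= 0 & s$x_um <= dims[1]))
    expect_true(all(s$y_um >= 0 & s$y_um <= dims[2]))
    expect_true(all(s$z_um >= 0 & s$z_um <= dims[3]))
    tracks <- as_cell_tracks(ts)
    # every division yields exactly two tracks sharing the mother's id
    kids <- table(vapply(tracks, function(tr) tr$parent_id, 0L)[
      !is.na(vapply(tracks, function(tr) tr$parent_id, 0L))])
    expect_true(all(kids == 2))
    div_ids <- s$cell_id[s$event == "divided"]
    expect_setequal(as.integer(names(kids)), div_ids)
    for (tr in tracks) {
      # a daughter can die on its very first transition, in which case the
      # died flag sits on its birth-day row: death_day >= birth_day
      if (!is.na(tr$birth_day) && !is.na(tr$death_day))
        expect_gte(tr$death_day, tr$birth_day)
      obs_days <- as.integer(rownames(tr$positions))
      expect_equal(obs_days, seq(min(obs_days), max(obs_days)))
    }
    # daughters start adjacent: first-day twin separation below the offset cap
    td <- twin_dispersion(ts)
    if (length(td$twin_age0_distances))
      expect_true(all(td$twin_age0_distances <= 2 * cfg$daughter_offset + 1e-9))
  }
})

test_that("pure-birth growth matches the analytic expectation", {
  p <- 0.01
  cfg <- simulation_config(n_fov = 1, initial_cells_per_fov = 74,
                           division_hazard = p, resident_death_hazard = 0,
                           newborn_death_hazard = 0, n_days = 15)
  sizes <- sapply(1:80, function(s) {
    cfg$seed <- s
    population_size(simulate_population(cfg))$n
  })
  mean_n <- rowMeans(sizes)
  expected <- 74 * (1 + p)^(0:14)
  se <- apply(sizes, 1, sd) / sqrt(ncol(sizes))
  expect_true(all(abs(mean_n - expected) <= pmax(3 * se, 1e-9)))
})

test_that("event counts match exhaustive per-cell Bernoulli enumeration", {
  # 10 cells, first transition: per-cell outcome is multinomial
  # (die .15, divide .20, none .65); division and death counts must follow
  # the binomial laws that exhaustive enumeration of outcomes yields.
  p_div <- 0.20; p_die <- 0.15; n_cells <- 10
  cfg <- simulation_config(n_fov = 1, initial_cells_per_fov = n_cells,
                           division_hazard = p_div,
                           resident_death_hazard = p_die,
                           newborn_death_hazard = p_die, n_days = 3)
  n_rep <- 2500
  counts <- t(sapply(1:n_rep, function(s) {
    cfg$seed <- s
    s0 <- simulate_population(cfg)[[1]]$snapshots
    c(div = sum(s0$event == "divided" & s0$day == 0),
      die = sum(s0$event == "died" & s0$day == 0))
  }))
  for (what in c("div", "die")) {
    p <- if (what == "div") p_div else p_die
    obs <- tabulate(counts[, what] + 1L, nbins = n_cells + 1L)
    expected <- dbinom(0:n_cells, n_cells, p) * n_rep
    # pool tail bins so expected counts stay >= ~5
    cut <- max(which(expected >= 5))
    obs_p <- c(obs[1:cut], sum(obs[-(1:cut)]))
    exp_p <- c(expected[1:cut], sum(expected[-(1:cut)]))
    chi2 <- sum((obs_p - exp_p)^2 / exp_p)
    expect_gt(pchisq(chi2, df = length(obs_p) - 1, lower.tail = FALSE), 0.01)
  }
})

test_that("coupled defaults conserve population size (steady state)", {
  # spec-level property at 500 seeds; run 300 for the test budget (the
  # criterion, mean terminal/initial within 5%, is unchanged)
  cfg <- simulation_config(coupling_mode = "local_replacement", n_fov = 3)
  ratios <- sapply(1:300, function(s) {
    cfg$seed <- s
    ps <- population_size(simulate_population(cfg))
    mean(ps$n[ps$day == max(ps$day)]) / mean(ps$n[ps$day == 0])
  })
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("apoptosis-blocked scenario rises then plateaus; controls stay flat", {
  base <- simulation_config(n_fov = 2, crowding_capacity = 1.3, n_days = 150)
  traj <- sapply(1:20, function(s) {
    cfg <- base; cfg$seed <- s
    ps <- population_size(simulate_apoptosis_blocked(cfg))
    tapply(ps$n, ps$day, mean)
  })
  mean_traj <- rowMeans(traj) / base$initial_cells_per_fov
  terminal <- mean_traj[length(mean_traj)]
  expect_gt(terminal, 1.10)            # increase of at least 10%
  expect_lte(terminal, 1.3 + 0.02)     # bounded by capacity
  last5 <- tail(mean_traj, 5)
  slope <- coef(lm(last5 ~ seq_along(last5)))[2]
  expect_lt(abs(slope), 0.002)         # plateau: < 0.2% of baseline per day
  # capacity 1.0: division fully suppressed, density stays at baseline
  cfg1 <- simulation_config(n_fov = 1, crowding_capacity = 1, n_days = 30,
                            seed = 2)
  ps1 <- population_size(simulate_apoptosis_blocked(cfg1))
  expect_true(all(ps1$n == cfg1$initial_cells_per_fov))
  # death hazards restored: no rise above baseline
  cfg2 <- simulation_config(n_fov = 3, crowding_capacity = 1.3, n_days = 60,
                            seed = 4)
  ps2 <- population_size(simulate_apoptosis_blocked(cfg2, block_death = FALSE))
  terminal2 <- mean(ps2$n[ps2$day == max(ps2$day)]) / cfg2$initial_cells_per_fov
  expect_lt(terminal2, 1.03)
  expect_error(simulate_apoptosis_blocked(simulation_config()),
               "crowding_capacity")
})
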