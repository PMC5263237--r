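#' Simulation configuration
#'
#' Builds and validates the parameter set for the spatial birth-death
#' simulator. Defaults describe the imaged system the package emulates: a
#' 317 x 317 x 160 um field of view (FOV) holding ~74 microglia, imaged daily
#' for 22 days across 9 FOVs, with a per-day division probability of 0.0079,
#' a resident per-day death probability of 0.0123 and an elevated death
#' probability of 0.024/day for newly born cells during their first
#' `newborn_window` days.
#'
#' @param volume_dims numeric length-3, FOV edge lengths in um.
#' @param n_fov number of fields of view to simulate.
#' @param initial_cells_per_fov cells present at day 0 in each FOV.
#' @param division_hazard per-cell per-day division probability.
#' @param resident_death_hazard per-cell per-day death probability for cells
#'   present at day 0 (and for born cells once older than `newborn_window`).
#' @param newborn_death_hazard per-cell per-day death probability applied to
#'   cells born during the observation window while their age is below
#'   `newborn_window` (used when `newborn_hazard_shape = "flat"`).
#' @param newborn_hazard_shape `"flat"` applies `newborn_death_hazard` for the
#'   whole newborn window; `"early5"` applies 0.05/day for the first 5 days of
#'   life and the resident hazard thereafter.
#' @param newborn_window days after birth during which the newborn hazard (and
#'   the newborn rate stratum) applies.
#' @param coupling_mode `"uncoupled"` or `"local_replacement"`. In the latter,
#'   every death deposits a transient division-propensity boost on its nearest
#'   neighbours, calibrated each day so expected births equal expected deaths.
#' @param coupling_radius um; boost recipients must lie within this radius of
#'   the death site.
#' @param coupling_lag days over which a death's boost remains active.
#' @param coupling_knn number of nearest cells (within the radius) sharing a
#'   death's boost; `Inf` shares it over every cell in the radius.
#' @param coupling_strength multiplier on the balance-calibrated boost
#'   (1 = steady density; used for sensitivity sweeps).
#' @param dispersion_step um per day moved by newly born cells during their
#'   random-walk dispersal phase.
#' @param dispersal_days days after birth during which daughters random-walk.
#' @param daughter_offset um; each daughter is placed at the mother's position
#'   plus an offset of this length in a random direction.
#' @param crowding_capacity max density ratio (relative to day 0) for the
#'   apoptosis-blocked scenario; `NA` unless that scenario is used.
#' @param apoptotic_clearance_min minutes a dying cell remains visible. At the
#'   daily sampling interval dying cells are simply absent from the next
#'   snapshot; the value is carried for depletion-time calculations.
#' @param population_label optional label flag (e.g. `"monocyte"`) applied to
#'   all initial cells.
#' @param n_days number of daily snapshots (days 0 .. n_days - 1).
#' @param seed integer seed; all simulator randomness flows from it.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_population()], [monocyte_wave_config()]
#' @export
simulation_config <- function(volume_dims = c(317, 317, 160),
                              n_fov = 9,
                              initial_cells_per_fov = 74,
                              division_hazard = 0.0079,
                              resident_death_hazard = 0.0123,
                              newborn_death_hazard = 0.024,
                              newborn_hazard_shape = c("flat", "early5"),
                              newborn_window = 10,
                              coupling_mode = c("uncoupled", "local_replacement"),
                              coupling_radius = 200,
                              coupling_lag = 1,
                              coupling_knn = 2,
                              coupling_strength = 1,
                              dispersion_step = 15,
                              dispersal_days = 4,
                              daughter_offset = 5,
                              crowding_capacity = NA_real_,
                              apoptotic_clearance_min = 80,
                              population_label = NULL,
                              n_days = 22,
                              seed = 1L) {
  cfg <- list(
    volume_dims = as.numeric(volume_dims),
    n_fov = as.integer(n_fov),
    initial_cells_per_fov = as.integer(initial_cells_per_fov),
    division_hazard = division_hazard,
    resident_death_hazard = resident_death_hazard,
    newborn_death_hazard = newborn_death_hazard,
    newborn_hazard_shape = match.arg(newborn_hazard_shape),
    newborn_window = as.integer(newborn_window),
    coupling_mode = match.arg(coupling_mode),
    coupling_radius = coupling_radius,
    coupling_lag = as.integer(coupling_lag),
    coupling_knn = coupling_knn,
    coupling_strength = coupling_strength,
    dispersion_step = dispersion_step,
    dispersal_days = as.integer(dispersal_days),
    daughter_offset = daughter_offset,
    crowding_capacity = crowding_capacity,
    apoptotic_clearance_min = apoptotic_clearance_min,
    population_label = population_label,
    n_days = as.integer(n_days),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param config a `sim_config` list.
#' @return `config`, invisibly, or an error describing the offending fields.
#' @export
validate_config <- function(config) {
  bad <- character(0)
  hz <- c("division_hazard", "resident_death_hazard", "newborn_death_hazard")
  for (h in hz) {
    v <- config[[h]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      bad <- c(bad, sprintf("%s must be a finite probability in [0, 1]", h))
  }
  if (length(config$volume_dims) != 3L || any(!is.finite(config$volume_dims)) ||
      any(config$volume_dims <= 0))
    bad <- c(bad, "volume_dims must be 3 strictly positive lengths (um)")
  if (!is.finite(config$coupling_radius) || config$coupling_radius <= 0)
    bad <- c(bad, "coupling_radius must be > 0")
  if (is.na(config$n_days) || config$n_days < 2L)
    bad <- c(bad, "n_days must be >= 2")
  if (is.na(config$coupling_lag) || config$coupling_lag < 1L)
    bad <- c(bad, "coupling_lag must be >= 1")
  if (!is.numeric(config$coupling_knn) || config$coupling_knn < 1)
    bad <- c(bad, "coupling_knn must be >= 1")
  if (config$n_fov < 1L || config$initial_cells_per_fov < 1L)
    bad <- c(bad, "n_fov and initial_cells_per_fov must be >= 1")
  if (!is.finite(config$dispersion_step) || config$dispersion_step < 0)
    bad <- c(bad, "dispersion_step must be >= 0")
  if (!is.na(config$crowding_capacity) && config$crowding_capacity < 1)
    bad <- c(bad, "crowding_capacity must be >= 1")
  if (length(bad))
    stop("invalid simulation configuration:\n  - ",
         paste(bad, collapse = "\n  - "), call. = FALSE)
  invisible(config)
}

#' Configuration preset for the perinatal monocyte wave
#'
#' A non-proliferating labeled population undergoing rapid constant apoptosis,
#' mirroring the infiltrated-monocyte wave cleared over roughly 2-3 days. The
#' death hazard is set so that the instantaneous apoptotic fraction (hazard
#' times the 80-min clearance interval) is ~3.2% of the population, the value
#' used by [depletion_time()].
#'
#' @param apoptotic_fraction_pct target instantaneous apoptotic fraction (%).
#' @param ... further overrides passed to [simulation_config()].
#' @return A `sim_config`.
#' @export
monocyte_wave_config <- function(apoptotic_fraction_pct = 3.17, ...) {
  clearance_days <- 80 / (24 * 60)
  hz <- min(1, (apoptotic_fraction_pct / 100) / clearance_days)
  simulation_config(division_hazard = 0,
                    resident_death_hazard = hz,
                    newborn_death_hazard = 0,
                    population_label = "monocyte",
                    n_days = 7,
                    n_fov = 3,
                    ...)
}

#' Read / write a simulation configuration as JSON
#'
#' The file is a flat JSON object whose keys mirror [simulation_config()]
#' field names exactly.
#'
#' @param path file path.
#' @return `read_config()` returns a validated `sim_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(simulation_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  raw <- raw[!vapply(raw, is.null, logical(1))] # nulls fall back to defaults
  if (!is.null(raw$population_label) && !nzchar(raw$population_label[1]))
    raw$population_label <- NULL
  do.call(simulation_config, raw)
}

#' @rdname read_config
#' @param config a `sim_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (is.null(x$population_label)) x$population_label <- ""
  x <- x[!vapply(x, function(v) length(v) == 1L && is.na(v), logical(1))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d FOV(s) of %s um, %d cells each, %d daily snapshots\n",
              x$n_fov, paste(x$volume_dims, collapse = " x "),
              x$initial_cells_per_fov, x$n_days))
  cat(sprintf("  hazards/day: division %.4f, resident death %.4f, newborn death %.4f (%s, %d-day window)\n",
              x$division_hazard, x$resident_death_hazard,
              x$newborn_death_hazard, x$newborn_hazard_shape, x$newborn_window))
  cat(sprintf("  coupling: %s (radius %g um, lag %d d, knn %s, strength %g)\n",
              x$coupling_mode, x$coupling_radius, x$coupling_lag,
              format(x$coupling_knn), x$coupling_strength))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
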