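# Closed-form pulse-chase labeling kinetics.
#
# Core identities (percent scale throughout):
#   F  = labeling index / S-fraction          (cycling fraction, %)
#   Tc = doubling onset / S-fraction          (cell-cycle length, hr)
#   X  = 100 * Tc / F                         (whole-population renewal, hr)
#   depletion = clearance / apoptotic fraction (linear removal)
# Printed reference values are truncations of the raw quotients; every
# function returns the raw value and, where relevant, the truncated one.

#' Cycling fraction from a labeling index
#'
#' A single label pulse marks only cells in S phase; if S occupies
#' `s_fraction` of the cycle, the fraction of cells in cycle is the labeling
#' index divided by `s_fraction`.
#'
#' @param labeling_index percent of cells label-positive right after a pulse.
#' @param s_fraction fraction of the cell cycle spent in S phase, in (0, 1].
#' @return Percent of cells in cycle, capped at 100 (with a warning and a
#'   `capped` attribute when the cap binds).
#' @examples
#' cycling_fraction(0.69, 0.5) # 1.38
#' @export
cycling_fraction <- function(labeling_index, s_fraction = 0.5) {
  if (!is.finite(s_fraction) || s_fraction <= 0 || s_fraction > 1)
    stop("s_fraction must lie in (0, 1]", call. = FALSE)
  if (any(!is.finite(labeling_index)) || any(labeling_index < 0) ||
      any(labeling_index > 100))
    stop("labeling_index must lie in [0, 100]", call. = FALSE)
  out <- labeling_index / s_fraction
  capped <- out > 100
  if (any(capped)) {
    warning("cycling fraction capped at 100%", call. = FALSE)
    out[capped] <- 100
  }
  attr(out, "capped") <- any(capped)
  out
}

#' Cell-cycle length from the pulse-to-doubling interval
#'
#' The time from pulse to the doubling of the labeled population reads out the
#' S-phase duration (G2/M lasts only a few hours and is ignored, a small
#' downward bias); dividing by the S-phase fraction gives the cycle length.
#'
#' @param doubling_onset_hr hours from pulse to doubling of the labeled pool.
#' @param s_fraction S-phase fraction of the cycle, in (0, 1].
#' @return Cell-cycle length Tc in hours.
#' @examples
#' estimate_cycle_length(16, 0.5) # 32
#' @export
estimate_cycle_length <- function(doubling_onset_hr, s_fraction = 0.5) {
  if (!is.finite(s_fraction) || s_fraction <= 0 || s_fraction > 1)
    stop("s_fraction must lie in (0, 1]", call. = FALSE)
  if (!is.finite(doubling_onset_hr) || doubling_onset_hr <= 0)
    stop("doubling_onset_hr must be > 0", call. = FALSE)
  doubling_onset_hr / s_fraction
}

#' Pulse-chase curve container
#'
#' @param times_hr hours post pulse, strictly increasing.
#' @param labeled_fraction_pct labeled percent of the population at each time.
#' @param region free-text region tag.
#' @param n_animals number of animals (or simulated FOVs) pooled.
#' @return A `pulse_chase_curve` (data.frame with attributes).
#' @export
pulse_chase_curve <- function(times_hr, labeled_fraction_pct,
                              region = "", n_animals = NA_integer_) {
  if (length(times_hr) != length(labeled_fraction_pct))
    stop("times and fractions must have equal length", call. = FALSE)
  if (length(times_hr) && any(diff(times_hr) <= 0))
    stop("times_hr must be strictly increasing", call. = FALSE)
  if (any(labeled_fraction_pct < 0 | labeled_fraction_pct > 100, na.rm = TRUE))
    stop("labeled_fraction_pct must lie in [0, 100]", call. = FALSE)
  structure(data.frame(time_hr = times_hr,
                       labeled_fraction_pct = labeled_fraction_pct),
            region = region, n_animals = n_animals,
            class = c("pulse_chase_curve", "data.frame"))
}

#' Read / write a pulse-chase curve CSV
#'
#' Dialect: header `time_hr,labeled_fraction_pct,region`.
#'
#' @param path file path.
#' @param curve a [pulse_chase_curve()].
#' @return `read_pulse_chase()` returns a `pulse_chase_curve`;
#'   `write_pulse_chase()` returns `path` invisibly.
#' @export
read_pulse_chase <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_hr", "labeled_fraction_pct")
  if (!all(need %in% names(df)))
    stop("pulse-chase file needs columns time_hr, labeled_fraction_pct",
         call. = FALSE)
  region <- if ("region" %in% names(df) && nrow(df)) df$region[1] else ""
  pulse_chase_curve(df$time_hr, df$labeled_fraction_pct, region = region)
}

#' @rdname read_pulse_chase
#' @export
write_pulse_chase <- function(curve, path) {
  df <- data.frame(time_hr = curve$time_hr,
                   labeled_fraction_pct = curve$labeled_fraction_pct,
                   region = attr(curve, "region"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detect the doubling onset of a pulse-chase curve
#'
#' Earliest sampled time at which the labeled fraction reaches
#' `(2 - tolerance)` times the first time point (no interpolation - onset is
#' read directly off the sampling grid), plus the earliest later time at which
#' the curve is back within `tolerance` of the initial value.
#'
#' @param curve a [pulse_chase_curve()] with at least 2 time points.
#' @param tolerance relative tolerance (default 0.05).
#' @return List with `onset_hr` and `baseline_return_hr` (`NA` if never
#'   reached).
#' @export
detect_doubling_onset <- function(curve, tolerance = 0.05) {
  if (nrow(curve) < 2L)
    stop("need at least two time points", call. = FALSE)
  base <- curve$labeled_fraction_pct[1]
  t <- curve$time_hr
  hit <- which(curve$labeled_fraction_pct >= (2 - tolerance) * base &
                 seq_len(nrow(curve)) > 1L)
  onset <- if (length(hit)) t[hit[1]] else NA_real_
  ret <- NA_real_
  if (!is.na(onset)) {
    later <- which(t > onset &
                     abs(curve$labeled_fraction_pct - base) <= tolerance * base)
    if (length(later)) ret <- t[later[1]]
  }
  list(onset_hr = onset, baseline_return_hr = ret)
}

#' Whole-population renewal time
#'
#' Renewal time `X = 100 * Tc / F`: with `F` percent of cells in a cycle of
#' length `Tc`, the whole population turns over once every `X` hours. Printed
#' reference values truncate the raw quotient to whole hours and whole days.
#'
#' @param cycle_length_hr cell-cycle length Tc (hours), > 0.
#' @param cycling_fraction percent of cells in cycle F, > 0.
#' @return A `kinetic_estimates` list: `cycle_length_hr`, `cycling_fraction`,
#'   `renewal_time_hr` (raw), `renewal_time_hr_trunc`, `renewal_time_days`
#'   (raw), `renewal_time_days_trunc`.
#' @examples
#' renewal_time(32, 1.38)$renewal_time_hr_trunc # 2318
#' @export
renewal_time <- function(cycle_length_hr, cycling_fraction) {
  if (!is.finite(cycle_length_hr) || cycle_length_hr <= 0)
    stop("cycle_length_hr must be > 0", call. = FALSE)
  if (!is.finite(cycling_fraction) || cycling_fraction <= 0)
    stop("cycling_fraction must be > 0 (population never renews)",
         call. = FALSE)
  x_hr <- 100 * cycle_length_hr / cycling_fraction
  hr_trunc <- trunc(x_hr)
  structure(list(cycle_length_hr = cycle_length_hr,
                 cycling_fraction = cycling_fraction,
                 renewal_time_hr = x_hr,
                 renewal_time_hr_trunc = hr_trunc,
                 renewal_time_days = x_hr / 24,
                 renewal_time_days_trunc = trunc(hr_trunc / 24)),
            class = "kinetic_estimates")
}

#' @export
print.kinetic_estimates <- function(x, ...) {
  cat(sprintf("<kinetic_estimates> Tc = %g hr, F = %g%%\n",
              x$cycle_length_hr, x$cycling_fraction))
  cat(sprintf("  renewal time X = %.2f hr (trunc %d hr, ~%d days)\n",
              x$renewal_time_hr, x$renewal_time_hr_trunc,
              x$renewal_time_days_trunc))
  invisible(x)
}

#' Lifetime renewal cycles
#'
#' Number of complete population renewals fitting into a lifespan.
#'
#' @param lifespan_months lifespan in months, > 0.
#' @param renewal_time_hr renewal time X in hours, > 0.
#' @param days_per_month days per month (default 30.44, the mean Gregorian
#'   month).
#' @return Integer `floor(lifespan_hours / renewal_time_hr)`.
#' @examples
#' renewal_cycles(21, 2318) # 6
#' @export
renewal_cycles <- function(lifespan_months, renewal_time_hr,
                           days_per_month = 30.44) {
  stopifnot(lifespan_months > 0, renewal_time_hr > 0, days_per_month > 0)
  floor(lifespan_months * days_per_month * 24 / renewal_time_hr)
}

#' Apoptotic depletion time
#'
#' Time for a population to be fully removed when `apoptotic_fraction`
#' percent of cells are apoptotic at any instant and each apoptotic cell is
#' cleared in `clearance_min` minutes. The linear form (constant absolute
#' removal flux) matches the arithmetic behind the 42-72 hr monocyte-wave
#' estimate; an exponential-decay variant (`model = "exponential"`, time for
#' the population to fall below 1%) is provided for comparison only.
#'
#' @param clearance_min minutes an apoptotic cell remains visible, > 0.
#' @param apoptotic_fraction percent of the population apoptotic, > 0.
#' @param model `"linear"` (default) or `"exponential"`.
#' @return A `depletion_estimate` list: `clearance_min`, `apoptotic_fraction`,
#'   `depletion_hr` (raw), `depletion_hr_trunc`, `model`.
#' @examples
#' depletion_time(80, 3.17)$depletion_hr_trunc # 42
#' depletion_time(80, 1.83)$depletion_hr_trunc # 72
#' @export
depletion_time <- function(clearance_min, apoptotic_fraction,
                           model = c("linear", "exponential")) {
  model <- match.arg(model)
  if (!is.finite(clearance_min) || clearance_min <= 0)
    stop("clearance_min must be > 0", call. = FALSE)
  if (!is.finite(apoptotic_fraction) || apoptotic_fraction <= 0)
    stop("apoptotic_fraction must be > 0", call. = FALSE)
  hr <- clearance_min / (apoptotic_fraction / 100) / 60
  if (model == "exponential") hr <- hr * log(100) # time to < 1% remaining
  structure(list(clearance_min = clearance_min,
                 apoptotic_fraction = apoptotic_fraction,
                 depletion_hr = hr,
                 depletion_hr_trunc = trunc(hr),
                 model = model),
            class = "depletion_estimate")
}

#' @export
print.depletion_estimate <- function(x, ...) {
  cat(sprintf("<depletion_estimate> %.1f min clearance, %.2f%% apoptotic -> %.2f hr (%s)\n",
              x$clearance_min, x$apoptotic_fraction, x$depletion_hr, x$model))
  invisible(x)
}

#' Convert a Ki67 index to a BrdU-equivalent labeling index
#'
#' Ki67 marks all cycle phases except G0 and labels roughly twice the
#' fraction that a single S-phase pulse does.
#'
#' @param ki67_index percent Ki67-positive, in [0, 100].
#' @return Equivalent S-phase (pulse) labeling index, percent.
#' @export
ki67_to_brdu_index <- function(ki67_index) {
  if (any(ki67_index < 0 | ki67_index > 100))
    stop("ki67_index must lie in [0, 100]", call. = FALSE)
  ki67_index / 2
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Ratio of proliferation rates between two groups or species
#'
#' @param rate_a,rate_b rates on the same scale; `rate_b > 0`.
#' @param decimals decimal places for half-up rounding of the ratio.
#' @return `rate_a / rate_b` rounded half-up.
#' @examples
#' species_rate_ratio(2.0, 0.69, 1) # 2.9
#' @export
species_rate_ratio <- function(rate_a, rate_b, decimals = 1) {
  if (!is.finite(rate_b) || rate_b <= 0)
    stop("rate_b must be > 0", call. = FALSE)
  round_half_up(rate_a / rate_b, decimals)
}

#' Unit converters
#'
#' Space is um, snapshots are days, cell-cycle quantities are hours and
#' clearance is minutes; these converters make the unit changes explicit.
#'
#' @param x numeric.
#' @return Converted numeric.
#' @name unit_converters
NULL

#' @rdname unit_converters
#' @export
hours_to_days <- function(x) x / 24

#' @rdname unit_converters
#' @export
days_to_hours <- function(x) x * 24

#' @rdname unit_converters
#' @export
minutes_to_hours <- function(x) x / 60
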