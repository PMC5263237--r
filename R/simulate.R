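# Spatial birth-death simulator at daily resolution.
#
# Convention: an event is flagged on a cell's LAST observed day. A cell whose
# day-t row carries "died" is absent from day t+1 onward (apoptotic clearance,
# ~80 min, is far below the 1-day sampling interval). A cell whose day-t row
# carries "divided" is replaced at day t+1 by two daughters flagged
# "appeared"; each daughter starts at the mother's position plus a
# `daughter_offset` um offset in a random direction, then random-walks
# `dispersion_step` um/day for `dispersal_days` days. Resident cells are
# static, matching the relatively immobile network seen in chronic imaging.

random_unit_rows <- function(n) {
  v <- matrix(stats::rnorm(3L * n), nrow = n, ncol = 3L)
  nr <- sqrt(rowSums(v^2))
  nr[nr == 0] <- 1
  v / nr
}

reflect_into <- function(pos, dims) {
  for (j in 1:3) {
    L <- dims[j]
    x <- pos[, j] %% (2 * L)
    over <- x > L
    x[over] <- 2 * L - x[over]
    pos[, j] <- x
  }
  pos
}

death_hazard_vec <- function(config, age) {
  n <- length(age)
  h <- rep(config$resident_death_hazard, n)
  nb <- !is.na(age) & age < config$newborn_window
  if (config$newborn_hazard_shape == "flat") {
    h[nb] <- config$newborn_death_hazard
  } else { # early5: elevated hazard only for the first 5 days of life
    h[nb & age < 5] <- 0.05
  }
  h
}

# Division-propensity boosts deposited by recent deaths (local replacement).
# Each active deposit spreads `daily` probability mass over the coupling_knn
# nearest live cells within coupling_radius of the death site.
boost_from_deposits <- function(deposits, t, pos, config) {
  boost <- numeric(nrow(pos))
  lo <- t - config$coupling_lag
  for (dy in lo:(t - 1L)) {
    dep <- deposits[[as.character(dy)]]
    if (is.null(dep)) next
    for (s in seq_len(nrow(dep$sites))) {
      d2 <- (pos[, 1] - dep$sites[s, 1])^2 +
            (pos[, 2] - dep$sites[s, 2])^2 +
            (pos[, 3] - dep$sites[s, 3])^2
      inr <- which(d2 <= config$coupling_radius^2)
      if (!length(inr)) inr <- seq_len(nrow(pos)) # no cell in radius: spread FOV-wide
      k <- min(config$coupling_knn, length(inr))
      nearest <- inr[order(d2[inr])[seq_len(k)]]
      boost[nearest] <- boost[nearest] + dep$daily / k
    }
  }
  boost
}

join_label <- function(labels, flag) {
  ifelse(nzchar(labels), paste(labels, flag, sep = ";"), flag)
}

simulate_fov <- function(config, fov_id, crowding = FALSE, block_death = TRUE) {
  dims <- config$volume_dims
  nd <- config$n_days
  n0 <- config$initial_cells_per_fov
  d_hz <- config$division_hazard

  id <- seq_len(n0)
  parent <- rep(NA_integer_, n0)
  birth <- rep(NA_integer_, n0)
  pos <- cbind(stats::runif(n0) * dims[1],
               stats::runif(n0) * dims[2],
               stats::runif(n0) * dims[3])
  labels <- rep(if (is.null(config$population_label)) "" else
                  config$population_label, n0)
  next_id <- n0 + 1L

  deposits <- list()
  acc <- vector("list", nd)
  extinct <- FALSE

  for (t in 0:(nd - 1L)) {
    n <- length(id)
    if (n == 0L) { extinct <- TRUE; break }
    ev <- rep("none", n)
    ev[!is.na(birth) & birth == t] <- "appeared"

    die <- divide <- rep(FALSE, n)
    if (t < nd - 1L) {
      age <- t - birth
      if (crowding && block_death) {
        h_death <- rep(0, n)
      } else {
        h_death <- death_hazard_vec(config, age)
      }
      if (crowding) {
        cap <- config$crowding_capacity
        ratio <- n / n0
        fac <- if (cap > 1) max(0, (cap - ratio) / (cap - 1)) else 0
        p_div <- rep(d_hz * fac, n)
      } else {
        p_div <- rep(d_hz, n)
        if (config$coupling_mode == "local_replacement")
          p_div <- p_div + boost_from_deposits(deposits, t, pos, config)
      }
      # death and division drawn from disjoint intervals of one uniform so
      # both per-day marginal probabilities are exact (mutually exclusive
      # competing events; division truncated only if the two hazards sum > 1)
      u <- stats::runif(n)
      die <- u < h_death
      divide <- u >= 1 - pmin(p_div, 1 - h_death)
      ev[die] <- "died"
      ev[divide] <- "divided"
    }

    acc[[t + 1L]] <- list(day = rep.int(t, n), cell_id = id,
                          parent_id = parent, x = pos[, 1], y = pos[, 2],
                          z = pos[, 3], event = ev, labels = labels)
    if (t == nd - 1L) break

    if (!crowding && config$coupling_mode == "local_replacement" && any(die)) {
      mbar <- mean(h_death)
      B <- if (mbar > 0) max(0, (mbar - d_hz) / mbar) else 0
      B <- B * config$coupling_strength
      if (B > 0)
        deposits[[as.character(t)]] <-
          list(sites = pos[die, , drop = FALSE], daily = B / config$coupling_lag)
    }

    n_div <- sum(divide)
    if (n_div > 0L) {
      mpos <- pos[divide, , drop = FALSE]
      d_pos <- reflect_into(
        rbind(mpos, mpos) + config$daughter_offset * random_unit_rows(2L * n_div),
        dims)
      d_id <- seq.int(next_id, length.out = 2L * n_div)
      next_id <- next_id + 2L * n_div
      d_parent <- rep(id[divide], 2L)
      d_birth <- rep.int(t + 1L, 2L * n_div)
      d_lab <- join_label(rep(labels[divide], 2L), "newborn")
    }

    keep <- !die & !divide
    id <- id[keep]; parent <- parent[keep]; birth <- birth[keep]
    pos <- pos[keep, , drop = FALSE]; labels <- labels[keep]

    walk <- !is.na(birth) & (t + 1L - birth) <= config$dispersal_days
    if (any(walk) && config$dispersion_step > 0)
      pos[walk, ] <- reflect_into(
        pos[walk, , drop = FALSE] +
          config$dispersion_step * random_unit_rows(sum(walk)),
        dims)

    if (n_div > 0L) {
      id <- c(id, d_id); parent <- c(parent, d_parent)
      birth <- c(birth, d_birth); pos <- rbind(pos, d_pos)
      labels <- c(labels, d_lab)
    }
  }

  acc <- acc[!vapply(acc, is.null, logical(1))]
  snaps <- data.frame(
    day = unlist(lapply(acc, `[[`, "day")),
    cell_id = unlist(lapply(acc, `[[`, "cell_id")),
    parent_id = unlist(lapply(acc, `[[`, "parent_id")),
    x_um = unlist(lapply(acc, `[[`, "x")),
    y_um = unlist(lapply(acc, `[[`, "y")),
    z_um = unlist(lapply(acc, `[[`, "z")),
    event = unlist(lapply(acc, `[[`, "event")),
    labels = unlist(lapply(acc, `[[`, "labels")),
    stringsAsFactors = FALSE
  )
  structure(list(snapshots = snaps, fov_id = fov_id, config = config,
                 extinct = extinct),
            class = "track_set")
}

#' Simulate a longitudinal cell population
#'
#' Runs the daily-resolution spatial birth-death model in each field of view.
#' Cells divide with probability `division_hazard` per day and die with the
#' resident or newborn hazard; in `"local_replacement"` coupling mode every
#' death transiently boosts the division propensity of its nearest neighbours
#' (within `coupling_radius`, for `coupling_lag` days), with the total boost
#' recalibrated daily so that expected births equal expected deaths.
#'
#' @param config a [simulation_config()].
#' @return A list of `track_set` objects (one per FOV), classed
#'   `track_collection`. Each `track_set` holds a long-format snapshot table
#'   (see [render_snapshots()]) plus an `extinct` flag that is `TRUE` when the
#'   FOV's population died out before the last snapshot.
#' @examples
#' ts <- simulate_population(simulation_config(n_fov = 1, n_days = 5, seed = 1))
#' head(render_snapshots(ts))
#' @export
simulate_population <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  out <- lapply(seq_len(config$n_fov), function(f) simulate_fov(config, f))
  structure(out, class = "track_collection", config = config)
}

#' Simulate the apoptosis-blocked (Bcl2-overexpression-like) scenario
#'
#' Death hazards are set to zero (unless `block_death = FALSE`) and the
#' division hazard is attenuated by crowding: the effective hazard scales with
#' `(capacity - density_ratio) / (capacity - 1)`, so density rises from
#' baseline and plateaus at `crowding_capacity` times the initial density.
#' With the default division hazard the plateau takes on the order of 100+
#' days to establish, so pass a config with a long `n_days`.
#'
#' @param config a [simulation_config()] with `crowding_capacity` set
#'   (`>= 1`; exactly 1 suppresses division entirely).
#' @param block_death keep death hazards active instead of zeroing them
#'   (control scenario; density then stays at or below baseline).
#' @return A `track_collection`, as [simulate_population()].
#' @export
simulate_apoptosis_blocked <- function(config, block_death = TRUE) {
  validate_config(config)
  if (is.na(config$crowding_capacity))
    stop("crowding_capacity must be set for the apoptosis-blocked scenario",
         call. = FALSE)
  set.seed(config$seed)
  out <- lapply(seq_len(config$n_fov), function(f)
    simulate_fov(config, f, crowding = TRUE, block_death = block_death))
  structure(out, class = "track_collection", config = config)
}

#' @export
print.track_set <- function(x, ...) {
  s <- x$snapshots
  cat(sprintf("<track_set fov=%s> %d cells, days %d-%d, %d divisions, %d deaths%s\n",
              format(x$fov_id), length(unique(s$cell_id)),
              min(s$day), max(s$day),
              sum(s$event == "divided"), sum(s$event == "died"),
              if (x$extinct) " [EXTINCT]" else ""))
  invisible(x)
}

#' @export
print.track_collection <- function(x, ...) {
  cat(sprintf("<track_collection> %d field(s) of view\n", length(x)))
  for (ts in x) print(ts)
  invisible(x)
}

#' Per-day population size
#'
#' @param x a `track_set` or `track_collection`.
#' @return data.frame with columns `fov`, `day`, `n`.
#' @export
population_size <- function(x) {
  if (inherits(x, "track_set")) x <- list(x)
  do.call(rbind, lapply(x, function(ts) {
    tab <- table(ts$snapshots$day)
    data.frame(fov = ts$fov_id, day = as.integer(names(tab)),
               n = as.integer(tab), row.names = NULL)
  }))
}
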