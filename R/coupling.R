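# Spatiotemporal coupling of death and proliferation events.
#
# All distances are within-FOV Euclidean. Cells sharing a founder (the same
# lineage tree) are excluded from a death's candidate divisions: relatives
# are born next to each other, so a family's early deaths and later divisions
# cluster in space and time purely through descent, which mimics coupling
# even in an uncoupled population. annotate_events() attaches a `root_id`
# per cell for this; on hand-built event lists without it the rule falls
# back to first-degree relations (self, parent, daughter, twin sibling).

#' Coupling analysis configuration
#'
#' @param radius_um vicinity radius around a death (default 200 um).
#' @param window_days temporal window on each side of a death (default 4).
#' @param n_permutations permutations for the null (>= 100, default 1000).
#' @param seed seed for the permutation draw.
#' @return A list of class `coupling_config`.
#' @export
coupling_config <- function(radius_um = 200, window_days = 4,
                            n_permutations = 1000, seed = 1L) {
  if (!is.finite(radius_um) || radius_um <= 0)
    stop("radius_um must be > 0", call. = FALSE)
  if (window_days < 1) stop("window_days must be >= 1", call. = FALSE)
  if (n_permutations < 100)
    stop("n_permutations must be >= 100", call. = FALSE)
  structure(list(radius_um = radius_um, window_days = as.integer(window_days),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "coupling_config")
}

#' Extract death and division event lists from a snapshot table
#'
#' A death's position is the cell's last observed position; a division's
#' position is the mother's position on her `divided` day.
#'
#' @param snapshots snapshot table, `track_set` or `track_collection`.
#' @return List with data.frames `deaths` and `divisions`, each with columns
#'   `fov`, `cell_id`, `parent_id`, `day`, `x_um`, `y_um`, `z_um`. Errors if
#'   a cell has observations after its terminal event (died/divided then
#'   reappears).
#' @export
annotate_events <- function(snapshots) {
  df <- check_snapshot_table(render_snapshots(snapshots))
  cols <- c("fov", "cell_id", "parent_id", "day", "x_um", "y_um", "z_um",
            "root_id")
  if (nrow(df)) {
    key <- paste(df$fov, df$cell_id, sep = ":")
    term <- df$event %in% c("died", "divided")
    if (any(term)) {
      last_day <- tapply(df$day, key, max)
      bad <- term & df$day < as.vector(last_day[key])
      if (any(bad)) {
        b <- df[bad, , drop = FALSE][1, ]
        stop(sprintf("cell %s (fov %s) has observations after its '%s' event on day %d",
                     b$cell_id, b$fov, b$event, b$day), call. = FALSE)
      }
    }
    df$root_id <- lineage_roots(df)
  } else {
    df$root_id <- character(0)
  }
  list(deaths = df[df$event == "died", cols, drop = FALSE],
       divisions = df[df$event == "divided", cols, drop = FALSE])
}

# founder (lineage-tree root) of every row's cell, as "fov:cell" keys
lineage_roots <- function(df) {
  key <- paste(df$fov, df$cell_id, sep = ":")
  pkey <- ifelse(is.na(df$parent_id), NA,
                 paste(df$fov, df$parent_id, sep = ":"))
  cells <- !duplicated(key)
  parent_of <- stats::setNames(pkey[cells], key[cells])
  root <- stats::setNames(names(parent_of), names(parent_of))
  repeat {
    p <- parent_of[root]
    up <- !is.na(p) & p %in% names(parent_of)
    if (!any(up)) break
    root[up] <- p[up]
  }
  unname(root[key])
}

# Lineage relation between a death event and division events (vectorised
# over divisions): same lineage tree when founder ids are available,
# first-degree relations otherwise.
lineage_related <- function(death, div) {
  if (!is.null(death$root_id) && !is.null(div$root_id) &&
      !is.na(death$root_id) && !anyNA(div$root_id))
    return(div$root_id == death$root_id)
  same <- div$cell_id == death$cell_id
  child <- !is.na(div$parent_id) & div$parent_id == death$cell_id
  parent <- !is.na(death$parent_id) & div$cell_id == death$parent_id
  sibling <- !is.na(death$parent_id) & !is.na(div$parent_id) &
    div$parent_id == death$parent_id
  same | child | parent | sibling
}

# in-radius, lineage-filtered (death_idx, div_idx, delta_day, dist) pairs
coupling_pairs <- function(deaths, divisions, config) {
  out <- list()
  for (f in unique(deaths$fov)) {
    de <- deaths[deaths$fov == f, , drop = FALSE]
    dv <- divisions[divisions$fov == f, , drop = FALSE]
    if (!nrow(de) || !nrow(dv)) next
    for (i in seq_len(nrow(de))) {
      d <- de[i, ]
      keep <- !lineage_related(d, dv)
      if (!any(keep)) next
      dist <- sqrt((dv$x_um[keep] - d$x_um)^2 + (dv$y_um[keep] - d$y_um)^2 +
                   (dv$z_um[keep] - d$z_um)^2)
      inr <- dist <= config$radius_um
      if (!any(inr)) next
      out[[length(out) + 1L]] <- data.frame(
        fov = f, death_id = d$cell_id, death_day = d$day,
        div_id = dv$cell_id[keep][inr], div_day = dv$day[keep][inr],
        dist = dist[inr])
    }
  }
  if (!length(out))
    return(data.frame(fov = integer(0), death_id = integer(0),
                      death_day = integer(0), div_id = integer(0),
                      div_day = integer(0), dist = numeric(0)))
  do.call(rbind, out)
}

#' Temporal coupling of proliferation to death
#'
#' Each death is a reference point (day 0); divisions within `radius_um` and
#' at most `window_days` away are binned as before (earlier), during (same
#' snapshot day) or after (later). The asymmetry statistic is
#' `(after - before) / (after + before)`.
#'
#' @param deaths,divisions event data.frames from [annotate_events()].
#' @param config a [coupling_config()].
#' @return A `temporal_coupling` list: counts, fractions (summing to 1 over
#'   counted events), `asymmetry`, `n_pairs`, `empty` flag (fractions are
#'   `NA`, not silent zeros, when no division falls in any window).
#' @export
temporal_coupling <- function(deaths, divisions, config = coupling_config()) {
  if (!nrow(deaths) || !nrow(divisions))
    stop("event lists must be non-empty", call. = FALSE)
  pr <- coupling_pairs(deaths, divisions, config)
  delta <- pr$div_day - pr$death_day
  keep <- abs(delta) <= config$window_days
  pr <- pr[keep, , drop = FALSE]
  delta <- delta[keep]
  n <- length(delta)
  if (n == 0L) {
    return(structure(list(counts = c(before = 0L, during = 0L, after = 0L),
                          fractions = c(before = NA_real_, during = NA_real_,
                                        after = NA_real_),
                          asymmetry = NA_real_, n_pairs = 0L,
                          per_death = NULL, empty = TRUE),
                     class = "temporal_coupling"))
  }
  counts <- c(before = sum(delta < 0), during = sum(delta == 0),
              after = sum(delta > 0))
  asym <- if (counts[["before"]] + counts[["after"]] > 0)
    (counts[["after"]] - counts[["before"]]) /
      (counts[["after"]] + counts[["before"]]) else NA_real_
  dk <- paste(pr$fov, pr$death_id, pr$death_day, sep = ":")
  per_death <- do.call(rbind, lapply(split(delta, dk), function(dl)
    data.frame(n_prolif_before = sum(dl < 0), n_prolif_during = sum(dl == 0),
               n_prolif_after = sum(dl > 0))))
  per_death$death <- rownames(per_death)
  rownames(per_death) <- NULL
  structure(list(counts = counts, fractions = counts / n, asymmetry = asym,
                 n_pairs = n, per_death = per_death, empty = FALSE),
            class = "temporal_coupling")
}

#' @export
print.temporal_coupling <- function(x, ...) {
  if (x$empty) {
    cat("<temporal_coupling> empty: no division within any death's window\n")
    return(invisible(x))
  }
  cat(sprintf("<temporal_coupling> %d vicinity events: before %.1f%%, during %.1f%%, after %.1f%% (asymmetry %.3f)\n",
              x$n_pairs, 100 * x$fractions[1], 100 * x$fractions[2],
              100 * x$fractions[3], x$asymmetry))
  invisible(x)
}

#' Nearest proliferating and resident cell for every death
#'
#' For each death: the Euclidean distance to the nearest division event
#' within `window_days` (any distance, lineage excluded), the distance to the
#' nearest resident cell present on the death day (excluding the dying cell
#' itself), and the neighbor rank of the nearest division (1 + number of
#' resident cells strictly closer). Summaries include median +/- IQR for both
#' distance sets and a paired signed-rank comparison over deaths with both
#' values observed.
#'
#' @param deaths,divisions event data.frames from [annotate_events()].
#' @param residents snapshot table providing the per-day cell positions
#'   (typically the same table the events came from).
#' @param config a [coupling_config()].
#' @return A `coupling_result` with `per_death` data.frame and `summary`
#'   list.
#' @export
nearest_event_distances <- function(deaths, divisions, residents,
                                    config = coupling_config()) {
  res <- check_snapshot_table(render_snapshots(residents))
  recs <- list()
  for (i in seq_len(nrow(deaths))) {
    d <- deaths[i, ]
    rr <- res[res$fov == d$fov & res$day == d$day &
                res$cell_id != d$cell_id, , drop = FALSE]
    if (!nrow(rr)) {
      warning("death of cell ", d$cell_id, " (fov ", d$fov,
              "): no resident cells on its death day; skipped", call. = FALSE)
      next
    }
    rdist <- sqrt((rr$x_um - d$x_um)^2 + (rr$y_um - d$y_um)^2 +
                  (rr$z_um - d$z_um)^2)
    dv <- divisions[divisions$fov == d$fov &
                      abs(divisions$day - d$day) <= config$window_days, ,
                    drop = FALSE]
    dv <- dv[!lineage_related(d, dv), , drop = FALSE]
    if (nrow(dv)) {
      pdist <- sqrt((dv$x_um - d$x_um)^2 + (dv$y_um - d$y_um)^2 +
                    (dv$z_um - d$z_um)^2)
      np <- min(pdist)
      rank <- 1L + sum(rdist < np)
    } else {
      np <- NA_real_
      rank <- NA_integer_
    }
    recs[[length(recs) + 1L]] <- data.frame(
      fov = d$fov, death_id = d$cell_id, day = d$day,
      nearest_proliferating_um = np, nearest_resident_um = min(rdist),
      rank_of_nearest_proliferating = rank)
  }
  per_death <- if (length(recs)) do.call(rbind, recs) else
    data.frame(fov = integer(0), death_id = integer(0), day = integer(0),
               nearest_proliferating_um = numeric(0),
               nearest_resident_um = numeric(0),
               rank_of_nearest_proliferating = integer(0))
  rownames(per_death) <- NULL
  np <- per_death$nearest_proliferating_um
  nr <- per_death$nearest_resident_um
  ok <- !is.na(np)
  paired <- if (sum(ok) >= 5L)
    wilcoxon_signed_rank(np[ok], nr[ok]) else NULL
  qi <- function(v) if (length(v))
    stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE) else rep(NA_real_, 3)
  qp <- qi(np[ok]); qr <- qi(nr)
  structure(list(
    per_death = per_death,
    summary = list(
      n_deaths = nrow(per_death), n_with_division = sum(ok),
      prolif_median = qp[2], prolif_iqr = c(lower = qp[1], upper = qp[3]),
      resident_median = qr[2], resident_iqr = c(lower = qr[1], upper = qr[3]),
      median_rank = stats::median(per_death$rank_of_nearest_proliferating,
                                  na.rm = TRUE),
      paired_test = paired)),
    class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<coupling_result> %d deaths (%d with a division in window)\n",
              s$n_deaths, s$n_with_division))
  cat(sprintf("  nearest proliferating: median %.2f um (IQR %.2f-%.2f)\n",
              s$prolif_median, s$prolif_iqr[1], s$prolif_iqr[2]))
  cat(sprintf("  nearest resident:      median %.2f um (IQR %.2f-%.2f)\n",
              s$resident_median, s$resident_iqr[1], s$resident_iqr[2]))
  cat(sprintf("  median neighbor rank of nearest division: %.1f\n",
              s$median_rank))
  if (!is.null(s$paired_test))
    cat(sprintf("  paired signed-rank: W+ = %g, p = %.4g (%s, n = %d)\n",
                s$paired_test$statistic, s$paired_test$p_value,
                s$paired_test$method, s$paired_test$n_used))
  invisible(x)
}

#' Permutation null for the temporal-coupling asymmetry
#'
#' Event days are shuffled within each event list (division days among
#' divisions, death days among deaths; positions fixed), which preserves the
#' spatial point pattern and both day-marginal intensities while breaking
#' any death-division time association, and the asymmetry statistic is
#' recomputed; the p-value is
#' `(1 + #{null >= observed}) / (1 + n_permutations)`. Shuffling only one
#' list would leave the null blind to the lagged dependence of newborn
#' deaths on past divisions and make the test anticonservative.
#'
#' @param deaths,divisions event data.frames from [annotate_events()]; at
#'   least 5 events of each type.
#' @param config a [coupling_config()]; its `seed` makes the draw
#'   reproducible.
#' @return A `permutation_null` list: `p_value`, `observed_asymmetry`,
#'   `null_asymmetry`, `n_permutations`.
#' @export
permutation_null <- function(deaths, divisions, config = coupling_config()) {
  if (nrow(deaths) < 5L || nrow(divisions) < 5L)
    stop("need at least 5 deaths and 5 divisions; collect more data",
         call. = FALSE)
  obs <- temporal_coupling(deaths, divisions, config)
  if (is.na(obs$asymmetry))
    stop("observed asymmetry undefined (no vicinity events)", call. = FALSE)
  pr <- coupling_pairs(deaths, divisions, config) # radius-filtered; days re-randomised below
  div_all <- paste(divisions$fov, divisions$cell_id, sep = ":")
  div_levels <- unique(div_all)
  div_idx <- match(paste(pr$fov, pr$div_id, sep = ":"), div_levels)
  div_days <- divisions$day[match(div_levels, div_all)]
  death_all <- paste(deaths$fov, deaths$cell_id, sep = ":")
  death_levels <- unique(death_all)
  death_idx <- match(paste(pr$fov, pr$death_id, sep = ":"), death_levels)
  death_days <- deaths$day[match(death_levels, death_all)]
  set.seed(config$seed)
  null_asym <- vapply(seq_len(config$n_permutations), function(k) {
    delta <- sample(div_days)[div_idx] - sample(death_days)[death_idx]
    keep <- abs(delta) <= config$window_days
    a <- sum(delta[keep] > 0); b <- sum(delta[keep] < 0)
    if (a + b == 0) 0 else (a - b) / (a + b)
  }, 0)
  p <- (1 + sum(null_asym >= obs$asymmetry)) / (1 + config$n_permutations)
  structure(list(p_value = p, observed_asymmetry = obs$asymmetry,
                 null_asymmetry = null_asym,
                 n_permutations = config$n_permutations),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> observed asymmetry %.3f, p = %.4g (%d permutations)\n",
              x$observed_asymmetry, x$p_value, x$n_permutations))
  invisible(x)
}

#' One-call coupling analysis of a snapshot table
#'
#' Runs [annotate_events()], [temporal_coupling()],
#' [nearest_event_distances()] and (when both event lists have >= 5 entries)
#' [permutation_null()].
#'
#' @param snapshots snapshot table, `track_set` or `track_collection`.
#' @param config a [coupling_config()].
#' @return List with `events`, `temporal`, `distances`, `permutation`
#'   (`NULL` if too few events).
#' @export
coupling_analysis <- function(snapshots, config = coupling_config()) {
  snaps <- check_snapshot_table(render_snapshots(snapshots))
  ev <- annotate_events(snaps)
  temporal <- if (nrow(ev$deaths) && nrow(ev$divisions))
    temporal_coupling(ev$deaths, ev$divisions, config) else NULL
  distances <- nearest_event_distances(ev$deaths, ev$divisions, snaps, config)
  permutation <- NULL
  if (nrow(ev$deaths) >= 5L && nrow(ev$divisions) >= 5L &&
      !is.null(temporal) && !temporal$empty && !is.na(temporal$asymmetry)) {
    permutation <- permutation_null(ev$deaths, ev$divisions, config)
  }
  list(events = ev, temporal = temporal, distances = distances,
       permutation = permutation)
}
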