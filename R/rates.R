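# Per-day event-rate estimators for longitudinal track tables.
#
# Denominator convention: cell-days at risk. A cell contributes one risk day
# for every snapshot at which it is present except the final snapshot of its
# FOV (events for the last inter-snapshot interval are unobservable), and an
# event is attributed to the risk day on which it is flagged. Strata
# partition risk days exactly: a born cell's risk days belong to the
# "newborn" stratum while its age is below `newborn_window` and to the
# "resident" stratum afterwards; day-0 cells are always resident.

prepare_risk_table <- function(snapshots) {
  df <- check_snapshot_table(render_snapshots(snapshots))
  if (!nrow(df)) stop("empty snapshot table", call. = FALSE)
  key <- paste(df$fov, df$cell_id, sep = ":")
  born <- !is.na(df$parent_id)
  bday <- tapply(ifelse(born, df$day, NA_integer_), key, min)
  df$birth_day <- as.vector(bday[key])
  df$age <- df$day - df$birth_day
  last_day <- tapply(df$day, df$fov, max)
  df$at_risk <- df$day < as.vector(last_day[as.character(df$fov)])
  df
}

stratum_mask <- function(df, stratification, newborn_window) {
  switch(stratification,
         all = rep(TRUE, nrow(df)),
         resident = is.na(df$age) | df$age >= newborn_window,
         newborn = !is.na(df$age) & df$age < newborn_window,
         newborn_first5 = !is.na(df$age) & df$age < 5,
         stop("unknown stratum: ", stratification, call. = FALSE))
}

event_rate <- function(snapshots, event, stratification, newborn_window) {
  df <- prepare_risk_table(snapshots)
  if (length(unique(df$day)) < 2L)
    stop("need at least 2 days of data to estimate a per-day rate",
         call. = FALSE)
  keep <- df$at_risk & stratum_mask(df, stratification, newborn_window)
  risk <- df[keep, , drop = FALSE]
  fovs <- sort(unique(df$fov))
  per_fov <- vapply(fovs, function(f) {
    r <- risk[risk$fov == f, , drop = FALSE]
    if (!nrow(r)) return(NA_real_)
    100 * sum(r$event == event) / nrow(r)
  }, 0)
  if (anyNA(per_fov)) {
    warning(sum(is.na(per_fov)), " FOV(s) with no risk days in stratum '",
            stratification, "' excluded", call. = FALSE)
    fovs <- fovs[!is.na(per_fov)]
    per_fov <- per_fov[!is.na(per_fov)]
  }
  n_events <- sum(risk$event == event)
  q <- stats::quantile(per_fov, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(
    rate_pct_per_day = 100 * n_events / nrow(risk),
    median = q[2], iqr = c(lower = q[1], upper = q[3]),
    per_fov = stats::setNames(per_fov, fovs),
    n_cells = length(unique(paste(risk$fov, risk$cell_id))),
    n_fov = length(fovs),
    n_events = n_events,
    n_risk_days = nrow(risk),
    stratum = stratification,
    event = event
  ), class = "rate_estimate")
}

#' Per-day proliferation rate
#'
#' Per FOV, `100 * division events / cell-days at risk`; the pooled rate uses
#' summed events and risk days, and the headline summary is the median and
#' interquartile range across FOVs. A division is one event (the mother's
#' `divided` flag), not two daughters.
#'
#' @param snapshots snapshot table, `track_set` or `track_collection`.
#' @param stratification one of `"all"`, `"resident"`, `"newborn"`,
#'   `"newborn_first5"` (see [death_rate()] for stratum definitions).
#' @param newborn_window days after birth during which a born cell's risk
#'   days count as "newborn" (match the generating window; default 10).
#' @return A `rate_estimate`: pooled `rate_pct_per_day`, `median`, `iqr`,
#'   `per_fov`, `n_cells`, `n_fov`, `n_events`, `n_risk_days`, `stratum`.
#' @export
proliferation_rate <- function(snapshots, stratification = "all",
                               newborn_window = 10) {
  event_rate(snapshots, "divided", stratification, newborn_window)
}

#' Per-day death rate
#'
#' As [proliferation_rate()] but counting `died` events. Strata: `"resident"`
#' covers day-0 cells (plus born cells older than `newborn_window`),
#' `"newborn"` covers cells with an observed birth while their age is below
#' `newborn_window`, and `"newborn_first5"` restricts to the first 5 days
#' after birth; resident and newborn risk days partition the total exactly.
#'
#' @inheritParams proliferation_rate
#' @return A `rate_estimate`.
#' @export
death_rate <- function(snapshots, stratification = "all",
                       newborn_window = 10) {
  event_rate(snapshots, "died", stratification, newborn_window)
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %s events, stratum '%s'\n", x$event, x$stratum))
  cat(sprintf("  pooled %.3f %%/day; median %.3f (IQR %.3f-%.3f) across %d FOVs\n",
              x$rate_pct_per_day, x$median, x$iqr[1], x$iqr[2], x$n_fov))
  cat(sprintf("  %d events / %d cell-days (%d cells)\n",
              x$n_events, x$n_risk_days, x$n_cells))
  invisible(x)
}

#' Nearest-neighbor distances of a point set
#'
#' Euclidean nearest-neighbor distance for each point, with mean +/- SEM and
#' median +/- IQR summaries. Distances are plain Euclidean (imaging FOVs are
#' physical crops); `torus_dims` switches to periodic distances, which is
#' useful for comparing against boundary-free closed forms.
#'
#' @param positions numeric matrix (or data.frame) with columns x, y, z.
#' @param torus_dims optional length-3 box for periodic (wrap-around)
#'   distances.
#' @return List with `distances` (per point) and `summary` (`mean`, `sem`,
#'   `median`, `iqr`). Duplicate coordinates give distance 0 with a warning.
#' @export
nearest_neighbor_distances <- function(positions, torus_dims = NULL) {
  p <- as.matrix(positions)
  if (nrow(p) < 2L) stop("need at least 2 points", call. = FALSE)
  if (is.null(torus_dims)) {
    dm <- as.matrix(stats::dist(p))
  } else {
    dm <- matrix(0, nrow(p), nrow(p))
    for (j in seq_len(ncol(p))) {
      dj <- abs(outer(p[, j], p[, j], "-"))
      dj <- pmin(dj, torus_dims[j] - dj)
      dm <- dm + dj^2
    }
    dm <- sqrt(dm)
  }
  diag(dm) <- Inf
  d <- apply(dm, 1L, min)
  if (any(d == 0))
    warning("duplicate coordinates: nearest-neighbor distance 0", call. = FALSE)
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
  list(distances = unname(d),
       summary = list(mean = mean(d), sem = stats::sd(d) / sqrt(length(d)),
                      median = q[2], iqr = c(lower = q[1], upper = q[3])))
}

#' Twin-pair dispersion profiles
#'
#' For every division with two co-observed daughters, the between-daughter
#' distance as a function of age (days since birth, age 0 = first observed
#' day). Also reports the first-24-hr twin distance against the resident
#' nearest-neighbor spacing (computed from day-0 positions per FOV), with a
#' rank-based comparison as the headline statistic and a t-test alongside.
#'
#' @param snapshots snapshot table, `track_set` or `track_collection`.
#' @return A `twin_dispersion` list: `pairs` (list of per-pair profiles),
#'   `profile` (data.frame age / n_pairs / median / q25 / q75),
#'   `twin_age0_distances`, `resident_nn` (per-cell day-0 NN distances),
#'   `reference_nn_distance` (their median), `comparison` (wilcoxon +
#'   t-test on first-24-hr twin vs resident spacing).
#' @export
twin_dispersion <- function(snapshots) {
  df <- check_snapshot_table(render_snapshots(snapshots))
  born <- df[!is.na(df$parent_id), , drop = FALSE]
  pairs <- list()
  if (nrow(born)) {
    pk <- paste(born$fov, born$parent_id, sep = ":")
    for (key in unique(pk)) {
      rows <- born[pk == key, , drop = FALSE]
      ids <- unique(rows$cell_id)
      if (length(ids) != 2L) next
      a <- rows[rows$cell_id == ids[1], , drop = FALSE]
      b <- rows[rows$cell_id == ids[2], , drop = FALSE]
      days <- intersect(a$day, b$day)
      if (!length(days)) {
        warning("twin pair ", key, " never co-observed; skipped",
                call. = FALSE)
        next
      }
      days <- sort(days)
      ia <- match(days, a$day); ib <- match(days, b$day)
      dist <- sqrt((a$x_um[ia] - b$x_um[ib])^2 +
                   (a$y_um[ia] - b$y_um[ib])^2 +
                   (a$z_um[ia] - b$z_um[ib])^2)
      birth <- min(days)
      pairs[[key]] <- list(pair_id = key,
                           distances_by_age = stats::setNames(dist, days - birth))
    }
  }
  ages <- sort(unique(unlist(lapply(pairs, function(p)
    as.integer(names(p$distances_by_age))))))
  profile <- do.call(rbind, lapply(ages, function(a) {
    d <- unlist(lapply(pairs, function(p) p$distances_by_age[as.character(a)]))
    d <- d[!is.na(d)]
    data.frame(age = a, n_pairs = length(d), median = stats::median(d),
               q25 = unname(stats::quantile(d, 0.25)),
               q75 = unname(stats::quantile(d, 0.75)))
  }))

  # resident reference spacing from day-0 positions, per FOV
  nn <- unlist(lapply(split(df, df$fov), function(s) {
    s0 <- s[s$day == min(s$day), , drop = FALSE]
    if (nrow(s0) < 2L) return(numeric(0))
    nearest_neighbor_distances(s0[, c("x_um", "y_um", "z_um")])$distances
  }))
  twin0 <- unlist(lapply(pairs, function(p) p$distances_by_age["0"]))
  twin0 <- twin0[!is.na(twin0)]
  comparison <- NULL
  if (length(twin0) >= 2L && length(nn) >= 2L) {
    comparison <- list(
      wilcoxon = stats::wilcox.test(twin0, nn, exact = FALSE),
      t_test = stats::t.test(twin0, nn)
    )
  }
  structure(list(pairs = pairs, profile = profile,
                 twin_age0_distances = unname(twin0),
                 resident_nn = unname(nn),
                 reference_nn_distance = if (length(nn)) stats::median(nn) else NA_real_,
                 comparison = comparison),
            class = "twin_dispersion")
}

#' @export
print.twin_dispersion <- function(x, ...) {
  cat(sprintf("<twin_dispersion> %d pair(s); resident NN median %.1f um\n",
              length(x$pairs), x$reference_nn_distance))
  if (!is.null(x$profile) && nrow(x$profile)) {
    utils::head(x$profile, 8)
    print(utils::head(x$profile, 8), row.names = FALSE)
  }
  invisible(x)
}
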