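# Independent brute-force oracles and small fixture builders, kept free of
# the implementation paths they check.

# nearest-neighbor distances by explicit double loop
oracle_nn <- function(p, torus = NULL) {
  p <- as.matrix(p)
  n <- nrow(p)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      dd <- 0
      for (k in seq_len(ncol(p))) {
        dk <- abs(p[i, k] - p[j, k])
        if (!is.null(torus)) dk <- min(dk, torus[k] - dk)
        dd <- dd + dk^2
      }
      best <- min(best, sqrt(dd))
    }
    out[i] <- best
  }
  out
}

# exact signed-rank p-value by full enumeration of 2^n sign assignments
oracle_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  p_le <- mean(W_all <= W_obs + 1e-9)
  p_ge <- mean(W_all >= W_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# per-death nearest division / resident scan by explicit loops
oracle_nearest_scan <- function(deaths, divisions, snaps, window) {
  res <- list()
  for (i in seq_len(nrow(deaths))) {
    d <- deaths[i, ]
    np <- Inf; nr <- Inf
    for (j in seq_len(nrow(divisions))) {
      v <- divisions[j, ]
      if (v$fov != d$fov || abs(v$day - d$day) > window) next
      rel <- if (!is.null(d$root_id) && !is.null(v$root_id)) {
        v$root_id == d$root_id
      } else {
        v$cell_id == d$cell_id ||
          (!is.na(v$parent_id) && v$parent_id == d$cell_id) ||
          (!is.na(d$parent_id) && v$cell_id == d$parent_id) ||
          (!is.na(d$parent_id) && !is.na(v$parent_id) &&
             v$parent_id == d$parent_id)
      }
      if (rel) next
      np <- min(np, sqrt((v$x_um - d$x_um)^2 + (v$y_um - d$y_um)^2 +
                           (v$z_um - d$z_um)^2))
    }
    rank <- 1L
    for (j in seq_len(nrow(snaps))) {
      s <- snaps[j, ]
      if (s$fov != d$fov || s$day != d$day || s$cell_id == d$cell_id) next
      dd <- sqrt((s$x_um - d$x_um)^2 + (s$y_um - d$y_um)^2 +
                   (s$z_um - d$z_um)^2)
      nr <- min(nr, dd)
      if (is.finite(np) && dd < np) rank <- rank + 1L
    }
    res[[i]] <- c(np = if (is.finite(np)) np else NA_real_,
                  nr = if (is.finite(nr)) nr else NA_real_,
                  rank = if (is.finite(np)) rank else NA_real_)
  }
  do.call(rbind, res)
}

# independent event-rate tally: loop over cells and day transitions
oracle_rate_tally <- function(snaps, event) {
  if (!"fov" %in% names(snaps)) snaps$fov <- 1L
  ev <- 0L
  risk <- 0L
  for (f in unique(snaps$fov)) {
    s <- snaps[snaps$fov == f, ]
    last <- max(s$day)
    for (id in unique(s$cell_id)) {
      rows <- s[s$cell_id == id, ]
      for (k in seq_len(nrow(rows))) {
        if (rows$day[k] < last) {
          risk <- risk + 1L
          if (rows$event[k] == event) ev <- ev + 1L
        }
      }
    }
  }
  100 * ev / risk
}

# minimal track_set wrapper for hand-built snapshot tables
toy_track_set <- function(df, config = simulation_config(), fov_id = 1L) {
  structure(list(snapshots = df, fov_id = fov_id, config = config,
                 extinct = FALSE),
            class = "track_set")
}

# n static cells observed on days 0..(days-1), optional event overrides:
# events = list(list(id=, day=, event=)) applied to matching rows
make_static_snaps <- function(n, days, events = list(), spacing = 25) {
  grid <- expand.grid(cell_id = seq_len(n), day = 0:(days - 1))
  df <- data.frame(day = grid$day, cell_id = grid$cell_id,
                   parent_id = NA_integer_,
                   x_um = spacing * ((grid$cell_id - 1) %% 10),
                   y_um = spacing * ((grid$cell_id - 1) %/% 10),
                   z_um = 50, event = "none", labels = "",
                   stringsAsFactors = FALSE)
  for (e in events) {
    hit <- df$cell_id == e$id & df$day == e$day
    df$event[hit] <- e$event
    if (e$event %in% c("died", "divided")) # drop later observations
      df <- df[!(df$cell_id == e$id & df$day > e$day), ]
  }
  df[order(df$day, df$cell_id), ]
}

toy_fixture_path <- function() {
  system.file("extdata", "toy_tracks.csv", package = "microturn")
}
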