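# Snapshot-table plumbing. The interchange dialect is a CSV with fixed header
#   day,cell_id,parent_id,x_um,y_um,z_um,event,labels
# (labels semicolon-joined). Multi-FOV collections append a 9th `fov` column.

SNAPSHOT_COLS <- c("day", "cell_id", "parent_id", "x_um", "y_um", "z_um",
                   "event", "labels")

empty_snapshot_table <- function() {
  data.frame(day = integer(0), cell_id = integer(0), parent_id = integer(0),
             x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
             event = character(0), labels = character(0),
             stringsAsFactors = FALSE)
}

#' Render a simulation as a long-format snapshot table
#'
#' One row per cell per observed day. The `event` column tags a cell's last
#' observed day with `"divided"` or `"died"` (the event happens in the
#' following inter-snapshot interval) and a born cell's first day with
#' `"appeared"`; all other rows are `"none"`. A daughter that dies on its very
#' first transition keeps the `"died"` flag (births stay recoverable from
#' `parent_id` plus first observed day), so the table is lossless with respect
#' to events.
#'
#' @param x a `track_set`, a `track_collection`, or an already-rendered
#'   snapshot data.frame (returned unchanged after validation).
#' @return A data.frame in the snapshot dialect; collections gain a `fov`
#'   column.
#' @export
render_snapshots <- function(x) {
  if (is.data.frame(x)) return(check_snapshot_table(x))
  if (inherits(x, "track_set")) {
    s <- x$snapshots
    if (nrow(s) == 0L) return(empty_snapshot_table())
    return(s[order(s$day, s$cell_id), , drop = FALSE])
  }
  if (inherits(x, "track_collection") || is.list(x)) {
    parts <- lapply(x, function(ts) {
      s <- render_snapshots(ts)
      if (nrow(s)) s$fov <- ts$fov_id
      s
    })
    out <- do.call(rbind, parts[vapply(parts, nrow, 0L) > 0])
    if (is.null(out)) {
      out <- empty_snapshot_table()
      out$fov <- integer(0)
    }
    rownames(out) <- NULL
    return(out)
  }
  stop("cannot render snapshots from class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

check_snapshot_table <- function(df) {
  missing <- setdiff(SNAPSHOT_COLS, names(df))
  if (length(missing))
    stop("snapshot table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"fov" %in% names(df)) df$fov <- 1L
  df
}

#' Write / read a snapshot table CSV
#'
#' Round-trip identity holds: `read_snapshots(write_snapshots(x, f))` equals
#' `render_snapshots(x)`.
#'
#' @param x snapshot table, `track_set` or `track_collection`.
#' @param path file path.
#' @return `write_snapshots()` returns `path` invisibly; `read_snapshots()`
#'   the snapshot data.frame.
#' @export
write_snapshots <- function(x, path) {
  df <- render_snapshots(x)
  df$parent_id[is.na(df$parent_id)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_snapshots
#' @export
read_snapshots <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(event = "character",
                                       labels = "character"))
  missing <- setdiff(SNAPSHOT_COLS, names(df))
  if (length(missing))
    stop("snapshot file missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$parent_id[df$parent_id %in% c("", "NA")] <- NA
  df$parent_id <- suppressWarnings(as.integer(df$parent_id))
  df$labels[is.na(df$labels)] <- ""
  df
}

#' Extract per-cell tracks from a track set
#'
#' Converts the long snapshot table into one record per cell: birth/death
#' days, parentage, label flags and the per-day position map.
#'
#' @param x a `track_set` or snapshot data.frame (single FOV).
#' @return A list of `cell_track` objects with fields `cell_id`, `parent_id`,
#'   `birth_day` (`NA` for day-0 cells), `death_day` (`NA` if the cell
#'   survives or divides), `divided_day`, `positions` (matrix with day
#'   rownames) and `labels` (character vector of flags).
#' @export
as_cell_tracks <- function(x) {
  s <- if (is.data.frame(x)) x else render_snapshots(x)
  if (nrow(s) == 0L) return(list())
  split_rows <- split(seq_len(nrow(s)), s$cell_id)
  lapply(split_rows, function(idx) {
    rows <- s[idx, , drop = FALSE]
    rows <- rows[order(rows$day), , drop = FALSE]
    born <- !is.na(rows$parent_id[1])
    last <- nrow(rows)
    pos <- as.matrix(rows[, c("x_um", "y_um", "z_um")])
    rownames(pos) <- rows$day
    structure(list(
      cell_id = rows$cell_id[1],
      parent_id = rows$parent_id[1],
      birth_day = if (born) rows$day[1] else NA_integer_,
      death_day = if (rows$event[last] == "died") rows$day[last] else NA_integer_,
      divided_day = if (rows$event[last] == "divided") rows$day[last] else NA_integer_,
      positions = pos,
      labels = setdiff(unique(unlist(strsplit(rows$labels, ";", fixed = TRUE))), "")
    ), class = "cell_track")
  })
}
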