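#' Default TrackMate column map
#'
#' Column names used by TrackMate's "spots" CSV export; override any entry
#' in [read_tracks()] for other tracking software.
#' @keywords internal
trackmate_columns <- function() {
  list(track_id = "TRACK_ID", frame = "FRAME",
       x = "POSITION_X", y = "POSITION_Y", t = "POSITION_T")
}

new_glt_tracks <- function(df, frame_rate) {
  df <- df[order(df$track_id, df$frame), c("track_id", "frame", "t", "x", "y")]
  rownames(df) <- NULL
  attr(df, "frame_rate") <- frame_rate
  class(df) <- c("glt_tracks", "data.frame")
  df
}

#' Read bead trajectories from a TrackMate-style spots table
#'
#' Reads a delimited spots table (TrackMate CSV dialect by default) into a
#' tidy track table: one row per (track, frame), positions in micrometres,
#' time in seconds. TrackMate's extra non-numeric sub-header rows (human-
#' readable names and units) are tolerated and dropped. If the file has no
#' time column, time is derived as `frame / frame_rate`.
#'
#' @param path path to a CSV/TSV spots file.
#' @param frame_rate acquisition frame rate, frames per second; used to
#'   derive time when absent and to validate it when present. Default 100.
#' @param columns column-name map, see [trackmate_columns()]. The `t` entry
#'   may be `NA` to force time derivation from frames.
#' @param sep field separator; `","` by default, auto-detected as tab if
#'   the header contains no commas.
#' @return A data.frame of class `glt_tracks` with columns `track_id`,
#'   `frame`, `t` (s), `x`, `y` (um), sorted by track then frame; the frame
#'   rate is kept as attribute `frame_rate`.
#' @export
read_tracks <- function(path, frame_rate = 100, columns = trackmate_columns(),
                        sep = NULL) {
  header <- readLines(path, n = 1)
  if (is.null(sep)) sep <- if (grepl(",", header, fixed = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "x", "y")
  for (key in need) {
    if (!(columns[[key]] %in% names(raw))) {
      stop(sprintf("required column '%s' (%s) not found in %s",
                   columns[[key]], key, path), call. = FALSE)
    }
  }
  has_t <- !is.na(columns$t) && columns$t %in% names(raw)
  # TrackMate v7 exports carry up to three non-numeric sub-header rows
  frame_num <- suppressWarnings(as.numeric(raw[[columns$frame]]))
  raw <- raw[!is.na(frame_num), , drop = FALSE]
  df <- data.frame(
    track_id = raw[[columns$track_id]],
    frame = as.integer(round(as.numeric(raw[[columns$frame]]))),
    x = as.numeric(raw[[columns$x]]),
    y = as.numeric(raw[[columns$y]]),
    stringsAsFactors = FALSE
  )
  df$t <- if (has_t) as.numeric(raw[[columns$t]]) else df$frame / frame_rate
  if (anyNA(df)) stop("non-numeric values in track columns of ", path, call. = FALSE)
  if (anyDuplicated(df[c("track_id", "frame")])) {
    stop("duplicate (track_id, frame) rows in ", path, call. = FALSE)
  }
  if (has_t) {
    mism <- abs(df$t - df$frame / frame_rate) > 0.51 / frame_rate
    if (any(mism)) {
      warning("declared frame rate inconsistent with time column for ",
              sum(mism), " spot(s)")
    }
  }
  out <- new_glt_tracks(df, frame_rate)
  bad <- vapply(split(out$frame, out$track_id),
                function(f) any(diff(f) <= 0), logical(1))
  if (any(bad)) {
    stop("non-monotone frames within track(s): ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  n_pts <- table(out$track_id)
  if (any(n_pts < 2)) {
    warning("track(s) with fewer than 2 points: ",
            paste(names(n_pts)[n_pts < 2], collapse = ", "))
  }
  out
}

#' Write bead trajectories in the TrackMate spots dialect
#'
#' Writes a `glt_tracks` table as a CSV readable by [read_tracks()]
#' (columns `TRACK_ID`, `FRAME`, `POSITION_X`, `POSITION_Y`, `POSITION_T`).
#'
#' @param tracks a `glt_tracks` table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "glt_tracks"))
  out <- data.frame(TRACK_ID = tracks$track_id, FRAME = tracks$frame,
                    POSITION_X = tracks$x, POSITION_Y = tracks$y,
                    POSITION_T = tracks$t)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a track table from vectors
#'
#' Low-level constructor for in-memory trajectories (used by the simulator
#' and in tests).
#'
#' @param track_id,frame,x,y per-spot vectors; `x`, `y` in micrometres.
#' @param frame_rate frames per second (time is `frame / frame_rate`).
#' @param t optional explicit time vector, s.
#' @return A `glt_tracks` table.
#' @export
glt_tracks <- function(track_id, frame, x, y, frame_rate = 100, t = NULL) {
  df <- data.frame(track_id = track_id, frame = as.integer(frame),
                   x = x, y = y, stringsAsFactors = FALSE)
  df$t <- if (is.null(t)) df$frame / frame_rate else t
  if (anyDuplicated(df[c("track_id", "frame")])) {
    stop("duplicate (track_id, frame) rows", call. = FALSE)
  }
  new_glt_tracks(df, frame_rate)
}

#' @export
print.glt_tracks <- function(x, ...) {
  ids <- unique(x$track_id)
  cat(sprintf("Bead tracks: %d track(s), %d spots, %g fps, t = [%g, %g] s\n",
              length(ids), nrow(x), attr(x, "frame_rate"),
              min(x$t), max(x$t)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

split_tracks <- function(tracks) {
  split(as.data.frame(tracks), tracks$track_id)
}
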