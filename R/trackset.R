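#' Track sets: the tabular single-molecule trajectory container
#'
#' A `track_set` holds every localization of one imaging channel (or both,
#' distinguished by the `channel` column) of one or more fields of view, as a
#' long table with one row per localization:
#' `field_id, channel, track_id, frame, x_um, y_um, intensity`.
#' Frames are 0-based; time is `frame * dt_s`; coordinates are in um.
#' Alongside the table the object carries the field geometry (`field_width_um`,
#' `field_height_um`), the frame interval `dt_s`, the movie length `n_frames`,
#' and whether the coordinates live on a periodic domain (`periodic`, TRUE for
#' simulated data; distance computations then use the minimal-image
#' convention).
#'
#' @param localizations data.frame with columns `field_id`, `channel`,
#'   `track_id`, `frame`, `x_um`, `y_um`, `intensity`.
#' @param field_width_um,field_height_um field dimensions, um.
#' @param dt_s frame interval, seconds.
#' @param n_frames movie length in frames.
#' @param periodic logical; simulated toroidal fields set this to TRUE.
#' @return object of class `track_set`.
#' @export
track_set <- function(localizations, field_width_um, field_height_um,
                      dt_s, n_frames, periodic = FALSE) {
  req <- c("field_id", "channel", "track_id", "frame", "x_um", "y_um",
           "intensity")
  missing_cols <- setdiff(req, names(localizations))
  if (length(missing_cols)) {
    stop("localizations missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dt <- data.table::as.data.table(localizations)[, req, with = FALSE]
  dt[, `:=`(track_id = as.integer(track_id), frame = as.integer(frame))]
  data.table::setkey(dt, field_id, channel, track_id, frame)
  bad <- dt[, any(diff(frame) <= 0), by = .(field_id, channel, track_id)][V1 == TRUE]
  if (nrow(bad)) {
    stop("frames must be strictly increasing within each track", call. = FALSE)
  }
  ts <- list(
    tracks = dt,
    field_width_um = field_width_um,
    field_height_um = field_height_um,
    dt_s = dt_s,
    n_frames = as.integer(n_frames),
    periodic = isTRUE(periodic)
  )
  class(ts) <- "track_set"
  ts
}

#' @export
print.track_set <- function(x, ...) {
  d <- channel_density(x)
  cat(sprintf("<track_set> %d localizations, %d tracks, %d frames @ %g s\n",
              nrow(x$tracks), data.table::uniqueN(x$tracks, by = c("field_id", "channel", "track_id")),
              x$n_frames, x$dt_s))
  cat(sprintf("  field %g x %g um%s\n", x$field_width_um, x$field_height_um,
              if (x$periodic) " (periodic)" else ""))
  for (ch in names(d)) cat(sprintf("  density %s: %.3g /um^2\n", ch, d[[ch]]))
  invisible(x)
}

#' Field area of a track set in um^2
#' @param ts a `track_set`.
#' @export
field_area <- function(ts) ts$field_width_um * ts$field_height_um

#' Time-averaged surface density per channel
#'
#' Mean number of localizations per frame divided by the field area,
#' averaged over fields; this is the density entering the association-rate
#' normalization.
#'
#' @param ts a `track_set`.
#' @return named numeric vector, molecules/um^2 per channel.
#' @export
channel_density <- function(ts) {
  n_fields <- max(1L, data.table::uniqueN(ts$tracks$field_id))
  denom <- field_area(ts) * ts$n_frames * n_fields
  counts <- ts$tracks[, .N, by = channel]
  stats::setNames(counts$N / denom, counts$channel)
}

#' Split a track set into per-track coordinate lists
#' @noRd
split_tracks <- function(ts, ch = NULL) {
  dt <- ts$tracks
  if (!is.null(ch)) dt <- dt[dt$channel %in% ch]
  split(dt, by = c("field_id", "channel", "track_id"), keep.by = TRUE)
}

#' Read / write the canonical track CSV format
#'
#' Columns: `field_id, channel, track_id, frame, x_um, y_um, intensity`.
#' Metadata (field size, dt, n_frames, periodic flag) travels in a JSON
#' sidecar written next to the CSV (`<file>.meta.json`).
#'
#' @param ts a `track_set`.
#' @param file path to the CSV file.
#' @return `write_tracks` returns `file` invisibly; `read_tracks` returns a
#'   `track_set`.
#' @export
write_tracks <- function(ts, file) {
  data.table::fwrite(ts$tracks, file)
  meta <- list(field_width_um = ts$field_width_um,
               field_height_um = ts$field_height_um,
               dt_s = ts$dt_s, n_frames = ts$n_frames, periodic = ts$periodic)
  jsonlite::write_json(meta, paste0(file, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_tracks
#' @param field_width_um,field_height_um,dt_s,n_frames,periodic metadata
#'   overrides used when no sidecar is present.
#' @export
read_tracks <- function(file, field_width_um = NULL, field_height_um = NULL,
                        dt_s = NULL, n_frames = NULL, periodic = NULL) {
  dt <- data.table::fread(file)
  side <- paste0(file, ".meta.json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  track_set(dt,
            field_width_um = field_width_um %||% meta$field_width_um,
            field_height_um = field_height_um %||% meta$field_height_um,
            dt_s = dt_s %||% meta$dt_s,
            n_frames = n_frames %||% meta$n_frames,
            periodic = periodic %||% meta$periodic %||% FALSE)
}

#' Restrict a track set to one channel or one field
#' @param ts a `track_set`.
#' @param channel,field_id values to keep (NULL keeps all).
#' @export
subset_tracks <- function(ts, channel = NULL, field_id = NULL) {
  ch <- channel; fid <- field_id
  dt <- ts$tracks
  if (!is.null(ch)) dt <- dt[dt$channel %in% ch]
  if (!is.null(fid)) dt <- dt[dt$field_id %in% fid]
  out <- ts
  out$tracks <- dt
  out
}
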