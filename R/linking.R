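#' Link dropout-split track segments into continuous trajectories
#'
#' Tracking software emits a new segment whenever a molecule goes undetected
#' for a few frames (or is interrupted by merge/split events). This
#' operation repairs such interruptions by greedy nearest-neighbor linking:
#' a segment ending at frame `f` is linked to the not-yet-matched segment
#' that starts after a gap of at most `max_gap_frames` missing frames
#' (i.e. start frame in `f + 1 .. f + max_gap_frames + 1`) and whose start
#' position lies nearest, within `max_link_distance_um`, of the segment's
#' end position. Ties are broken by distance, then by the smaller candidate
#' track id; segments are processed in order of end frame (then track id),
#' which makes the result deterministic. Linked chains keep the id of their
#' earliest segment. No localization is duplicated or lost; frames stay
#' strictly increasing because a continuation always starts after its
#' predecessor ends.
#'
#' Greedy per-frame linking (rather than global assignment) is adequate for
#' dropout repair at the low densities this package targets; at high density
#' it can chain distinct molecules and its bias should be checked against
#' simulations.
#'
#' @param ts a [track_set()].
#' @param max_gap_frames maximum number of missing frames bridged
#'   (default 2).
#' @param max_link_distance_um maximum end-to-start distance, um
#'   (default 0.3).
#' @return a [track_set()] with rewritten `track_id`s.
#' @export
link_segments <- function(ts, max_gap_frames = 2L,
                          max_link_distance_um = 0.3) {
  dt <- data.table::copy(ts$tracks)
  seg <- dt[, .(start_frame = frame[1], end_frame = frame[.N],
                sx = x_um[1], sy = y_um[1],
                ex = x_um[.N], ey = y_um[.N]),
            by = .(field_id, channel, track_id)]
  max_d2 <- max_link_distance_um^2
  W <- ts$field_width_um; H <- ts$field_height_um

  seg[, new_id := track_id]
  for (grp in split(seg, by = c("field_id", "channel"))) {
    data.table::setorder(grp, end_frame, track_id)
    taken <- logical(nrow(grp))          # start already consumed
    succ <- integer(nrow(grp))           # successor row index, 0 = none
    starts <- grp$start_frame
    for (i in seq_len(nrow(grp))) {
      f <- grp$end_frame[i]
      cand <- which(!taken &
                      starts > f &
                      starts <= f + max_gap_frames + 1L)
      cand <- cand[cand != i]
      if (!length(cand)) next
      d2 <- dist2_xy(grp$sx[cand] - grp$ex[i], grp$sy[cand] - grp$ey[i],
                     W, H, ts$periodic)
      ok <- d2 <= max_d2
      if (!any(ok)) next
      cand <- cand[ok]; d2 <- d2[ok]
      j <- cand[order(d2, grp$track_id[cand])][1]
      succ[i] <- j
      taken[j] <- TRUE
    }
    # propagate chain-head ids along successor pointers
    heads <- which(!taken)
    for (hh in heads) {
      id <- grp$track_id[hh]
      k <- hh
      repeat {
        seg[field_id == grp$field_id[k] & channel == grp$channel[k] &
              track_id == grp$track_id[k], new_id := id]
        k <- succ[k]
        if (k == 0L) break
      }
    }
  }
  dt <- seg[, .(field_id, channel, track_id, new_id)][dt,
    on = c("field_id", "channel", "track_id")]
  dt[, track_id := new_id][, new_id := NULL]
  out <- ts
  out$tracks <- dt
  data.table::setkey(out$tracks, field_id, channel, track_id, frame)
  out
}

#' Fill missing frames inside tracks by linear interpolation
#'
#' After segment linking, a track can still contain holes where detections
#' dropped out. Downstream frame-wise colocalization with the strict
#' "present again at f + 1" extension rule would break events at every
#' hole, biasing dwell times short; gap closing with interpolated positions
#' (as particle-tracking packages do) removes the holes. Interpolated
#' localizations get the mean of the flanking intensities. On periodic
#' fields steps are unwrapped before interpolating.
#'
#' @param ts a [track_set()].
#' @param max_gap_frames only holes of at most this many missing frames are
#'   filled (default 5).
#' @return a [track_set()] with interpolated rows added.
#' @export
interpolate_gaps <- function(ts, max_gap_frames = 5L) {
  W <- ts$field_width_um; H <- ts$field_height_um
  fill <- function(tr) {
    fr <- tr$frame
    gaps <- which(diff(fr) > 1L & diff(fr) <= max_gap_frames + 1L)
    if (!length(gaps)) return(NULL)
    if (ts$periodic) {
      x <- cumsum(c(tr$x_um[1], torus_diff(diff(tr$x_um), W)))
      y <- cumsum(c(tr$y_um[1], torus_diff(diff(tr$y_um), H)))
    } else {
      x <- tr$x_um; y <- tr$y_um
    }
    new <- lapply(gaps, function(g) {
      miss <- (fr[g] + 1L):(fr[g + 1L] - 1L)
      w <- (miss - fr[g]) / (fr[g + 1L] - fr[g])
      data.table::data.table(
        field_id = tr$field_id[1], channel = tr$channel[1],
        track_id = tr$track_id[1], frame = miss,
        x_um = x[g] + w * (x[g + 1L] - x[g]),
        y_um = y[g] + w * (y[g + 1L] - y[g]),
        intensity = (tr$intensity[g] + tr$intensity[g + 1L]) / 2)
    })
    out <- data.table::rbindlist(new)
    if (ts$periodic) {
      out[, `:=`(x_um = wrap_torus(x_um, W), y_um = wrap_torus(y_um, H))]
    }
    out
  }
  added <- data.table::rbindlist(lapply(split_tracks(ts), fill))
  out <- ts
  out$tracks <- data.table::rbindlist(list(ts$tracks, added), use.names = TRUE)
  data.table::setkey(out$tracks, field_id, channel, track_id, frame)
  out
}
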