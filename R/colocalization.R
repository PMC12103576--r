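#' Detect frame-wise two-channel colocalization events
#'
#' For every frame, each channel-A particle is matched one-to-one to the
#' nearest channel-B particle within `search_radius_um` (matching is greedy
#' by ascending distance, ties broken by the smaller B track id). A pair
#' matched at frame `f` and again at frame `f + g` with
#' `g <= 1 + max_gap_frames` continues the same event (the strict
#' "present again at f + 1" extension rule corresponds to `max_gap_frames =
#' 0`; a positive gap tolerates detection dropouts). Events are maximal runs
#' and are flagged right-censored when they reach the last frame of the
#' movie or of either participating track, since their true duration is then
#' only bounded from below.
#'
#' Both track sets must be registered to a common coordinate frame and share
#' `dt_s` and `n_frames`. For simulated (periodic) fields distances use the
#' minimal-image convention.
#'
#' @param a,b [track_set()]s for the two channels (may contain several
#'   fields; fields are processed independently and must appear in both).
#' @param search_radius_um colocalization search radius, um (default 150 nm).
#' @param max_gap_frames frames of tolerated interruption within one event.
#' @return data.frame of events: `field_id, a_track, b_track, start_frame,
#'   end_frame, duration_frames, right_censored`.
#' @export
detect_colocalizations <- function(a, b, search_radius_um = 0.15,
                                   max_gap_frames = 0L) {
  if (!isTRUE(all.equal(a$dt_s, b$dt_s)) || a$n_frames != b$n_frames) {
    stop("track sets must share dt_s and n_frames", call. = FALSE)
  }
  periodic <- a$periodic && b$periodic
  W <- a$field_width_um; H <- a$field_height_um
  r2 <- search_radius_um^2
  fields <- sort(unique(c(a$tracks$field_id, b$tracks$field_id)))
  out <- vector("list", length(fields))
  for (fi in seq_along(fields)) {
    fid <- fields[fi]
    da <- a$tracks[a$tracks$field_id == fid]
    db <- b$tracks[b$tracks$field_id == fid]
    if (nrow(da) == 0L || nrow(db) == 0L) next
    matches <- match_frames(da, db, r2, W, H, periodic)
    out[[fi]] <- events_from_matches(matches, da, db, fid,
                                     a$n_frames, max_gap_frames)
  }
  ev <- data.table::rbindlist(out)
  if (nrow(ev) == 0L) {
    ev <- data.table::data.table(
      field_id = character(0), a_track = integer(0), b_track = integer(0),
      start_frame = integer(0), end_frame = integer(0),
      duration_frames = integer(0), right_censored = logical(0))
  }
  as.data.frame(ev)
}

# per-frame greedy one-to-one matching; returns data.table(frame, a_track,
# b_track)
match_frames <- function(da, db, r2, W, H, periodic) {
  fa <- split(da[, .(frame, track_id, x_um, y_um)], by = "frame",
              keep.by = FALSE)
  fb <- split(db[, .(frame, track_id, x_um, y_um)], by = "frame",
              keep.by = FALSE)
  common <- intersect(names(fa), names(fb))
  res <- vector("list", length(common))
  for (i in seq_along(common)) {
    pa <- fa[[common[i]]]; pb <- fb[[common[i]]]
    dx <- outer(pa$x_um, pb$x_um, `-`)
    dy <- outer(pa$y_um, pb$y_um, `-`)
    d2 <- dist2_xy(dx, dy, W, H, periodic)
    cand <- which(d2 <= r2, arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    ord <- order(d2[cand], pb$track_id[cand[, 2]])
    used_a <- logical(nrow(pa)); used_b <- logical(nrow(pb))
    ka <- integer(0); kb <- integer(0)
    for (k in ord) {
      ia <- cand[k, 1]; ib <- cand[k, 2]
      if (used_a[ia] || used_b[ib]) next
      used_a[ia] <- TRUE; used_b[ib] <- TRUE
      ka <- c(ka, ia); kb <- c(kb, ib)
    }
    res[[i]] <- data.table::data.table(
      frame = as.integer(common[i]),
      a_track = pa$track_id[ka], b_track = pb$track_id[kb])
  }
  data.table::rbindlist(res)
}

# turn per-frame (a_track, b_track) matches into maximal events with gap
# tolerance and right-censoring flags
events_from_matches <- function(matches, da, db, fid, n_frames,
                                max_gap_frames) {
  if (is.null(matches) || nrow(matches) == 0L) return(NULL)
  last_a <- da[, .(last = max(frame)), by = track_id]
  last_b <- db[, .(last = max(frame)), by = track_id]
  la <- stats::setNames(last_a$last, last_a$track_id)
  lb <- stats::setNames(last_b$last, last_b$track_id)
  data.table::setorder(matches, a_track, b_track, frame)
  matches[, run := cumsum(c(1L, diff(frame) > (1L + max_gap_frames))),
          by = .(a_track, b_track)]
  ev <- matches[, .(start_frame = min(frame), end_frame = max(frame)),
                by = .(a_track, b_track, run)]
  ev[, run := NULL]
  ev[, `:=`(
    field_id = fid,
    duration_frames = end_frame - start_frame + 1L,
    right_censored = end_frame >= (n_frames - 1L) |
      end_frame >= la[as.character(a_track)] |
      end_frame >= lb[as.character(b_track)]
  )]
  data.table::setcolorder(ev, c("field_id", "a_track", "b_track",
                                "start_frame", "end_frame",
                                "duration_frames", "right_censored"))
  data.table::setorder(ev, start_frame, a_track, b_track)
  ev
}

#' Dwell-time distribution of colocalization events
#'
#' Histograms event durations at the frame interval. Events shorter than
#' `min_duration_frames` are excluded from the histogram but counted
#' (single-frame coincidences are dominated by detection noise);
#' right-censored events are tallied separately with their observed
#' durations, for survival-style rate fitting downstream.
#'
#' @param events event table from [detect_colocalizations()] (one condition).
#' @param dt_s frame interval, seconds (= bin width).
#' @param min_duration_frames shortest duration (frames) kept (default 2).
#' @param kind one of "observed", "null", "deconvolved".
#' @return object of class `dwell_dist`: `counts` (index = duration in
#'   frames, from 1), `bin_width_s`, `n_events` (events in the histogram),
#'   `n_censored`, `n_excluded_short`, `censored_frames` (durations of
#'   censored events), `min_duration_frames`, `kind`.
#' @export
dwell_distribution <- function(events, dt_s, min_duration_frames = 2L,
                               kind = "observed") {
  kind <- match.arg(kind, c("observed", "null", "deconvolved"))
  dur <- events$duration_frames
  cens <- as.logical(events$right_censored)
  keep <- !cens & dur >= min_duration_frames
  kmax <- max(1L, dur, 1L)
  counts <- tabulate(dur[keep], nbins = kmax)
  structure(list(
    bin_width_s = dt_s,
    counts = as.numeric(counts),
    n_events = sum(keep),
    n_censored = sum(cens),
    n_excluded_short = sum(!cens & dur < min_duration_frames),
    censored_frames = sort(dur[cens]),
    min_duration_frames = as.integer(min_duration_frames),
    kind = kind
  ), class = "dwell_dist")
}

#' @export
print.dwell_dist <- function(x, ...) {
  cat(sprintf("<dwell_dist:%s> %s events (+%d censored, %d short-excluded), bin %g s, max %d frames\n",
              x$kind, format(round(x$n_events, 1)), x$n_censored,
              x$n_excluded_short, x$bin_width_s, length(x$counts)))
  invisible(x)
}
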