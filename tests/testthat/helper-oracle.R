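# Independent brute-force oracles and fixture builders used across tests.
# These deliberately re-derive results by exhaustive enumeration, without
# reusing the package's optimized code paths.

# exhaustive pair-frame colocalization oracle: enumerates every (A, B, frame)
# distance, applies the same greedy one-to-one rule from the full matrix,
# then extracts maximal runs per pair with the gap rule
oracle_colocalize <- function(a, b, radius_um, max_gap = 0L) {
  stopifnot(a$n_frames == b$n_frames)
  da <- as.data.frame(a$tracks)
  db <- as.data.frame(b$tracks)
  W <- a$field_width_um; H <- a$field_height_um
  per <- a$periodic && b$periodic
  out <- list()
  for (fid in unique(da$field_id)) {
    pa <- da[da$field_id == fid, ]
    pb <- db[db$field_id == fid, ]
    pairs <- list()
    for (f in 0:(a$n_frames - 1L)) {
      ra <- pa[pa$frame == f, ]
      rb <- pb[pb$frame == f, ]
      if (!nrow(ra) || !nrow(rb)) next
      cand <- expand.grid(i = seq_len(nrow(ra)), j = seq_len(nrow(rb)))
      dx <- ra$x_um[cand$i] - rb$x_um[cand$j]
      dy <- ra$y_um[cand$i] - rb$y_um[cand$j]
      if (per) {
        dx <- dx - round(dx / W) * W
        dy <- dy - round(dy / H) * H
      }
      cand$d2 <- dx^2 + dy^2
      cand <- cand[cand$d2 <= radius_um^2, , drop = FALSE]
      if (!nrow(cand)) next
      cand <- cand[order(cand$d2, rb$track_id[cand$j]), , drop = FALSE]
      ua <- character(0); ub <- character(0)
      for (r in seq_len(nrow(cand))) {
        ai <- as.character(ra$track_id[cand$i[r]])
        bi <- as.character(rb$track_id[cand$j[r]])
        if (ai %in% ua || bi %in% ub) next
        ua <- c(ua, ai); ub <- c(ub, bi)
        pairs[[length(pairs) + 1L]] <- data.frame(
          frame = f, a_track = as.integer(ai), b_track = as.integer(bi))
      }
    }
    if (!length(pairs)) next
    m <- do.call(rbind, pairs)
    m <- m[order(m$a_track, m$b_track, m$frame), ]
    for (key in unique(paste(m$a_track, m$b_track))) {
      mm <- m[paste(m$a_track, m$b_track) == key, ]
      brk <- c(TRUE, diff(mm$frame) > 1L + max_gap)
      grp <- cumsum(brk)
      for (g in unique(grp)) {
        fr <- mm$frame[grp == g]
        la <- max(pa$frame[pa$track_id == mm$a_track[1]])
        lb <- max(pb$frame[pb$track_id == mm$b_track[1]])
        out[[length(out) + 1L]] <- data.frame(
          field_id = fid, a_track = mm$a_track[1], b_track = mm$b_track[1],
          start_frame = min(fr), end_frame = max(fr),
          duration_frames = max(fr) - min(fr) + 1L,
          right_censored = max(fr) >= a$n_frames - 1L ||
            max(fr) >= la || max(fr) >= lb)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(field_id = character(0), a_track = integer(0),
                      b_track = integer(0), start_frame = integer(0),
                      end_frame = integer(0), duration_frames = integer(0),
                      right_censored = logical(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start_frame, res$a_track, res$b_track), ]
}

# canonical ordering for event-table comparison
sort_events <- function(ev) {
  ev <- ev[order(ev$field_id, ev$a_track, ev$b_track, ev$start_frame), ]
  rownames(ev) <- NULL
  ev[, c("field_id", "a_track", "b_track", "start_frame", "end_frame",
         "duration_frames", "right_censored")]
}

# random track fixture: n_a/n_b particles random-walking (non-periodic)
random_fixture <- function(n_a, n_b, n_frames, seed, width = 5, height = 5,
                           d = 0.05, dt = 0.033, p_present = 0.9) {
  set.seed(seed)
  mk <- function(n, chan) {
    rows <- lapply(seq_len(n), function(i) {
      x <- cumsum(c(runif(1, 0, width), rnorm(n_frames - 1, 0, sqrt(2 * d * dt))))
      y <- cumsum(c(runif(1, 0, height), rnorm(n_frames - 1, 0, sqrt(2 * d * dt))))
      x <- pmin(pmax(x, 0), width); y <- pmin(pmax(y, 0), height)
      keep <- runif(n_frames) < p_present
      keep[1] <- TRUE
      data.frame(field_id = "FX", channel = chan, track_id = i,
                 frame = which(keep) - 1L, x_um = x[keep], y_um = y[keep],
                 intensity = 1000)
    })
    do.call(rbind, rows)
  }
  list(a = track_set(mk(n_a, "A"), width, height, dt, n_frames),
       b = track_set(mk(n_b, "B"), width, height, dt, n_frames))
}

# build a track_set from a compact per-track spec list:
# list(list(channel=, id=, frames=, x=, y=), ...)
make_tracks <- function(specs, width = 10, height = 10, dt = 0.033,
                        n_frames = NULL, periodic = FALSE) {
  rows <- lapply(specs, function(s) {
    data.frame(field_id = s$field_id %||% "F1", channel = s$channel,
               track_id = s$id, frame = s$frames, x_um = s$x, y_um = s$y,
               intensity = s$intensity %||% 1000)
  })
  locs <- do.call(rbind, rows)
  track_set(locs, width, height, dt,
            n_frames %||% (max(locs$frame) + 1L), periodic = periodic)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
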