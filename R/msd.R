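#' Time-averaged mean squared displacement of a single trajectory
#'
#' TAMSD(n dt) = < |r(t + n dt) - r(t)|^2 >_t, averaged over every pair of
#' localizations n frames apart that are both present (missing frames are
#' simply excluded from the average). Lags run from one frame up to
#' `max_lag_fraction` of the track's frame span. For tracks simulated on a
#' periodic field, consecutive steps are unwrapped with the minimal-image
#' convention before displacements are accumulated, so boundary crossings do
#' not inflate the MSD.
#'
#' @param track data.frame with columns `frame`, `x_um`, `y_um` (one track).
#' @param dt_s frame interval, seconds.
#' @param max_lag_fraction largest lag as a fraction of the track span.
#' @param periodic unwrap steps on a torus of size `width` x `height`.
#' @param width,height field dimensions (um), required when `periodic`.
#' @return object of class `msd_profile`: `lags_s`, `tamsd_um2`, `n_pairs`
#'   (pairs averaged per lag), `n_obs`, `span_frames`.
#' @export
compute_tamsd <- function(track, dt_s, max_lag_fraction = 0.25,
                          periodic = FALSE, width = NULL, height = NULL) {
  fr <- track$frame
  if (length(fr) < 2L) stop("track must have at least 2 localizations",
                            call. = FALSE)
  span <- max(fr) - min(fr)
  # frame-indexed coordinate arrays (NA where not observed)
  idx <- fr - min(fr) + 1L
  x <- rep(NA_real_, span + 1L); y <- rep(NA_real_, span + 1L)
  if (periodic) {
    dx <- torus_diff(diff(track$x_um), width)
    dy <- torus_diff(diff(track$y_um), height)
    xs <- cumsum(c(track$x_um[1], dx))
    ys <- cumsum(c(track$y_um[1], dy))
  } else {
    xs <- track$x_um; ys <- track$y_um
  }
  x[idx] <- xs; y[idx] <- ys
  max_lag <- max(1L, floor(span * max_lag_fraction))
  tamsd <- numeric(max_lag); n_pairs <- integer(max_lag)
  for (n in seq_len(max_lag)) {
    d2 <- (x[-(1:n)] - x[1:(length(x) - n)])^2 +
      (y[-(1:n)] - y[1:(length(y) - n)])^2
    n_pairs[n] <- sum(!is.na(d2))
    tamsd[n] <- if (n_pairs[n]) mean(d2, na.rm = TRUE) else NA_real_
  }
  structure(list(lags_s = seq_len(max_lag) * dt_s, tamsd_um2 = tamsd,
                 n_pairs = n_pairs, n_obs = length(fr),
                 span_frames = span + 1L, dt_s = dt_s),
            class = "msd_profile")
}

#' Construct an MSD profile from precomputed values
#'
#' Mostly useful for closed-form checks and for fitting externally computed
#' TAMSD curves.
#' @param lags_s,tamsd_um2 lag times (s) and MSD values (um^2).
#' @param n_pairs pairs averaged per lag (fit weights); defaults to equal.
#' @param span_frames underlying track length in frames.
#' @export
msd_profile <- function(lags_s, tamsd_um2, n_pairs = NULL,
                        span_frames = length(lags_s) + 1L) {
  structure(list(lags_s = lags_s, tamsd_um2 = tamsd_um2,
                 n_pairs = n_pairs %||% rep(1L, length(lags_s)),
                 n_obs = span_frames, span_frames = span_frames,
                 dt_s = if (length(lags_s) > 1) diff(lags_s[1:2]) else lags_s[1]),
            class = "msd_profile")
}

#' Diffusion coefficient from the short-lag TAMSD slope
#'
#' Weighted least-squares fit of `TAMSD = 4 D t + c` over the first
#' `n_fit_points` lags, the intercept absorbing the static localization
#' variance (4 sigma^2 for isotropic noise of s.d. sigma per axis). Only
#' tracks of at least `min_track_frames` frames qualify; shorter tracks
#' return `qualifies = FALSE` rather than an error so population summaries
#' can report how many tracks entered. A negative fitted slope is clipped to
#' `D = 0` and flagged.
#'
#' @param profile an `msd_profile`.
#' @param n_fit_points lags used in the fit (default 4).
#' @param min_track_frames minimum track span in frames (default 100).
#' @return list `d_um2_s`, `intercept_um2`, `clipped`, `qualifies`,
#'   `n_points_fit`.
#' @export
estimate_d <- function(profile, n_fit_points = 4L, min_track_frames = 100L) {
  if (profile$span_frames < min_track_frames) {
    return(list(d_um2_s = NA_real_, intercept_um2 = NA_real_,
                clipped = FALSE, qualifies = FALSE,
                n_points_fit = 0L))
  }
  np <- min(n_fit_points, sum(is.finite(profile$tamsd_um2)))
  if (np < 2L) stop("need at least 2 finite TAMSD points to fit",
                    call. = FALSE)
  i <- which(is.finite(profile$tamsd_um2))[seq_len(np)]
  fit <- stats::lm.wfit(cbind(1, profile$lags_s[i]),
                        profile$tamsd_um2[i],
                        w = as.numeric(profile$n_pairs[i]))
  slope <- fit$coefficients[2]
  d <- slope / 4
  clipped <- FALSE
  if (!is.finite(d)) stop("diffusion fit failed", call. = FALSE)
  if (d < 0) { d <- 0; clipped <- TRUE }
  list(d_um2_s = unname(d), intercept_um2 = unname(fit$coefficients[1]),
       clipped = clipped, qualifies = TRUE, n_points_fit = np)
}

#' Per-track diffusion coefficients for a whole track set
#'
#' @param ts a [track_set()].
#' @param n_fit_points,min_track_frames as in [estimate_d()].
#' @param max_lag_fraction as in [compute_tamsd()].
#' @return data.frame with one row per track: ids, `n_frames_span`,
#'   `d_um2_s`, `qualifies`.
#' @export
track_diffusion <- function(ts, n_fit_points = 4L, min_track_frames = 100L,
                            max_lag_fraction = 0.25) {
  trs <- split_tracks(ts)
  rows <- lapply(trs, function(tr) {
    span <- max(tr$frame) - min(tr$frame) + 1L
    d <- NA_real_; q <- FALSE
    if (nrow(tr) >= 2L && span >= min_track_frames) {
      prof <- compute_tamsd(tr, ts$dt_s, max_lag_fraction,
                            periodic = ts$periodic,
                            width = ts$field_width_um,
                            height = ts$field_height_um)
      est <- estimate_d(prof, n_fit_points, min_track_frames)
      d <- est$d_um2_s; q <- est$qualifies
    }
    data.frame(field_id = tr$field_id[1], channel = tr$channel[1],
               track_id = tr$track_id[1], n_frames_span = span,
               d_um2_s = d, qualifies = q)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
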