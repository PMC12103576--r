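#' Sliding-window confinement classification of a single trajectory
#'
#' Implements the probability-level confinement test: for each window of
#' `window_frames` consecutive localizations, the maximal displacement R
#' from the window's first position is compared with what free diffusion at
#' `d_reference` would produce over the window duration t, through the
#' probability `psi = exp(0.2048 - 2.5117 * D t / R^2)` (valid for psi below
#' ~0.1; larger values are treated as "not confined"). The confinement index
#' of a window is `L = -log10(psi) - 1` where `psi <= 0.1`, else 0; each
#' frame receives the average L over all windows covering it. Frames whose
#' averaged index exceeds `threshold_L` in runs of at least
#' `min_confined_frames` are marked confined; the first and last
#' half-windows, where the index cannot be computed symmetrically, are
#' marked undefined.
#'
#' @param track data.frame with `frame`, `x_um`, `y_um` (one track).
#' @param dt_s frame interval, seconds.
#' @param d_reference free diffusion coefficient used as the null, um^2/s.
#' @param window_frames sliding window length in localizations (default 30).
#' @param threshold_L confinement-index threshold (default 0.5).
#' @param min_confined_frames minimum run length kept as confined.
#' @param periodic,width,height unwrapping, as in [compute_tamsd()].
#' @return object of class `conf_annotation`: `frames`, `state` (factor
#'   confined/free/undefined), `L` (per-frame index), and
#'   `confined_intervals`.
#' @export
classify_confinement <- function(track, dt_s, d_reference,
                                 window_frames = 30L, threshold_L = 0.5,
                                 min_confined_frames = 10L,
                                 periodic = FALSE, width = NULL,
                                 height = NULL) {
  if (!is.numeric(d_reference) || d_reference <= 0) {
    stop("d_reference must be > 0", call. = FALSE)
  }
  n <- nrow(track)
  if (n < window_frames) {
    stop("track shorter than the confinement window", call. = FALSE)
  }
  fr <- track$frame
  if (periodic) {
    dx <- torus_diff(diff(track$x_um), width)
    dy <- torus_diff(diff(track$y_um), height)
    x <- cumsum(c(track$x_um[1], dx))
    y <- cumsum(c(track$y_um[1], dy))
  } else {
    x <- track$x_um; y <- track$y_um
  }
  w <- window_frames
  n_win <- n - w + 1L
  Lsum <- numeric(n); Lcnt <- numeric(n)
  for (s in seq_len(n_win)) {
    j <- s:(s + w - 1L)
    r2 <- max((x[j] - x[s])^2 + (y[j] - y[s])^2)
    t_w <- (fr[s + w - 1L] - fr[s]) * dt_s
    if (r2 <= 0) {
      Lw <- Inf  # zero excursion: infinitely unlikely under free diffusion
    } else {
      log_psi <- 0.2048 - 2.5117 * d_reference * t_w / r2
      psi <- exp(log_psi)
      Lw <- if (psi <= 0.1) -log_psi / log(10) - 1 else 0
    }
    Lsum[j] <- Lsum[j] + Lw
    Lcnt[j] <- Lcnt[j] + 1
  }
  L <- Lsum / Lcnt
  half <- floor(w / 2)
  defined <- rep(TRUE, n)
  defined[seq_len(min(half, n))] <- FALSE
  defined[seq.int(n - min(half, n) + 1L, n)] <- FALSE

  above <- L > threshold_L & defined
  state <- rep("free", n)
  runs <- intervals_from_logical(above, seq_len(n))
  for (k in seq_len(nrow(runs))) {
    span <- fr[runs$end_frame[k]] - fr[runs$start_frame[k]] + 1L
    if (span >= min_confined_frames) {
      state[runs$start_frame[k]:runs$end_frame[k]] <- "confined"
    }
  }
  state[!defined] <- "undefined"
  conf_iv <- intervals_from_logical(state == "confined", fr)
  structure(list(frames = fr, state = state, L = L,
                 confined_intervals = conf_iv,
                 params = list(window_frames = w, threshold_L = threshold_L,
                               min_confined_frames = min_confined_frames,
                               d_reference = d_reference)),
            class = "conf_annotation")
}

#' Confinement annotation of every track in a set
#'
#' Applies [classify_confinement()] track by track and returns a long table
#' of per-frame states. The reference diffusion coefficient is, by default,
#' the population median of the per-track fitted D over qualifying tracks
#' (free diffusion reference); `d_mode = "track"` uses each track's own
#' fitted D instead, falling back to the population median for short tracks.
#' Tracks shorter than the window are skipped (no states emitted).
#'
#' @param ts a [track_set()].
#' @param d_reference explicit reference D (um^2/s); overrides `d_mode`.
#' @param d_mode "population" (default) or "track".
#' @param window_frames,threshold_L,min_confined_frames see
#'   [classify_confinement()].
#' @param min_track_frames_d track length required for a track-own D fit.
#' @return data.frame `field_id, channel, track_id, frame, state, L`.
#' @export
annotate_confinement <- function(ts, d_reference = NULL,
                                 d_mode = c("population", "track"),
                                 window_frames = 30L, threshold_L = 0.5,
                                 min_confined_frames = 10L,
                                 min_track_frames_d = 100L) {
  d_mode <- match.arg(d_mode)
  trs <- split_tracks(ts)
  d_tab <- NULL; pop_d <- d_reference
  if (is.null(d_reference)) {
    d_tab <- track_diffusion(ts, min_track_frames = min_track_frames_d)
    ok <- d_tab$qualifies & is.finite(d_tab$d_um2_s) & d_tab$d_um2_s > 0
    if (!any(ok)) stop("no qualifying tracks to estimate a reference D; ",
                       "supply d_reference", call. = FALSE)
    pop_d <- stats::median(d_tab$d_um2_s[ok])
    if (d_mode == "track") {
      key <- paste(d_tab$field_id, d_tab$channel, d_tab$track_id)
      d_own <- stats::setNames(ifelse(ok, d_tab$d_um2_s, pop_d), key)
    }
  }
  rows <- lapply(trs, function(tr) {
    if (nrow(tr) < window_frames) return(NULL)
    dref <- if (is.null(d_reference) && d_mode == "track") {
      unname(d_own[paste(tr$field_id[1], tr$channel[1], tr$track_id[1])])
    } else pop_d
    ann <- classify_confinement(tr, ts$dt_s, dref, window_frames,
                                threshold_L, min_confined_frames,
                                periodic = ts$periodic,
                                width = ts$field_width_um,
                                height = ts$field_height_um)
    data.frame(field_id = tr$field_id[1], channel = tr$channel[1],
               track_id = tr$track_id[1], frame = ann$frames,
               state = ann$state, L = ann$L)
  })
  out <- data.table::rbindlist(rows)
  as.data.frame(out)
}

#' Per-cell confinement proportions with bootstrap confidence intervals
#'
#' The per-cell (field) proportion of classifiable frames in the confined
#' state, summarized per condition as the median across cells with a
#' seeded percentile bootstrap CI. The cell, not the track, is the
#' resampling unit, matching how per-cell n is reported in single-molecule
#' imaging studies.
#'
#' @param ann long annotation table ([annotate_confinement()]); may carry a
#'   `condition` column, otherwise all rows form one group.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @return list with `per_cell` (condition, field_id, proportion) and
#'   `summary` (condition, median, ci_lower, ci_upper, n_cells).
#' @export
confinement_proportions <- function(ann, n_boot = 1000L, seed = 1L) {
  dt <- data.table::as.data.table(ann)
  if (!"condition" %in% names(dt)) dt[, condition := "all"]
  dt <- dt[state != "undefined"]
  if (nrow(dt) == 0L) stop("no classifiable frames", call. = FALSE)
  per_cell <- dt[, .(proportion = mean(state == "confined"), n_frames = .N),
                 by = .(condition, field_id)]
  groups <- unique(per_cell$condition)
  summ <- lapply(seq_along(groups), function(gi) {
    g <- groups[gi]
    v <- per_cell$proportion[per_cell$condition == g]
    if (!length(v)) stop("empty group: ", g, call. = FALSE)
    ci <- boot_ci(v, n_boot = n_boot, seed = seed + gi)
    data.frame(condition = g, median = ci$estimate, ci_lower = ci$lower,
               ci_upper = ci$upper, n_cells = length(v))
  })
  list(per_cell = as.data.frame(per_cell), summary = do.call(rbind, summ))
}
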