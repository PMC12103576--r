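#' Random-colocalization null distribution
#'
#' Runs colocalization detection on a control channel pair with no true
#' interactions (e.g. a receptor of similar mobility co-imaged with the B
#' channel, or a simulated field with zero binding hazard) and returns the
#' duration distribution of the purely random colocalizations, normalized to
#' a probability kernel. This distribution is the point-spread function that
#' smears true interaction times into observed colocalization times.
#'
#' @param control_a,control_b [track_set()]s of the non-interacting pair.
#' @param search_radius_um search radius, um; must equal the one used for
#'   the condition of interest.
#' @param max_gap_frames gap tolerance, as in [detect_colocalizations()].
#' @return a `dwell_dist` of kind `"null"`; its `counts` sum to 1.
#' @export
null_distribution <- function(control_a, control_b, search_radius_um = 0.15,
                              max_gap_frames = 0L) {
  ev <- detect_colocalizations(control_a, control_b, search_radius_um,
                               max_gap_frames)
  ev <- ev[!ev$right_censored, , drop = FALSE]
  if (nrow(ev) == 0L) {
    stop("no random colocalization events in the control pair; ",
         "null distribution unidentifiable", call. = FALSE)
  }
  nd <- dwell_distribution(ev, control_a$dt_s, min_duration_frames = 1L,
                           kind = "null")
  nd$counts <- nd$counts / sum(nd$counts)
  nd
}

#' Convolve a dwell distribution with a null kernel
#'
#' Forward model of the observed colocalization times: an event with true
#' duration `t` frames is observed with duration `t + o` frames, where the
#' random prolongation `o >= 0` has probability `kernel[o + 1]` -- i.e. the
#' first bin of the null corresponds to zero prolongation, so a null
#' concentrated in its first bin leaves the distribution unchanged.
#'
#' @param counts numeric vector of true-duration counts (index = frames).
#' @param kernel null kernel (`counts` of a normalized null `dwell_dist`).
#' @return convolved counts, same length as `counts`.
#' @export
convolve_dwell <- function(counts, kernel) {
  K <- length(counts)
  kern <- kernel / sum(kernel)
  out <- numeric(K)
  for (t in seq_len(K)) {
    if (counts[t] == 0) next
    omax <- min(K - t, length(kern) - 1L)
    idx <- t + 0:omax
    out[idx] <- out[idx] + counts[t] * kern[1:(omax + 1L)]
  }
  out
}

# lower-triangular Toeplitz convolution matrix: obs = C %*% true
conv_matrix <- function(kernel, K) {
  kern <- kernel / sum(kernel)
  kern <- c(kern, numeric(max(0L, K - length(kern))))[1:K]
  C <- matrix(0, K, K)
  for (t in seq_len(K)) {
    C[t:K, t] <- kern[1:(K - t + 1L)]
  }
  C
}

#' Lucy-Richardson deconvolution of observed colocalization times
#'
#' Iteratively recovers the true interaction-time distribution from the
#' observed colocalization-time distribution, using the random-colocalization
#' null as the (shift-invariant, one-sided) point-spread kernel over the
#' duration axis. The multiplicative update preserves nonnegativity and
#' total mass. Iteration stops at `n_iterations` or when the relative L1
#' change drops below `tol`; deconvolution lacks an intrinsic stopping rule
#' and over-iteration amplifies histogram noise, so both knobs are recorded
#' in the result.
#'
#' @param observed `dwell_dist` of kind "observed".
#' @param null `dwell_dist` of kind "null" (normalized kernel).
#' @param n_iterations maximum iterations (default 50).
#' @param tol relative-change early-stopping threshold.
#' @return `dwell_dist` of kind "deconvolved"; counts are nonnegative reals
#'   summing to `observed$n_events`, censoring bookkeeping carried over.
#' @export
deconvolve_dwells <- function(observed, null, n_iterations = 50L,
                              tol = 1e-6) {
  if (!isTRUE(all.equal(observed$bin_width_s, null$bin_width_s))) {
    stop("observed and null must share the bin width", call. = FALSE)
  }
  if (sum(null$counts) <= 0) stop("null kernel has zero mass", call. = FALSE)
  obs <- observed$counts
  if (sum(obs) <= 0) stop("observed distribution is empty", call. = FALSE)
  K <- length(obs)
  C <- conv_matrix(null$counts, K)
  s <- colSums(C)
  s[s == 0] <- 1
  f <- obs
  eps <- 1e-12
  iters_run <- n_iterations
  for (it in seq_len(n_iterations)) {
    est <- as.vector(C %*% f)
    ratio <- obs / pmax(est, eps)
    f_new <- f * as.vector(crossprod(C, ratio)) / s
    delta <- sum(abs(f_new - f)) / max(sum(f), eps)
    f <- f_new
    if (delta < tol) { iters_run <- it; break }
  }
  out <- observed
  out$kind <- "deconvolved"
  out$counts <- f * (observed$n_events / sum(f))
  out$n_events <- observed$n_events
  out$iterations <- iters_run
  out
}

# censored geometric/exponential MLE on (possibly real-valued) duration
# weights; returns the per-frame continuation estimate and koff
koff_mle <- function(counts, censored_frames, dt_s, min_duration_frames) {
  dmin <- min_duration_frames
  d <- seq_along(counts)
  keep <- d >= dmin & counts > 0
  w <- counts[keep]; dv <- d[keep]
  cens <- censored_frames[censored_frames >= dmin]
  W_u <- sum(w)
  if (W_u + length(cens) < 1) stop("no events at or above the minimum duration",
                                   call. = FALSE)
  if (W_u == 0) stop("all usable events are right-censored; ",
                     "dissociation rate unidentifiable", call. = FALSE)
  S <- sum(w * (dv - dmin)) + sum(cens - dmin)
  p_hat <- W_u / (W_u + S)
  p_hat <- min(p_hat, 1 - 1e-12)
  -log(1 - p_hat) / dt_s
}

#' Dissociation rate constant from a deconvolved dwell distribution
#'
#' Fits a single-exponential (geometric at the frame resolution) dwell model
#' by maximum likelihood to the deconvolved interaction-time distribution,
#' restricted to durations of at least `min_duration_frames`. Right-censored
#' events contribute survival terms, which matters whenever interaction
#' times approach the observation window. With event durations `d_i`
#' (frames) and left truncation at `d_min`, the continuation probability
#' estimate is `p = W_u / (W_u + sum w_i (d_i - d_min))` over uncensored
#' mass `W_u` plus censored terms in the denominator, and
#' `koff = -log(1 - p) / dt`, which is exact for geometric dwells.
#'
#' @param deconvolved `dwell_dist` (kind "deconvolved"; an observed
#'   distribution works too when no random-colocalization correction is
#'   needed).
#' @param min_duration_frames left-truncation threshold (frames).
#' @param min_events minimum effective event mass required.
#' @return list with `koff_per_s` and `mean_dwell_s = 1/koff`.
#' @export
estimate_koff <- function(deconvolved, min_duration_frames = 2L,
                          min_events = 20) {
  eff <- sum(deconvolved$counts[seq_along(deconvolved$counts) >=
                                  min_duration_frames])
  if (eff < min_events) {
    stop(sprintf("only %.1f effective events (need >= %g)", eff, min_events),
         call. = FALSE)
  }
  k <- koff_mle(deconvolved$counts, deconvolved$censored_frames,
                deconvolved$bin_width_s, min_duration_frames)
  list(koff_per_s = k, mean_dwell_s = 1 / k)
}

#' Association rate constant normalized by molecule counts and density
#'
#' `kon = N_events / sum_fields(T_field * N_A_field * rho_B_field)` with
#' `N_A` the time-averaged number of channel-A molecules in the field and
#' `rho_B` the time-averaged channel-B surface density, giving
#' um^2 molecule^-1 s^-1.
#'
#' @param events_true_count number of true interaction events (deconvolved
#'   mass at or above the minimum duration, plus censored events).
#' @param tracks_a,tracks_b the two channels' [track_set()]s (all fields of
#'   the condition).
#' @return kon, um^2 molecule^-1 s^-1.
#' @export
estimate_kon <- function(events_true_count, tracks_a, tracks_b) {
  denom <- kon_denominator(tracks_a, tracks_b)
  if (denom <= 0) stop("zero molecule density in one channel", call. = FALSE)
  events_true_count / denom
}

# sum over fields of T * N_A * rho_B, optionally restricted to given fields
# (with multiplicity, for bootstrap resampling)
kon_denominator <- function(tracks_a, tracks_b, fields = NULL) {
  area <- field_area(tracks_a)
  T_field <- tracks_a$n_frames * tracks_a$dt_s
  ca <- tracks_a$tracks[, .N, by = field_id]
  cb <- tracks_b$tracks[, .N, by = field_id]
  n_a <- stats::setNames(ca$N / tracks_a$n_frames, ca$field_id)
  rho_b <- stats::setNames(cb$N / tracks_b$n_frames / area, cb$field_id)
  if (is.null(fields)) fields <- names(n_a)
  fields <- as.character(fields)
  sum(T_field * n_a[fields] * rho_b[fields], na.rm = TRUE)
}

#' Full kinetics estimate with per-cell bootstrap confidence intervals
#'
#' Orchestrates the dwell-time pipeline for one condition: pools the
#' observed colocalization events over cells (fields), deconvolves with the
#' random-colocalization null, fits the censored exponential dissociation
#' rate, and normalizes the true event count into an association rate
#' constant. 95% confidence intervals come from a percentile bootstrap that
#' resamples cells and repeats the entire deconvolution + fit.
#'
#' @param events event table for the condition ([detect_colocalizations()]).
#' @param tracks_a,tracks_b the condition's channel track sets.
#' @param null normalized null `dwell_dist` ([null_distribution()]).
#' @param min_duration_frames events shorter than this (frames) are treated
#'   as noise-dominated and never contribute directly (default 2).
#' @param fit_min_frames left-truncation cut (frames) for the rate fit and
#'   the true-event count (default 6). Deconvolution removes random
#'   colocalizations only imperfectly at the shortest durations, where true
#'   and random events are statistically confusable; fitting above the cut
#'   and correcting the count by the fitted survival `S(cut)` removes that
#'   contamination. The result is insensitive to the cut over roughly
#'   4-12 frames.
#' @param n_iterations Lucy-Richardson iterations.
#' @param n_boot bootstrap resamples over cells (default 1000).
#' @param seed seed for the bootstrap.
#' @return object of class `kinetics_estimate`.
#' @export
estimate_kinetics <- function(events, tracks_a, tracks_b, null,
                              min_duration_frames = 2L,
                              fit_min_frames = 6L, n_iterations = 50L,
                              n_boot = 1000L, seed = 1L) {
  dt_s <- tracks_a$dt_s
  cells <- sort(unique(events$field_id))
  if (length(cells) == 0L) stop("no events supplied", call. = FALSE)
  cut <- max(fit_min_frames, min_duration_frames)

  fit_once <- function(ev, fields) {
    # deconvolve the full observed histogram (including single-frame events,
    # which pin down the random component); truncation cuts apply to the
    # deconvolved distribution when fitting kinetics
    obs <- dwell_distribution(ev, dt_s, min_duration_frames = 1L)
    dec <- deconvolve_dwells(obs, null, n_iterations)
    k <- koff_mle(dec$counts, dec$censored_frames, dt_s, cut)
    # true-event count: deconvolved mass above the cut, scaled back up by
    # the fitted dwell survival to undo the truncation
    surv <- (1 - (1 - exp(-k * dt_s)))^(cut - 1L)
    mass <- sum(dec$counts[seq_along(dec$counts) >= cut]) +
      sum(dec$censored_frames >= cut)
    n_true <- mass / surv
    kon <- n_true / kon_denominator(tracks_a, tracks_b, fields)
    c(koff = k, kon = kon, n_true = n_true)
  }

  pt <- fit_once(events, cells)
  ev_by_cell <- split(as.data.frame(events), events$field_id)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, 2,
                  dimnames = list(NULL, c("koff", "kon")))
  for (b in seq_len(n_boot)) {
    pick <- sample(cells, replace = TRUE)
    ev_b <- do.call(rbind, ev_by_cell[as.character(pick)])
    res <- tryCatch(fit_once(ev_b, pick), error = function(e) c(NA, NA, NA))
    boots[b, ] <- res[1:2]
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)

  ci <- function(col, est) {
    q <- stats::quantile(boots[, col], c(0.025, 0.975), na.rm = TRUE,
                         names = FALSE)
    c(min(q[1], est), max(q[2], est))
  }
  obs <- dwell_distribution(events, dt_s, min_duration_frames)
  structure(list(
    kon_um2_per_molecule_s = unname(pt["kon"]),
    koff_per_s = unname(pt["koff"]),
    mean_dwell_s = unname(1 / pt["koff"]),
    ci95_kon = ci("kon", pt["kon"]),
    ci95_koff = ci("koff", pt["koff"]),
    n_cells = length(cells),
    n_events = obs$n_events,
    n_censored = obs$n_censored,
    n_true_events = unname(pt["n_true"]),
    method = list(lr_iterations = n_iterations,
                  min_duration_frames = min_duration_frames,
                  fit_min_frames = cut,
                  n_boot = n_boot, seed = seed)
  ), class = "kinetics_estimate")
}

#' @export
print.kinetics_estimate <- function(x, ...) {
  cat("<kinetics_estimate>\n")
  cat(sprintf("  kon : %.3g um^2 molecule^-1 s^-1 (95%% CI %.3g - %.3g)\n",
              x$kon_um2_per_molecule_s, x$ci95_kon[1], x$ci95_kon[2]))
  cat(sprintf("  koff: %.3g s^-1 (95%% CI %.3g - %.3g); mean dwell %.3g s\n",
              x$koff_per_s, x$ci95_koff[1], x$ci95_koff[2], x$mean_dwell_s))
  cat(sprintf("  %d cells, %d events (%d censored), %.1f true events\n",
              x$n_cells, x$n_events, x$n_censored, x$n_true_events))
  invisible(x)
}

#' Classify interaction events as co-confined, co-diffusing, or mixed
#'
#' During each colocalization event, frames where both partners have a
#' defined confinement state are polled: the event is co-confined when both
#' partners are confined for at least `majority_fraction` of those frames,
#' co-diffusing when both are free for at least that fraction, otherwise
#' mixed. Events without any classifiable frame are reported as undefined.
#'
#' @param events event table ([detect_colocalizations()]).
#' @param ann_a,ann_b per-frame confinement annotations of the two channels
#'   ([annotate_confinement()] long tables with columns `field_id, channel,
#'   track_id, frame, state`).
#' @param majority_fraction vote threshold in (0, 1] (default 0.5).
#' @return object of class `interaction_state_summary`: the per-event state,
#'   per-cell co-confined / co-diffusing fractions, and group medians with
#'   bootstrap 95% CIs.
#' @export
classify_interaction_state <- function(events, ann_a, ann_b,
                                       majority_fraction = 0.5,
                                       n_boot = 1000L, seed = 1L) {
  ev <- data.table::as.data.table(events)
  ev[, event_id := .I]
  evf <- ev[, .(frame = seq(start_frame, end_frame)),
            by = .(event_id, field_id, a_track, b_track)]
  a <- data.table::as.data.table(ann_a)[, .(field_id, track_id, frame,
                                            state_a = state)]
  b <- data.table::as.data.table(ann_b)[, .(field_id, track_id, frame,
                                            state_b = state)]
  evf <- a[evf, on = c(field_id = "field_id", track_id = "a_track",
                       frame = "frame")]
  data.table::setnames(evf, "track_id", "a_track")
  evf <- b[evf, on = c(field_id = "field_id", track_id = "b_track",
                       frame = "frame")]
  data.table::setnames(evf, "track_id", "b_track")
  per_ev <- evf[, {
    ok <- !is.na(state_a) & !is.na(state_b) &
      state_a != "undefined" & state_b != "undefined"
    n_ok <- sum(ok)
    f_cc <- if (n_ok) sum(state_a[ok] == "confined" &
                            state_b[ok] == "confined") / n_ok else NA_real_
    f_cd <- if (n_ok) sum(state_a[ok] == "free" &
                            state_b[ok] == "free") / n_ok else NA_real_
    .(n_classifiable = n_ok, frac_both_confined = f_cc, frac_both_free = f_cd)
  }, by = .(event_id, field_id)]
  per_ev[, state := data.table::fifelse(
    n_classifiable == 0L, "undefined",
    data.table::fifelse(frac_both_confined >= majority_fraction, "co-confined",
      data.table::fifelse(frac_both_free >= majority_fraction, "co-diffusing",
                          "mixed")))]
  per_cell <- per_ev[state != "undefined",
                     .(fraction_co_confined = mean(state == "co-confined"),
                       fraction_co_diffusing = mean(state == "co-diffusing"),
                       n_events = .N),
                     by = field_id]
  if (nrow(per_cell) == 0L) {
    na2 <- c(NA_real_, NA_real_)
    return(structure(list(events = as.data.frame(per_ev),
                          per_cell = as.data.frame(per_cell),
                          fraction_co_confined = NA_real_,
                          ci95_co_confined = na2,
                          fraction_co_diffusing = NA_real_,
                          ci95_co_diffusing = na2,
                          n_undefined = sum(per_ev$state == "undefined")),
                     class = "interaction_state_summary"))
  }
  cc <- boot_ci(per_cell$fraction_co_confined, n_boot = n_boot, seed = seed)
  cd <- boot_ci(per_cell$fraction_co_diffusing, n_boot = n_boot, seed = seed + 1L)
  structure(list(
    events = as.data.frame(per_ev),
    per_cell = as.data.frame(per_cell),
    fraction_co_confined = cc$estimate,
    ci95_co_confined = c(cc$lower, cc$upper),
    fraction_co_diffusing = cd$estimate,
    ci95_co_diffusing = c(cd$lower, cd$upper),
    n_undefined = sum(per_ev$state == "undefined")
  ), class = "interaction_state_summary")
}

#' @export
print.interaction_state_summary <- function(x, ...) {
  cat("<interaction_state_summary>\n")
  cat(sprintf("  co-confined : median %.3f (95%% CI %.3f - %.3f)\n",
              x$fraction_co_confined, x$ci95_co_confined[1],
              x$ci95_co_confined[2]))
  cat(sprintf("  co-diffusing: median %.3f (95%% CI %.3f - %.3f)\n",
              x$fraction_co_diffusing, x$ci95_co_diffusing[1],
              x$ci95_co_diffusing[2]))
  invisible(x)
}
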