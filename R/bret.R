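#' Simulate a BRET kinetic plate
#'
#' Per-well BRET ratio time series mimicking a ligand-stimulation
#' experiment: `n_pre_reads` basal reads before stimulation at t = 0, then
#' `n_post_reads` reads at `read_interval_s`. Stimulated wells respond with
#' a mono-exponential rise `amplitude * (1 - exp(-rate * t))`; a shared
#' linear vehicle drift (substrate decay, temperature) affects all wells
#' post-stimulation; Gaussian noise is added to every read. Half the wells
#' are stimulated, half vehicle.
#'
#' @param n_wells total wells (>= 2, even).
#' @param baseline_level basal BRET ratio.
#' @param response_amplitude plateau of the stimulated ratio increase.
#' @param response_rate rise rate, 1/s.
#' @param vehicle_drift shared linear drift of the ratio, 1/s.
#' @param noise_sigma read noise s.d. (ratio units).
#' @param n_pre_reads,n_post_reads reads before/after stimulation.
#' @param read_interval_s time between reads, seconds (default 120).
#' @param seed integer seed.
#' @return tidy data.frame: `well, condition, time_s, bret_ratio` (pre-reads
#'   have negative `time_s`; stimulation at t = 0).
#' @export
simulate_bret_plate <- function(n_wells = 6L, baseline_level = 0.1,
                                response_amplitude = 0.05,
                                response_rate = 1 / 150,
                                vehicle_drift = 0, noise_sigma = 0.002,
                                n_pre_reads = 3L, n_post_reads = 30L,
                                read_interval_s = 120, seed = 1L) {
  if (n_pre_reads < 1L) stop("need at least 1 pre-stimulation read",
                             call. = FALSE)
  set.seed(seed)
  times <- c(-(n_pre_reads:1), seq_len(n_post_reads)) * read_interval_s
  cond <- rep(c("stimulated", "vehicle"), length.out = n_wells)
  rows <- lapply(seq_len(n_wells), function(wi) {
    post <- pmax(times, 0)
    resp <- if (cond[wi] == "stimulated") {
      response_amplitude * (1 - exp(-response_rate * post)) * (times > 0)
    } else 0
    ratio <- baseline_level + resp + vehicle_drift * post +
      stats::rnorm(length(times), 0, noise_sigma)
    data.frame(well = sprintf("W%02d", wi), condition = cond[wi],
               time_s = times, bret_ratio = ratio)
  })
  do.call(rbind, rows)
}

#' Double-baseline-corrected Delta-BRET kinetics
#'
#' Applies the two corrections used for kinetic BRET traces: first each
#' well's mean pre-stimulation ratio (reads at `time_s < 0`) is subtracted
#' (well baseline), then the per-time-point mean of the baseline-corrected
#' vehicle wells is subtracted from every well (vehicle control), so any
#' well-constant offset and any plate-wide time-varying drift cancel
#' exactly.
#'
#' @param table tidy kinetic table: `well, condition, time_s` and either
#'   `bret_ratio` or `donor_counts` + `acceptor_counts` (the ratio is then
#'   acceptor/donor). Vehicle wells must have `condition == "vehicle"`.
#' @return list with `per_well` (well-level Delta-BRET trace) and `summary`
#'   (per condition and time: mean, SEM, n).
#' @export
delta_bret <- function(table) {
  dt <- data.table::as.data.table(table)
  if (!"bret_ratio" %in% names(dt)) {
    if (!all(c("donor_counts", "acceptor_counts") %in% names(dt))) {
      stop("table needs bret_ratio or donor_counts + acceptor_counts",
           call. = FALSE)
    }
    if (any(dt$donor_counts <= 0)) stop("donor_counts must be positive",
                                        call. = FALSE)
    dt[, bret_ratio := acceptor_counts / donor_counts]
  }
  if (!any(dt$condition == "vehicle")) {
    stop("no vehicle wells on the plate", call. = FALSE)
  }
  if (!any(dt$time_s < 0)) {
    stop("no pre-stimulation reads (time_s < 0)", call. = FALSE)
  }
  dt[, baseline := mean(bret_ratio[time_s < 0]), by = well]
  dt[, corrected := bret_ratio - baseline]
  veh <- dt[condition == "vehicle",
            .(vehicle_mean = mean(corrected)), by = time_s]
  dt <- veh[dt, on = "time_s"]
  dt[, delta_bret := corrected - vehicle_mean]
  per_well <- as.data.frame(dt[, .(well, condition, time_s, delta_bret)])
  summary <- as.data.frame(dt[, .(
    mean_delta_bret = mean(delta_bret),
    sem = stats::sd(delta_bret) / sqrt(.N), n = .N
  ), by = .(condition, time_s)])
  list(per_well = per_well, summary = summary)
}

#' Net BRET from an acceptor titration
#'
#' Baseline-corrects an acceptor-titration experiment: the mean fluorescence
#' and mean BRET ratio of the donor-only wells (0% acceptor expression) are
#' subtracted from every well, yielding net BRET against net acceptor
#' fluorescence.
#'
#' @param titration data.frame with `fluorescence`, `bret_ratio`, and a
#'   logical `donor_only` column marking 0%-acceptor wells.
#' @return the input with added `net_fluorescence` and `net_bret` columns.
#' @export
net_bret <- function(titration) {
  if (!any(titration$donor_only)) {
    stop("no donor-only (0% acceptor) wells", call. = FALSE)
  }
  f0 <- mean(titration$fluorescence[titration$donor_only])
  b0 <- mean(titration$bret_ratio[titration$donor_only])
  titration$net_fluorescence <- titration$fluorescence - f0
  titration$net_bret <- titration$bret_ratio - b0
  titration
}

#' Simulate a saturating acceptor-titration plate
#'
#' Net BRET follows a one-site hyperbola `bmax * x / (k50 + x)` of the net
#' acceptor fluorescence `x`, on top of background fluorescence and
#' background BRET; includes donor-only wells.
#'
#' @param n_wells titration wells (plus `n_donor_only` background wells).
#' @param bmax,k50 hyperbola plateau and half-saturation (fluorescence
#'   units).
#' @param background_fluor,background_bret additive backgrounds.
#' @param max_fluor largest acceptor fluorescence.
#' @param noise_sigma read noise on the ratio.
#' @param n_donor_only number of 0%-acceptor wells.
#' @param seed integer seed.
#' @return data.frame `well, fluorescence, bret_ratio, donor_only`.
#' @export
simulate_bret_titration <- function(n_wells = 24L, bmax = 0.3, k50 = 2e4,
                                    background_fluor = 5e3,
                                    background_bret = 0.08,
                                    max_fluor = 1e5, noise_sigma = 0,
                                    n_donor_only = 4L, seed = 1L) {
  set.seed(seed)
  x <- seq(0, max_fluor, length.out = n_wells + 1L)[-1]
  net <- bmax * x / (k50 + x)
  df <- data.frame(
    well = sprintf("T%02d", seq_len(n_wells + n_donor_only)),
    fluorescence = c(x + background_fluor, rep(background_fluor, n_donor_only)),
    bret_ratio = c(net + background_bret, rep(background_bret, n_donor_only)) +
      stats::rnorm(n_wells + n_donor_only, 0, noise_sigma),
    donor_only = rep(c(FALSE, TRUE), c(n_wells, n_donor_only)))
  df
}

#' Fit a one-site saturation hyperbola to net BRET data
#'
#' `net_bret = bmax * x / (k50 + x)`; used to extract the specific-binding
#' plateau from acceptor titrations.
#'
#' @param net data.frame with `net_fluorescence` and `net_bret` (from
#'   [net_bret()]), donor-only wells excluded automatically.
#' @return list `bmax`, `k50`.
#' @export
fit_bret_saturation <- function(net) {
  d <- net[!net$donor_only & net$net_fluorescence > 0, ]
  fit <- stats::nls(net_bret ~ bmax * net_fluorescence / (k50 + net_fluorescence),
                    data = d,
                    start = list(bmax = max(d$net_bret),
                                 k50 = stats::median(d$net_fluorescence)),
                    # scaleOffset makes convergence well-defined for
                    # noise-free (zero-residual) data
                    control = stats::nls.control(maxiter = 200,
                                                 scaleOffset = 1))
  as.list(stats::coef(fit))
}
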