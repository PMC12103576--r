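# helper: dwell_dist objects built directly from count vectors
dd_from_counts <- function(counts, dt = 0.033, kind = "observed",
                           censored = integer(0)) {
  structure(list(bin_width_s = dt, counts = as.numeric(counts),
                 n_events = sum(counts), n_censored = length(censored),
                 n_excluded_short = 0L, censored_frames = censored,
                 min_duration_frames = 1L, kind = kind),
            class = "dwell_dist")
}

test_that("a delta null kernel is the identity for deconvolution", {
  obs <- dd_from_counts(c(0, 5, 9, 4, 2, 1))
  null <- dd_from_counts(c(1, 0, 0, 0, 0, 0), kind = "null")
  dec <- deconvolve_dwells(obs, null, 50L)
  expect_equal(dec$counts, obs$counts, tolerance = 1e-8)
  expect_identical(dec$kind, "deconvolved")
})

test_that("deconvolution inverts a known forward convolution", {
  set.seed(2)
  K <- 120
  true <- 300 * stats::dgeom(0:(K - 1), prob = 0.05)   # dwell histogram
  kern <- c(0.5, 0.3, 0.15, 0.05)                      # null kernel
  obs_counts <- convolve_dwell(true, kern)
  obs <- dd_from_counts(obs_counts)
  null <- dd_from_counts(c(kern, rep(0, 10)), kind = "null")
  dec <- deconvolve_dwells(obs, null, 200L)
  tv <- sum(abs(dec$counts / sum(dec$counts) - true / sum(true))) / 2
  expect_lt(tv, 0.05)
  # round trip: re-convolving the output reproduces the observation
  back <- convolve_dwell(dec$counts, kern)
  tv2 <- sum(abs(back / sum(back) - obs_counts / sum(obs_counts))) / 2
  expect_lt(tv2, 0.02)
})

test_that("deconvolution error paths trigger", {
  obs <- dd_from_counts(c(0, 3, 2))
  expect_error(deconvolve_dwells(obs, dd_from_counts(c(0, 0, 0), kind = "null")),
               "zero mass")
  null_dt <- dd_from_counts(1, dt = 0.05, kind = "null")
  expect_error(deconvolve_dwells(obs, null_dt), "bin width")
  expect_error(deconvolve_dwells(dd_from_counts(c(0, 0)), dd_from_counts(1)),
               "empty")
})

test_that("null distribution requires control events and normalizes", {
  # far-separated static control -> no events -> error path
  far <- make_tracks(list(
    list(channel = "A", id = 1L, frames = 0:20, x = rep(1, 21), y = rep(1, 21)),
    list(channel = "B", id = 1L, frames = 0:20, x = rep(5, 21), y = rep(5, 21))
  ), n_frames = 21L)
  expect_error(null_distribution(subset_tracks(far, "A"),
                                 subset_tracks(far, "B"), 0.15),
               "unidentifiable")

  ctrl <- simulate_condition("control-pair", n_cells = 2, seed = 300)
  nd <- null_distribution(ctrl$a, ctrl$b, 0.15)
  expect_equal(sum(nd$counts), 1, tolerance = 1e-12)
  expect_identical(nd$kind, "null")
  # random colocalizations are short-lived at paper-like densities
  expect_lt(sum(nd$counts[-(1:9)]), 0.05)
})

test_that("null distribution is reproducible across independent seeds", {
  n1 <- null_distribution(
    simulate_condition("control-pair", 3, seed = 11)$a,
    simulate_condition("control-pair", 3, seed = 11)$b, 0.15)
  ctrl2 <- simulate_condition("control-pair", 3, seed = 12)
  n2 <- null_distribution(ctrl2$a, ctrl2$b, 0.15)
  k <- max(length(n1$counts), length(n2$counts))
  pad <- function(x) c(x, rep(0, k - length(x)))
  ks <- max(abs(cumsum(pad(n1$counts)) - cumsum(pad(n2$counts))))
  expect_gt(n1$n_events + n2$n_events, 2000)
  expect_lt(ks, 0.05)
})

test_that("exponential rate fits are exact on exact histograms", {
  dt <- 0.033
  p <- 1 - exp(-1.0 * dt)                 # koff = 1/s, geometric at dt bins
  counts <- 1e5 * stats::dgeom(0:399, p)  # durations 1..400 frames
  est <- estimate_koff(dd_from_counts(counts, kind = "deconvolved"),
                       min_duration_frames = 2L)
  expect_lt(abs(est$koff_per_s - 1.0), 0.01)
  expect_equal(est$koff_per_s * est$mean_dwell_s, 1, tolerance = 1e-12)

  # reciprocal worked example: koff 0.64 -> mean dwell 1.5625 s
  p64 <- 1 - exp(-0.64 * dt)
  est64 <- estimate_koff(dd_from_counts(1e5 * stats::dgeom(0:999, p64),
                                        kind = "deconvolved"))
  expect_equal(est64$mean_dwell_s, 1 / 0.64, tolerance = 1e-3)

  expect_error(estimate_koff(dd_from_counts(c(0, 5))), "effective events")
  expect_error(
    estimate_koff(dd_from_counts(rep(0, 30), censored = rep(25L, 30)),
                  min_events = 0),
    "censored")
})

test_that("censored fitting corrects the short-window bias of the naive fit", {
  set.seed(8)
  koff <- 0.3; dt <- 0.033; n_frames <- 400
  d <- rgeom(4000, 1 - exp(-koff * dt)) + 1L
  start <- sample(0:(n_frames - 1L), 4000, TRUE)
  cens <- start + d - 1L >= n_frames
  d_obs <- ifelse(cens, n_frames - start, d)
  counts <- tabulate(d_obs[!cens], nbins = n_frames)
  k_cens <- sptkin:::koff_mle(counts, d_obs[cens], dt, 2L)
  k_naive <- sptkin:::koff_mle(tabulate(d_obs, nbins = n_frames), integer(0),
                               dt, 2L)
  expect_lt(abs(k_cens - koff) / koff, 0.05)
  expect_gt(k_naive, k_cens)  # ignoring censoring overestimates the rate
})

test_that("kon normalization is arithmetic and scales with density", {
  # 10 events, T = 10 s, N_A = 10 molecules, rho_B = 0.1 /um2 -> kon = 1
  mk <- function(n_b, area_side = 10) {
    frames <- 0:99
    specs <- c(
      lapply(1:10, function(i) list(channel = "A", id = i, frames = frames,
                                    x = rep(i / 2, 100), y = rep(1, 100))),
      lapply(1:n_b, function(i) list(channel = "B", id = i, frames = frames,
                                     x = rep(i / 2, 100), y = rep(5, 100)))
    )
    ts <- make_tracks(specs, width = area_side, height = area_side,
                      dt = 0.1, n_frames = 100L)
    list(a = subset_tracks(ts, "A"), b = subset_tracks(ts, "B"))
  }
  f10 <- mk(10)
  expect_equal(estimate_kon(10, f10$a, f10$b), 1.0, tolerance = 1e-12)
  f20 <- mk(20)  # doubling rho_B halves kon at the same event count
  expect_equal(estimate_kon(10, f20$a, f20$b), 0.5, tolerance = 1e-12)
  # invariant to field area at fixed densities: 4x area, 4x molecules
  f_big <- mk(40, area_side = 20)
  ts_big_a <- make_tracks(lapply(1:40, function(i) {
    list(channel = "A", id = i, frames = 0:99, x = rep(i / 4, 100),
         y = rep(2, 100))
  }), width = 20, height = 20, dt = 0.1, n_frames = 100L)
  expect_equal(estimate_kon(40, ts_big_a, f_big$b), 1.0, tolerance = 1e-12)
})

test_that("kinetics estimates carry coherent intervals and metadata", {
  ctrl <- simulate_condition("control-pair", n_cells = 3, seed = 400)
  null <- null_distribution(ctrl$a, ctrl$b, 0.15)
  pre <- sim_preset("wnt16b-early-like", 1)
  cond <- simulate_condition(pre, n_cells = 3, seed = 401, hazard = 0.25)
  ev <- detect_colocalizations(cond$a, cond$b, 0.15, 1)
  kin <- estimate_kinetics(ev, cond$a, cond$b, null, n_boot = 50, seed = 2)
  expect_s3_class(kin, "kinetics_estimate")
  expect_true(kin$koff_per_s > 0)
  expect_equal(kin$mean_dwell_s * kin$koff_per_s, 1, tolerance = 1e-12)
  expect_true(kin$ci95_koff[1] <= kin$koff_per_s &&
                kin$koff_per_s <= kin$ci95_koff[2])
  expect_true(kin$ci95_kon[1] <= kin$kon_um2_per_molecule_s &&
                kin$kon_um2_per_molecule_s <= kin$ci95_kon[2])
  expect_identical(kin$n_cells, 3L)
  # determinism of the seeded bootstrap
  kin2 <- estimate_kinetics(ev, cond$a, cond$b, null, n_boot = 50, seed = 2)
  expect_identical(kin$ci95_koff, kin2$ci95_koff)
})
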