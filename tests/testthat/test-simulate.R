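test_that("config validation rejects impossible worlds", {
  expect_error(sim_config(density_a_per_um2 = 0.001),
               "density x area")
  expect_error(sim_config(dt_s = -1), "dt_s")
  expect_error(sim_config(dropout_prob = 1.5), "dropout_prob")
  expect_error(sim_config(d_confined_factor = 0), "d_confined_factor")
})

test_that("no association is possible with zero hazard", {
  cfg <- sim_config(kon_hazard = 0, koff_per_s = 1, seed = 3)
  sim <- simulate_field(cfg)
  expect_identical(nrow(sim$truth$bound_intervals), 0L)
})

test_that("a frozen field emits constant-position tracks", {
  cfg <- sim_config(d_free_um2_s = 0, d_bound_um2_s = 0, loc_sigma_um = 0,
                    registration_residual_um = 0, dropout_prob = 0,
                    confinement_area_fraction = 0, seed = 5)
  sim <- simulate_field(cfg)
  spread <- sim$a$tracks[, .(sx = stats::sd(x_um), sy = stats::sd(y_um),
                             n = .N), by = track_id]
  expect_true(all(spread$n == cfg$n_frames))
  expect_true(all(spread$sx == 0 & spread$sy == 0))
})

test_that("noise-free emission reproduces true positions bit for bit", {
  cfg <- sim_config(loc_sigma_um = 0, registration_residual_um = 0,
                    dropout_prob = 0, kon_hazard = 0.3, koff_per_s = 1,
                    n_frames = 100L, seed = 8)
  sim <- simulate_field(cfg)
  for (chan in c("a", "b")) {
    pos <- sim$truth[[paste0("pos_", chan)]]
    org <- sim$truth[[paste0("origin_", chan)]]
    trk <- sim[[chan]]$tracks
    expect_identical(nrow(org), length(unique(trk$track_id)))
    for (k in seq_len(nrow(org))) {
      tr <- trk[track_id == org$track_id[k]]
      expect_identical(tr$x_um, pos$x[tr$frame + 1L, org$mol_id[k]])
      expect_identical(tr$y_um, pos$y[tr$frame + 1L, org$mol_id[k]])
    }
  }
})

test_that("same seed gives identical fields, different seeds differ", {
  cfg <- sim_config(kon_hazard = 0.2, koff_per_s = 1, n_frames = 80L,
                    seed = 11)
  s1 <- simulate_field(cfg)
  s2 <- simulate_field(cfg)
  expect_identical(s1$a$tracks, s2$a$tracks)
  expect_identical(s1$b$tracks, s2$b$tracks)
  expect_identical(s1$truth$bound_intervals, s2$truth$bound_intervals)
  cfg$seed <- 12L
  expect_false(identical(simulate_field(cfg)$a$tracks, s1$a$tracks))
})

test_that("realized densities are within Poisson error of the target", {
  counts_a <- counts_b <- numeric(20)
  for (i in 1:20) {
    sim <- simulate_field(sim_config(seed = 100 + i, n_frames = 2L,
                                     dropout_prob = 0))
    counts_a[i] <- sim$truth$n_a
    counts_b[i] <- sim$truth$n_b
  }
  # mean of 20 Poisson(42) draws: SE = sqrt(42/20) ~ 1.45
  expect_lt(abs(mean(counts_a) - 42), 5 * sqrt(42 / 20))
  expect_lt(abs(mean(counts_b) - 59), 5 * sqrt(59 / 20))
})

test_that("true bound durations are geometric with the koff-derived parameter", {
  # small dense field, high hazard, fast unbinding -> many short intervals
  cfg <- sim_config(field_width_um = 5, field_height_um = 5,
                    density_a_per_um2 = 4, density_b_per_um2 = 4,
                    kon_hazard = 0.8, koff_per_s = 3,
                    reaction_radius_um = 0.25, release_radius_um = 0.26,
                    confinement_area_fraction = 0, n_frames = 300L,
                    dropout_prob = 0, seed = 21)
  durs <- integer(0)
  s <- 0L
  while (length(durs) < 1e4 && s < 40L) {
    s <- s + 1L
    cfg$seed <- 21L + s
    iv <- simulate_field(cfg)$truth$bound_intervals
    durs <- c(durs, with(iv[!iv$censored, ], end_frame - start_frame + 1L))
  }
  expect_gte(length(durs), 1e4)
  p <- 1 - exp(-3 * 0.033)
  # chi-squared goodness of fit against the geometric pmf, pooled tail
  kmax <- 30L
  obs <- tabulate(pmin(durs, kmax + 1L), nbins = kmax + 1L)
  expp <- c(stats::dgeom(0:(kmax - 1L), p), stats::pgeom(kmax - 1L, p,
                                                         lower.tail = FALSE))
  gof <- stats::chisq.test(obs, p = expp)
  expect_gt(gof$p.value, 0.01)
})

test_that("mean true bound duration matches 1/koff at koff = 0.64", {
  cfg <- sim_config(field_width_um = 6, field_height_um = 6,
                    density_a_per_um2 = 3, density_b_per_um2 = 3,
                    kon_hazard = 0.6, koff_per_s = 0.64,
                    reaction_radius_um = 0.25, release_radius_um = 0.26,
                    confinement_area_fraction = 0, n_frames = 3000L,
                    dropout_prob = 0, seed = 31)
  truths <- lapply(1:4, function(s) {
    cfg$seed <- 31L + s
    simulate_field(cfg)$truth
  })
  n_iv <- sum(vapply(truths, function(tr) sum(!tr$bound_intervals$censored),
                     numeric(1)))
  expect_gte(n_iv, 2000)
  m <- mean_bound_duration(truths)
  # geometric mean duration in seconds: dt / (1 - exp(-koff dt))
  expect_lt(abs(m - 1 / 0.64) / (1 / 0.64), 0.05)
})

test_that("coarse time steps trigger the koff warning and empty channels error", {
  expect_warning(simulate_field(sim_config(koff_per_s = 20, seed = 2,
                                           n_frames = 10L)),
                 "too coarse")
  expect_error(sim_config(field_width_um = 0.5, field_height_um = 0.5),
               "density x area")
})

test_that("hazard calibration hits its target and is monotone in radius", {
  cfg <- sim_config(koff_per_s = 1.32, reaction_radius_um = 0.25,
                    release_radius_um = 0.26,
                    confinement_area_fraction = 0)
  expect_identical(as.numeric(calibrate_binding_hazard(cfg, 0)), 0)

  h <- calibrate_binding_hazard(cfg, 0.3, n_reps = 3L, seed = 4)
  expect_true(as.numeric(h) > 0 && as.numeric(h) < 1)
  # self-consistency: fresh fields simulated at h recover the target within 10%
  truths <- lapply(1:6, function(s) {
    ci <- cfg; ci$kon_hazard <- as.numeric(h); ci$seed <- 600L + s
    simulate_field(ci)$truth
  })
  expect_lt(abs(kon_from_truth(truths) - 0.3) / 0.3, 0.10)

  # doubling the capture area lowers the hazard needed for the same kon
  cfg_big <- cfg
  cfg_big$reaction_radius_um <- 0.25 * sqrt(2)
  h_big <- calibrate_binding_hazard(cfg_big, 0.3, n_reps = 3L, seed = 4)
  expect_lt(as.numeric(h_big), as.numeric(h))

  # unreachable target names the bracket
  expect_error(calibrate_binding_hazard(cfg, 50, n_reps = 2L, seed = 4),
               "bracket")
})
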