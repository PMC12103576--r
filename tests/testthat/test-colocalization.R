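test_that("static particle pairs produce the expected events", {
  ts2 <- function(dx) make_tracks(list(
    list(channel = "A", id = 1L, frames = 0:9, x = rep(1, 10), y = rep(1, 10)),
    list(channel = "B", id = 1L, frames = 0:9, x = rep(1 + dx, 10),
         y = rep(1, 10))
  ), n_frames = 10L)
  near <- ts2(0.10)
  ev <- detect_colocalizations(subset_tracks(near, "A"),
                               subset_tracks(near, "B"), 0.15)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$duration_frames, 10L)
  expect_true(ev$right_censored)  # runs to the end of the movie

  far <- ts2(0.20)
  ev2 <- detect_colocalizations(subset_tracks(far, "A"),
                                subset_tracks(far, "B"), 0.15)
  expect_identical(nrow(ev2), 0L)
})

test_that("gap tolerance extends events across missed frames", {
  # B jumps away for exactly one frame
  xb <- rep(1.05, 11); xb[6] <- 3
  ts <- make_tracks(list(
    list(channel = "A", id = 1L, frames = 0:10, x = rep(1, 11), y = rep(1, 11)),
    list(channel = "B", id = 1L, frames = 0:10, x = xb, y = rep(1, 11))
  ), n_frames = 11L)
  a <- subset_tracks(ts, "A"); b <- subset_tracks(ts, "B")
  strict <- detect_colocalizations(a, b, 0.15, max_gap_frames = 0L)
  expect_identical(nrow(strict), 2L)
  bridged <- detect_colocalizations(a, b, 0.15, max_gap_frames = 1L)
  expect_identical(nrow(bridged), 1L)
  expect_identical(bridged$duration_frames, 11L)
})

test_that("event lists match the exhaustive brute-force oracle", {
  set.seed(77)
  specs <- data.frame(n_a = sample(10:100, 20, TRUE),
                      n_b = sample(10:100, 20, TRUE),
                      n_frames = sample(50:200, 20, TRUE))
  for (i in seq_len(20)) {
    fx <- random_fixture(specs$n_a[i], specs$n_b[i], specs$n_frames[i],
                         seed = 1000 + i)
    gap <- i %% 3L  # exercise gap tolerances 0, 1, 2
    got <- sort_events(detect_colocalizations(fx$a, fx$b, 0.15, gap))
    want <- sort_events(oracle_colocalize(fx$a, fx$b, 0.15, gap))
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("matching is one-to-one at every frame", {
  set.seed(5)
  fx <- random_fixture(60, 60, 100, seed = 4, width = 3, height = 3)
  ev <- detect_colocalizations(fx$a, fx$b, 0.2)
  # expand to per-frame assignments and check uniqueness both ways
  per_frame <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    data.frame(frame = ev$start_frame[i]:ev$end_frame[i],
               a = ev$a_track[i], b = ev$b_track[i])
  }))
  dup_a <- any(duplicated(per_frame[, c("frame", "a")]))
  dup_b <- any(duplicated(per_frame[, c("frame", "b")]))
  expect_false(dup_a || dup_b)
})

test_that("mismatched movie geometry is rejected", {
  fx <- random_fixture(5, 5, 20, seed = 9)
  b_bad <- fx$b; b_bad$n_frames <- 30L
  expect_error(detect_colocalizations(fx$a, b_bad, 0.15), "n_frames")
})

test_that("dwell distributions bin durations and track exclusions", {
  ev <- data.frame(duration_frames = c(5L, 5L, 5L, 1L, 7L),
                   right_censored = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  dd <- dwell_distribution(ev, dt_s = 0.033, min_duration_frames = 2L)
  expect_identical(dd$counts[5], 3)
  expect_identical(sum(dd$counts), 3)
  expect_identical(dd$n_events, 3L)
  expect_identical(dd$n_censored, 1L)
  expect_identical(dd$n_excluded_short, 1L)
  expect_identical(dd$censored_frames, 7L)

  empty <- dwell_distribution(ev[0, ], 0.033)
  expect_identical(empty$n_events, 0L)
  expect_true(all(empty$counts == 0))
})

test_that("observed durations dominate true durations on noiseless fields", {
  cfg <- sim_config(kon_hazard = 0.4, koff_per_s = 1,
                    reaction_radius_um = 0.1, loc_sigma_um = 0,
                    registration_residual_um = 0, dropout_prob = 0,
                    confinement_area_fraction = 0, seed = 61)
  sim <- simulate_field(cfg)
  ev <- data.table::as.data.table(
    detect_colocalizations(sim$a, sim$b, 0.15))
  oa <- sim$truth$origin_a; ob <- sim$truth$origin_b
  ev[, a_mol := oa$mol_id[match(a_track, oa$track_id)]]
  ev[, b_mol := ob$mol_id[match(b_track, ob$track_id)]]
  ti <- sim$truth$bound_intervals
  ok <- vapply(seq_len(nrow(ti)), function(i) {
    cand <- ev[a_mol == ti$a_id[i] & b_mol == ti$b_id[i] &
                 start_frame <= ti$end_frame[i] &
                 end_frame >= ti$start_frame[i]]
    if (nrow(cand) == 0L) return(NA)
    # random prolongation is nonnegative: observed span covers the true one
    max(cand$end_frame) - min(cand$start_frame) + 1L >=
      ti$end_frame[i] - ti$start_frame[i] + 1L
  }, logical(1))
  expect_gt(mean(!is.na(ok)), 0.95)
  expect_true(all(ok, na.rm = TRUE))
})
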