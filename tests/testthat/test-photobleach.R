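test_that("noiseless staircases are fitted exactly", {
  trace <- rep(c(3000, 2000, 1000, 0), each = 25)
  fit <- fit_steps(trace, max_steps = 15L)
  expect_identical(fit$n_steps, 3L)
  expect_identical(fit$step_frames, c(25L, 50L, 75L))
  expect_equal(fit$level_means, c(3000, 2000, 1000, 0), tolerance = 1e-12)
  expect_identical(fit$n_up, 0L)

  flat <- rep(500, 50)
  expect_identical(fit_steps(flat)$n_steps, 0L)
  expect_error(fit_steps(flat, max_steps = 0L), "max_steps")
  expect_error(fit_steps(flat[1:5]), "at least 10")
})

test_that("step fitting is scale invariant and flags upward transitions", {
  set.seed(3)
  base <- rep(c(2, 1, 0), each = 40) + rnorm(120, 0, 0.2)
  f1 <- fit_steps(base)
  f2 <- fit_steps(base * 1e4)
  expect_identical(f1$n_steps, f2$n_steps)
  expect_identical(f1$step_frames, f2$step_frames)

  blink <- c(rep(1000, 30), rep(0, 20), rep(1000, 30), rep(0, 30))
  fb <- fit_steps(blink)
  expect_identical(fb$n_up, 1L)
  expect_identical(fb$n_steps, 2L)  # two downward steps, one blink up
})

test_that("photobleaching generator obeys its own invariants", {
  sim <- simulate_photobleaching_traces(50, c(0, 0, 1), unit_intensity = 100,
                                        bleach_rate_per_s = 1,
                                        noise_sigma = 0, n_frames = 200L,
                                        seed = 4)
  expect_true(all(sim$true_fluor_count == 3L))
  tr <- sim$traces[, 1]
  expect_true(all(diff(tr) <= 0))
  expect_setequal(unique(round(diff(tr)[diff(tr) < 0], 9)) %% 100, 0)

  const <- simulate_photobleaching_traces(5, c(1), bleach_rate_per_s = 0,
                                          noise_sigma = 0, n_frames = 50L,
                                          seed = 5)
  expect_true(all(apply(const$traces, 2, stats::sd) == 0))
  expect_error(simulate_photobleaching_traces(5, c(0.4, 0.4)), "sum to 1")
})

test_that("monomer traces are recovered as single steps at moderate noise", {
  sim <- simulate_photobleaching_traces(100, 1, unit_intensity = 1000,
                                        bleach_rate_per_s = 0.25,
                                        noise_sigma = 200, n_frames = 400L,
                                        seed = 6)
  steps <- apply(sim$traces, 2, function(tr) fit_steps(tr)$n_steps)
  # particles that never bleached in the movie are excluded, as in analysis
  bleached <- steps > 0
  expect_gte(mean(steps[bleached] == 1L), 0.95)
})

test_that("step counts at SNR 5 are mostly exact for sizes 1-8", {
  # traces long enough for complete bleaching, so the fluorophore count is
  # observable in principle
  sizes <- rep(1/8, 8)
  sim <- simulate_photobleaching_traces(150, sizes, unit_intensity = 1000,
                                        bleach_rate_per_s = 0.25,
                                        noise_sigma = 200, n_frames = 1000L,
                                        seed = 7)
  steps <- apply(sim$traces, 2, function(tr) fit_steps(tr)$n_steps)
  truth <- sim$true_fluor_count
  expect_gte(mean(steps == truth), 0.75)
  expect_gte(mean(abs(steps - truth) <= 1), 0.95)
})

test_that("cluster size distributions summarize step counts", {
  csd <- cluster_size_distribution(c(1L, 1L, 1L, 1L))
  expect_identical(csd$fraction_monomeric, 1)
  csd2 <- cluster_size_distribution(c(1L, 1L, 2L, 2L, 0L))
  expect_identical(csd2$fraction_monomeric, 0.5)
  expect_identical(csd2$n_zero_step, 1L)
  expect_identical(csd2$n_particles, 4L)
  expect_identical(sum(csd2$counts), 4L)
  expect_error(cluster_size_distribution(integer(0)), "no particles")
  expect_error(cluster_size_distribution(c(0L, 0L)), "zero detected steps")
  # restriction to co-confined particles
  csd3 <- cluster_size_distribution(c(1L, 2L, 3L), restrict_to = c(1, 3))
  expect_identical(csd3$n_particles, 2L)
  expect_identical(csd3$fraction_monomeric, 0.5)
})

test_that("cluster-weighted presets have lower monomeric fractions", {
  fits_for <- function(preset, seed) {
    sim <- simulate_photobleaching_traces(150, size_preset(preset),
                                          noise_sigma = 200, seed = seed)
    steps <- apply(sim$traces, 2, function(tr) fit_steps(tr)$n_steps)
    cluster_size_distribution(steps)$fraction_monomeric
  }
  expect_gt(fits_for("monomer-weighted", 8),
            fits_for("cluster-weighted", 8))
})
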