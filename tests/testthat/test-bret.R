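test_that("identical stimulated and vehicle traces give zero Delta-BRET", {
  plate <- simulate_bret_plate(6, response_amplitude = 0, noise_sigma = 0,
                               seed = 1)
  db <- delta_bret(plate)
  expect_true(all(abs(db$per_well$delta_bret) < 1e-12))
})

test_that("a constant post-stimulation offset is recovered exactly", {
  plate <- simulate_bret_plate(4, baseline_level = 0.1,
                               response_amplitude = 0, noise_sigma = 0,
                               seed = 2)
  up <- plate$condition == "stimulated" & plate$time_s > 0
  plate$bret_ratio[up] <- plate$bret_ratio[up] + 0.1
  db <- delta_bret(plate)
  s <- db$summary[db$summary$condition == "stimulated", ]
  expect_true(all(abs(s$mean_delta_bret[s$time_s > 0] - 0.1) < 1e-12))
  expect_true(all(abs(s$mean_delta_bret[s$time_s < 0]) < 1e-12))
})

test_that("noise-free plateau Delta-BRET equals the generating amplitude", {
  a <- 0.07
  plate <- simulate_bret_plate(6, response_amplitude = a, response_rate = 1 / 60,
                               vehicle_drift = -2e-6, noise_sigma = 0,
                               n_post_reads = 60, seed = 3)
  db <- delta_bret(plate)
  s <- db$summary[db$summary$condition == "stimulated", ]
  plateau <- s$mean_delta_bret[which.max(s$time_s)]
  expect_equal(plateau, a * (1 - exp(-max(s$time_s) / 60)), tolerance = 1e-10)
})

test_that("vehicle drift with zero amplitude cancels identically", {
  plate <- simulate_bret_plate(8, response_amplitude = 0,
                               vehicle_drift = 5e-6, noise_sigma = 0,
                               seed = 4)
  db <- delta_bret(plate)
  expect_true(all(abs(db$per_well$delta_bret) < 1e-12))
})

test_that("double-baseline correction commutes with offsets and drift", {
  set.seed(5)
  plate <- simulate_bret_plate(6, response_amplitude = 0.05,
                               noise_sigma = 0.001, seed = 5)
  base <- delta_bret(plate)
  # add a well-constant offset and a plate-wide time-varying drift
  mod <- plate
  off <- stats::setNames(runif(length(unique(plate$well)), -0.1, 0.1),
                         unique(plate$well))
  mod$bret_ratio <- mod$bret_ratio + off[mod$well] +
    0.002 * sin(mod$time_s / 300)
  mod_db <- delta_bret(mod)
  expect_equal(mod_db$per_well$delta_bret, base$per_well$delta_bret,
               tolerance = 1e-10)
})

test_that("delta_bret validates its inputs", {
  plate <- simulate_bret_plate(4, seed = 6)
  expect_error(delta_bret(plate[plate$condition != "vehicle", ]), "vehicle")
  expect_error(delta_bret(plate[plate$time_s > 0, ]), "pre-stimulation")
  # ratio computed from donor/acceptor counts when absent
  plate2 <- plate
  plate2$donor_counts <- 1e5
  plate2$acceptor_counts <- plate2$bret_ratio * 1e5
  plate2$bret_ratio <- NULL
  db <- delta_bret(plate2)
  expect_equal(db$per_well$delta_bret, delta_bret(plate)$per_well$delta_bret,
               tolerance = 1e-12)
})

test_that("net BRET zeroes donor-only wells and cancels uniform background", {
  tit <- simulate_bret_titration(12, bmax = 0.25, k50 = 2e4,
                                 background_fluor = 4e3,
                                 background_bret = 0.09, seed = 7)
  net <- net_bret(tit)
  expect_true(all(abs(net$net_bret[net$donor_only]) < 1e-12))
  expect_true(all(abs(net$net_fluorescence[net$donor_only]) < 1e-12))
  # uniform additive fluorescence background cancels exactly
  tit2 <- tit
  tit2$fluorescence <- tit2$fluorescence + 1234
  net2 <- net_bret(tit2)
  expect_equal(net2$net_fluorescence, net$net_fluorescence, tolerance = 1e-9)
  expect_error(net_bret(tit[!tit$donor_only, ]), "donor-only")
})

test_that("saturation fit recovers the generating plateau within 2%", {
  tit <- simulate_bret_titration(24, bmax = 0.3, k50 = 2e4, noise_sigma = 0,
                                 seed = 8)
  fit <- fit_bret_saturation(net_bret(tit))
  expect_lt(abs(fit$bmax - 0.3) / 0.3, 0.02)
  expect_lt(abs(fit$k50 - 2e4) / 2e4, 0.02)
})
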