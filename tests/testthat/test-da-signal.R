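test_that("no spikes give a flat trace at baseline", {
  k <- da_kernel("nacc", baseline = 50)
  tr <- spikes_to_concentration(numeric(0), k, resolution = 0.01,
                                duration = 2)
  expect_true(all(tr$concentration == 50))
})

test_that("a single spike peaks at baseline + increment and decays exponentially", {
  k <- da_kernel("nacc", baseline = 50, release_increment = 2)
  tr <- spikes_to_concentration(100, k, resolution = 0.01, duration = 2)
  expect_equal(max(tr$concentration), 50 + 2)
  i0 <- which.max(tr$concentration)
  decay <- tr$concentration[i0 + 10] - 50
  expect_equal(decay, 2 * exp(-0.1 / k$clearance_tau), tolerance = 1e-10)
})

test_that("steady-state mean matches the shot-noise formula", {
  trains <- generate_fixture_spiketrains("poisson", 4.5, 100000, seed = 42,
                                         n_trains = 100)
  k <- da_kernel("nacc", baseline = 50)
  tr <- spikes_to_concentration(trains, k, resolution = 0.01,
                                duration = 100)
  sel <- tr$times > 5  # discard the filter transient
  expected <- shot_noise_mean(4.5, k$release_increment, k$clearance_tau,
                              100, 50)
  expect_lt(abs(mean(tr$concentration[sel]) - expected) / expected, 0.05)
})

test_that("the readout is linear in its input trains", {
  trains <- generate_fixture_spiketrains("poisson", 4, 5000, seed = 3,
                                         n_trains = 3)
  k <- da_kernel("nacc", baseline = 10)
  union <- spikes_to_concentration(trains, k, resolution = 0.01,
                                   duration = 5)
  parts <- lapply(trains, spikes_to_concentration, kernel = k,
                  resolution = 0.01, duration = 5)
  summed <- Reduce(`+`, lapply(parts, `[[`, "concentration")) -
    (length(parts) - 1) * k$baseline
  expect_equal(union$concentration, summed, tolerance = 1e-10)
})

test_that("unsorted spike times are rejected", {
  k <- da_kernel("nacc")
  expect_error(spikes_to_concentration(c(200, 100), k), "increasing")
})

test_that("a burst-attributable DA change matches the closed-form kernel integral", {
  k <- da_kernel("nacc", baseline = 20)
  onset <- 3000
  burst <- onset + (0:9) * 10   # 10 spikes from onset, ms
  W <- 0.5                      # response window, s
  trace <- spikes_to_concentration(list(burst), k, resolution = 0.001,
                                   duration = 4)
  dda <- delta_da(trace, rpe_event(onset, 1), baseline_window = 1,
                  response_window = W)
  oracle <- sum(vapply(burst / 1000, function(ts) {
    k$release_increment * k$clearance_tau *
      (1 - exp(-(onset / 1000 + W - ts) / k$clearance_tau)) / W
  }, 0))
  expect_equal(dda, oracle, tolerance = 0.01)
})

test_that("measurement windows must fit the recording", {
  k <- da_kernel("nacc")
  trace <- spikes_to_concentration(list(c(100, 300)), k,
                                   resolution = 0.01, duration = 2)
  expect_error(delta_da(trace, rpe_event(300, 1), baseline_window = 1),
               "before the recording start")
  expect_error(delta_da(trace, rpe_event(1800, 1), baseline_window = 1,
                        response_window = 1),
               "past the recording end")
})

test_that("DA responds with the sign of the reward-prediction error", {
  cfg <- network_config()
  net <- build_network(cfg, seed = 6)
  k <- da_kernel("nacc")
  measure <- function(delta) {
    rec <- run_simulation(net, agency_input(cfg$A_control),
                          list(rpe_event(3000, delta)), seed = 6,
                          duration = 4000)
    delta_da(rec, rpe_event(3000, delta), k)
  }
  none <- {
    rec <- run_simulation(net, agency_input(cfg$A_control), seed = 6,
                          duration = 4000)
    delta_da(rec, rpe_event(3000, 0), k)
  }
  expect_gt(measure(1), 5)
  expect_lt(measure(-1), -2)
  expect_lt(abs(none), 5)
})

test_that("a single burst keeps cortical DA above baseline for 20 to 30 minutes", {
  dur <- 7200e3
  tr <- generate_fixture_spiketrains("burst_injected", 4.5, dur,
                                     burst_time = 4800e3)
  trace <- spikes_to_concentration(tr, da_kernel("cortex"), resolution = 1,
                                   duration = dur / 1000)
  pre <- trace$times > 4200 & trace$times < 4800
  base <- mean(trace$concentration[pre])
  eps <- 0.01 * base
  post <- which(trace$times >= 4800)
  above <- trace$concentration[post] > base + eps
  exceed_min <- (which(!above)[1] - 1) / 60
  expect_gte(exceed_min, 20)
  expect_lte(exceed_min, 30)
})

test_that("michaelis-menten clearance is available and saturates", {
  k <- da_kernel("custom", clearance_tau = 1, baseline = 0,
                 mode = "michaelis_menten", vmax = 5, km = 1)
  tr <- spikes_to_concentration(list(c(100)), k, resolution = 0.01,
                                duration = 3)
  expect_equal(max(tr$concentration), k$release_increment)
  expect_true(all(diff(tr$concentration[tr$times > 0.11]) <= 1e-12))
  expect_error(da_kernel("custom", mode = "michaelis_menten"), "requires")
})
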