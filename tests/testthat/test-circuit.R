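test_that("wiring is deterministic given the seed and has the declared structure", {
  cfg <- small_config()
  a <- build_network(cfg, seed = 11)
  b <- build_network(cfg, seed = 11)
  c <- build_network(cfg, seed = 12)
  expect_identical(a$W_vp_nacc, b$W_vp_nacc)
  expect_identical(a$W_da_vp, b$W_da_vp)
  expect_identical(a$aversive, b$aversive)
  expect_false(identical(a$W_da_vp, c$W_da_vp))
  expect_equal(dim(a$W_vp_nacc), c(cfg$n_vp, cfg$n_nacc))
  expect_equal(dim(a$W_da_vp), c(cfg$n_da, cfg$n_vp))
  expect_true(all(a$W_da_vp >= 0))
  expect_equal(sum(a$aversive), round(cfg$aversive_fraction * cfg$n_da))
})

test_that("zero connection probability yields unconnected populations", {
  cfg <- small_config(connection_probability = 0)
  net <- build_network(cfg, seed = 1)
  expect_true(all(net$W_vp_nacc == 0))
  rec <- run_simulation(net, agency_input(1), seed = 1)
  # VP unaffected by (strong) NAcc drive: pure 7 Hz pacemakers
  expect_equal(population_rate(rec, "vp", c(1000, 4000)), 7,
               tolerance = 0.05)
})

test_that("recordings are reproducible given the seed", {
  net <- build_network(small_config(), seed = 5)
  a <- run_simulation(net, agency_input(0.5), seed = 9)
  b <- run_simulation(net, agency_input(0.5), seed = 9)
  expect_identical(a$da, b$da)
  expect_identical(a$nacc, b$nacc)
})

test_that("raising agency disinhibits the dopamine population", {
  cfg <- network_config()
  net <- build_network(cfg, seed = 2)
  lo <- run_simulation(net, agency_input(cfg$A_control), seed = 2)
  hi <- run_simulation(net, agency_input(cfg$A_high), seed = 2)
  win <- c(2000, 12000)
  expect_gt(population_rate(hi, "nacc", win), population_rate(lo, "nacc", win))
  expect_lt(population_rate(hi, "vp", win), population_rate(lo, "vp", win))
  n_active <- function(rec) sum(classify_da_states(rec, win) != "silent")
  expect_gt(n_active(hi), n_active(lo))
  # dropping agency below control does the opposite
  off <- run_simulation(net, agency_input(0), seed = 2)
  expect_gte(population_rate(off, "vp", win), population_rate(lo, "vp", win))
  expect_lte(n_active(off), n_active(lo))
})

test_that("pallidal tone silences a large share of DA neurons", {
  cfg <- network_config()
  lesion <- network_config(w_vp_da = 0)
  win <- c(2000, 12000)
  intact <- run_simulation(build_network(cfg, seed = 3),
                           agency_input(0), seed = 3)
  lesioned <- run_simulation(build_network(lesion, seed = 3),
                             agency_input(0), seed = 3)
  n_silent <- function(rec) sum(classify_da_states(rec, win) == "silent")
  expect_lt(n_silent(lesioned), 5)
  expect_gt(n_silent(intact), cfg$n_da / 3)
  expect_gt(n_silent(intact), n_silent(lesioned) + cfg$n_da / 4)
})

test_that("agency and reward act through independent channels", {
  cfg <- network_config()
  net <- build_network(cfg, seed = 4)
  win <- c(2000, 12000)
  # agency change alone: no bursts at any level
  for (A in c(cfg$A_control, cfg$A_high)) {
    st <- classify_da_states(run_simulation(net, agency_input(A), seed = 4),
                             win)
    expect_equal(sum(st == "phasic"), 0)
  }
  # a positive RPE causes bursts among tonic neurons but leaves the silent
  # pool unchanged
  base <- classify_da_states(run_simulation(net, agency_input(cfg$A_control),
                                            seed = 4), win)
  ev <- classify_da_states(
    run_simulation(net, agency_input(cfg$A_control),
                   list(rpe_event(6000, 1)), seed = 4), win)
  expect_gt(sum(ev == "phasic"), 0)
  expect_lt(abs(sum(ev == "silent") - sum(base == "silent")), 6)
})

test_that("DA state classification follows the rate and burst rules", {
  # no spikes -> silent
  empty <- c(list(numeric(0)),
             generate_fixture_spiketrains("regular", 4.5, 11000))
  st <- classify_da_states(empty, window = c(0, 10000))
  expect_equal(as.character(st[1]), "silent")
  # regular 4.5 Hz train without short ISIs -> tonic
  expect_equal(as.character(st[2]), "tonic")
  # injected 3-spike cluster at 60 ms ISI -> phasic
  tr <- generate_fixture_spiketrains("burst_injected", 4.5, 11000,
                                     burst_time = 5000, burst_k = 3,
                                     burst_isi = 60)
  st <- classify_da_states(tr, window = c(0, 10000))
  expect_equal(as.character(st[1]), "phasic")
  # a neuron exactly at threshold counts as tonic (>= comparison)
  at_thr <- list(seq(500, 9999, length.out = 5))  # 0.5 Hz over 10 s
  st <- classify_da_states(at_thr, window = c(0, 10000),
                           tonic_threshold = 0.5)
  expect_equal(as.character(st[1]), "tonic")
})

test_that("invalid simulation inputs are rejected", {
  net <- build_network(small_config(), seed = 1)
  expect_error(run_simulation(net, rpe_events = list(rpe_event(9000, 1)),
                              seed = 1),
               "outside")
  expect_error(run_simulation(net,
                              rpe_events = list(rpe_event(1000, 1),
                                                rpe_event(1100, 0.5)),
                              seed = 1),
               "non-overlapping")
  expect_error(agency_input(1.5), "\\[0, 1\\]")
  expect_error(rpe_event(0, 2), "delta")
  expect_error(classify_da_states(list(), window = c(0, 2000)), "empty")
  expect_error(classify_da_states(list(numeric(0)), window = c(0, 500)),
               "1000 ms")
})
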