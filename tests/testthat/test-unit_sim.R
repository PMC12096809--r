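test_that("mean spike count matches the programmed rate integral", {
  # Poisson oracle: with n trials the mean count estimate has SE
  # sqrt(lambda/n); the thinning sampler must agree within 3 SE.
  lib <- fixture_library()
  proto <- trial_protocol(post_stimulus_ms = 450, n_trials = 200, seed = 42)
  prof <- dac_profile()
  for (id in c("echo_1", "app_3", "aggr_2")) {
    call <- lib$calls[[id]]
    kernel <- vocsel:::response_kernel(prof, vocsel:::envelope_dt(call))
    lambda <- prof$baseline_rate_hz * vocsel:::trial_length_ms(proto) / 1000 +
      prof$driven_gain_hz * sum(kernel) * vocsel:::SIM_DT_MS / 1000
    sts <- simulate_call_response(prof, call, proto)
    observed <- mean(lengths(sts$trials))
    expect_lt(abs(observed - lambda), 3 * sqrt(lambda / proto$n_trials))
  }
})

test_that("simulation is deterministic and spikes stay in range", {
  lib <- fixture_library()
  proto <- trial_protocol(post_stimulus_ms = 450, n_trials = 20, seed = 3)
  a <- simulate_call_response(dac_profile(), lib$calls$aggr_1, proto)
  b <- simulate_call_response(dac_profile(), lib$calls$aggr_1, proto)
  expect_identical(a$trials, b$trials)
  proto2 <- trial_protocol(post_stimulus_ms = 450, n_trials = 20, seed = 4)
  c2 <- simulate_call_response(dac_profile(), lib$calls$aggr_1, proto2)
  expect_false(identical(a$trials, c2$trials))
  tlen <- vocsel:::trial_length_ms(proto)
  for (tr in a$trials) {
    expect_false(is.unsorted(tr))
    expect_true(all(tr >= 0 & tr < tlen))
  }
})

test_that("zero driven gain gives indistinguishable pre/post activity", {
  lib <- fixture_library()
  proto <- trial_protocol(post_stimulus_ms = 450, n_trials = 300, seed = 8)
  prof <- dac_profile(driven_gain_hz = 0, baseline_rate_hz = 20)
  sts <- simulate_call_response(prof, lib$calls$app_1, proto)
  pre_rate <- mean(vapply(sts$trials, function(tr) sum(tr < 50), numeric(1))) / 50
  post_rate <- mean(vapply(sts$trials, function(tr) sum(tr >= 50 & tr < 500),
                           numeric(1))) / 450
  # both estimate 20 Hz: compare within 3 SE of the difference
  se <- sqrt(0.02 / (50 * 300) + 0.02 / (450 * 300)) * 1000
  expect_lt(abs(pre_rate - post_rate) * 1000, 3 * se * 1000)
})

test_that("phasic responses lock to the aggression call envelope", {
  lib <- fixture_library()
  proto <- trial_protocol(post_stimulus_ms = 450, n_trials = 40, seed = 12)
  prof <- dac_profile()
  sts <- simulate_call_response(prof, lib$calls$aggr_3, proto)
  psth <- compute_psth(sts, bin_width_ms = 1)
  driven <- psth$counts[56:250] # response epoch, 1-ms bins
  ac <- stats::acf(driven, lag.max = 12, plot = FALSE)$acf[, 1, 1]
  # periodicity at the ~8 ms inter-pulse interval
  expect_gt(max(ac[8:10]), max(ac[4:6]))
})

test_that("tonic units respond far beyond a short stimulus", {
  lib <- fixture_library()
  proto <- trial_protocol(post_stimulus_ms = 450, n_trials = 60, seed = 2)
  prof <- faf_profile()
  sts <- simulate_call_response(prof, lib$calls$echo_1, proto) # < 3 ms call
  psth <- compute_psth(sts, bin_width_ms = 1)
  base <- mean(psth$counts[1:50])
  late <- mean(psth$counts[131:141]) # ~90 ms after onset + latency
  early_gap <- mean(psth$counts[56:70]) # before the 35-ms latency
  expect_gt(late, 2 * base)
  expect_lt(early_gap, 2 * base)
})

test_that("tone grid covers the default frequency grid and thresholds work", {
  expect_length(default_tone_freqs_khz(), 33)
  expect_equal(range(default_tone_freqs_khz()), c(5, 80))
  prof <- dac_profile(baseline_rate_hz = 0)
  proto <- trial_protocol(post_stimulus_ms = 150, n_trials = 30, seed = 6)
  grid <- simulate_tone_grid(prof, freqs_khz = prof$cf_khz,
                             levels_db = c(prof$threshold_db,
                                           prof$threshold_db - 5),
                             protocol = proto)
  at_thr <- grid[[1L]]
  below <- grid[[2L]]
  expect_gt(mean(lengths(at_thr$trials)), 1)
  expect_equal(mean(lengths(below$trials)), 0)
})

test_that("make_population is deterministic with distinct jittered profiles", {
  spec <- list(list(template = dac_profile(unit_id = "d"), n = 3),
               list(template = faf_profile(unit_id = "f"), n = 2))
  pop1 <- make_population(spec, seed = 9)
  pop2 <- make_population(spec, seed = 9)
  expect_length(pop1, 5)
  expect_identical(vapply(pop1, `[[`, character(1), "unit_id"),
                   vapply(pop2, `[[`, character(1), "unit_id"))
  expect_identical(pop1$d_001$cf_khz, pop2$d_001$cf_khz)
  expect_false(pop1$d_001$cf_khz == pop1$d_002$cf_khz)
  expect_length(make_population(list(), seed = 1), 0)
})

test_that("demo population matches the recorded unit counts", {
  pop <- demo_population(seed = 1)
  areas <- vapply(pop, `[[`, character(1), "area")
  expect_equal(sum(areas == "FAF"), 92)
  expect_equal(sum(areas == "dAC"), 142)
})

test_that("spike CSV and JSON round trips are lossless", {
  lib <- fixture_library()
  proto <- trial_protocol(post_stimulus_ms = 450, n_trials = 5, seed = 3)
  sets <- list(
    a = simulate_call_response(dac_profile(), lib$calls$echo_1, proto),
    b = simulate_call_response(dac_profile(), lib$calls$aggr_1, proto)
  )
  # echo responses are sparse: some trials are empty, exercising the NA rows
  expect_true(any(lengths(sets$a$trials) == 0))
  dir <- withr::local_tempdir()
  write_spike_csv(sets, file.path(dir, "s.csv"))
  rt <- read_spike_csv(file.path(dir, "s.csv"))
  expect_length(rt, 2)
  k <- paste(sets$a$unit_id, sets$a$stimulus_id, sep = "/")
  expect_equal(rt[[k]]$trials, sets$a$trials, tolerance = 1e-9)

  write_spike_json(sets, file.path(dir, "s.json"))
  rt2 <- read_spike_json(file.path(dir, "s.json"))
  expect_equal(rt2[[k]]$trials, sets$a$trials, tolerance = 1e-12)
  expect_equal(rt2[[k]]$protocol$n_trials, 5L)
})

test_that("protocol validation rejects too-short recordings", {
  lib <- fixture_library()
  proto <- trial_protocol(post_stimulus_ms = 100, n_trials = 5, seed = 1)
  expect_error(simulate_call_response(faf_profile(), lib$calls$aggr_5, proto),
               "too short")
})
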