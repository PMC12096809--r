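test_that("category generators respect the printed duration ranges", {
  for (v in 1:5) {
    for (seed in c(1, 7)) {
      expect_lt(synth_echolocation_call(seed, v)$duration_ms, 3)
      d <- synth_appeasement_call(seed, v)$duration_ms
      expect_gte(d, 25)
      expect_lte(d, 46)
      d <- synth_aggression_call(seed, v)$duration_ms
      expect_gte(d, 134)
      expect_lte(d, 271)
    }
  }
})

test_that("generators are pure functions of (seed, variant)", {
  for (gen in list(synth_echolocation_call, synth_appeasement_call,
                   synth_aggression_call)) {
    a <- gen(seed = 3, variant = 2)
    b <- gen(seed = 3, variant = 2)
    expect_identical(a$samples, b$samples)
    expect_false(identical(a$samples, gen(seed = 4, variant = 2)$samples))
    expect_false(identical(a$samples, gen(seed = 3, variant = 3)$samples))
  }
  expect_error(synth_echolocation_call(1, 0), "variant")
  expect_error(synth_echolocation_call(1, 6), "variant")
})

test_that("echolocation energy sits in the high-frequency band", {
  for (v in 1:5) {
    w <- synth_echolocation_call(2, v)
    n <- length(w$samples)
    p <- Mod(stats::fft(w$samples))^2
    f <- (seq_len(n) - 1) / n * w$sample_rate_hz
    half <- f <= w$sample_rate_hz / 2
    expect_gt(sum(p[half & f > 40000]), 10 * sum(p[half & f < 20000]))
  }
})

test_that("appeasement calls carry a ~17 kHz fundamental", {
  for (v in 1:5) {
    f0 <- vocsel:::estimate_f0(synth_appeasement_call(1, v))
    expect_gte(f0, 15000)
    expect_lte(f0, 19000)
  }
})

test_that("aggression envelope is modulated at ~8 ms intervals", {
  for (v in c(1, 3, 5)) {
    w <- synth_aggression_call(1, v)
    env <- call_envelope(w, smoothing_ms = 1)
    sr <- w$sample_rate_hz
    ac <- stats::acf(env, lag.max = round(sr * 0.012), plot = FALSE)$acf[, 1, 1]
    lags_ms <- (seq_along(ac) - 1) / sr * 1000
    search <- lags_ms >= 5 & lags_ms <= 12
    peak_lag <- lags_ms[search][which.max(ac[search])]
    expect_gt(peak_lag, 6.5)
    expect_lt(peak_lag, 9.5)
  }
})

test_that("call library has 3 categories x 5 unique calls", {
  lib <- fixture_library()
  expect_length(lib$calls, 15)
  expect_named(lib$categories, c("echolocation", "appeasement", "aggression"))
  expect_true(all(lengths(lib$categories) == 5))
  expect_false(anyDuplicated(names(lib$calls)) > 0)
  man <- call_manifest(lib)
  expect_equal(nrow(man), 15)
  expect_equal(unname(table(man$category)[c("echolocation", "appeasement", "aggression")]),
               c(5L, 5L, 5L), ignore_attr = TRUE)
})

test_that("envelope is non-negative, sign-invariant, and flat for a tone", {
  t <- seq_len(9600) / 192000
  tone <- call_waveform("tone", "appeasement", 0.9 * sin(2 * pi * 17000 * t))
  env <- call_envelope(tone, smoothing_ms = 1)
  expect_length(env, length(tone$samples))
  expect_true(all(env >= 0))
  core <- env[500:(length(env) - 500)]
  expect_lt(diff(range(core)) / mean(core), 0.05)

  flipped <- call_waveform("tone2", "appeasement", -tone$samples)
  expect_equal(call_envelope(flipped, 1), env, tolerance = 1e-12)

  silence <- call_waveform("sil", "appeasement", numeric(100) )
  expect_equal(call_envelope(silence, 1), numeric(100))
})

test_that("aggression envelope has one local maximum per pulse", {
  w <- synth_aggression_call(1, 2)
  env <- call_envelope(w, smoothing_ms = 2)
  thr <- 0.3 * max(env)
  peaks <- sum(diff(sign(diff(env))) < 0 & env[2:(length(env) - 1)] > thr)
  expect_gte(peaks, 10)
})

test_that("acoustic features match closed-form cases", {
  t <- seq_len(round(0.040 * 192000)) / 192000
  tone <- call_waveform("tone", "appeasement", 0.9 * sin(2 * pi * 17000 * t))
  af <- acoustic_features(tone)
  expect_equal(af$spectral_centroid_hz, 17000, tolerance = 0.02)
  expect_equal(af$temporal_centroid_ms, 20, tolerance = 0.05)
  expect_gt(af$harmonic_ratio, 0.9)

  # seeded broadband noise: harmonic bands capture little energy
  noise <- vocsel:::with_seed(7, stats::rnorm(19200))
  nz <- call_waveform("nz", "echolocation", 0.98 * noise / max(abs(noise)))
  expect_lt(acoustic_features(nz)$harmonic_ratio, 0.3)

  expect_error(acoustic_features(call_waveform("z", "appeasement", numeric(64))),
               "all-zero")
})

test_that("feature invariants hold across the library", {
  lib <- fixture_library()
  feats <- lapply(lib$calls, acoustic_features)
  for (f in feats) {
    expect_gte(f$temporal_centroid_ms, 0)
    expect_lte(f$temporal_centroid_ms, f$duration_ms)
    expect_gte(f$harmonic_ratio, 0)
    expect_lte(f$harmonic_ratio, 1)
  }
})

test_that("categories form separable clusters in feature space", {
  lib <- fixture_library()
  man <- call_manifest(lib)
  dur <- split(man$duration_ms, man$category)
  # duration separates all three categories with disjoint ranges
  expect_lt(max(dur$echolocation), min(dur$appeasement))
  expect_lt(max(dur$appeasement), min(dur$aggression))
  # spectral centroid separates echolocation from both communication types
  sc <- vapply(lib$calls, function(w) acoustic_features(w)$spectral_centroid_hz,
               numeric(1))
  sc <- split(sc, man$category[match(names(sc), man$call_id)])
  expect_gt(min(sc$echolocation), max(sc$appeasement))
  expect_gt(min(sc$echolocation), max(sc$aggression))
})

test_that("WAV round trip and library export/import preserve the stimuli", {
  dir <- withr::local_tempdir()
  x <- sin(2 * pi * 5000 * seq_len(4800) / 192000) * 0.8
  write_wav(x, 192000, file.path(dir, "t.wav"), bits = 16)
  rt <- read_wav(file.path(dir, "t.wav"))
  expect_equal(rt$sample_rate_hz, 192000)
  expect_equal(rt$samples, x, tolerance = 1e-4)

  write_wav(x, 192000, file.path(dir, "t32.wav"), bits = 32)
  expect_equal(read_wav(file.path(dir, "t32.wav"))$samples, x, tolerance = 1e-7)

  lib <- fixture_library()
  export_call_library(lib, file.path(dir, "lib"))
  lib2 <- import_call_library(file.path(dir, "lib"))
  expect_equal(names(lib2$calls), names(lib$calls))
  expect_equal(lib2$calls$aggr_3$category, "aggression")
  expect_equal(lib2$calls$app_2$duration_ms, lib$calls$app_2$duration_ms,
               tolerance = 1e-6)
  expect_equal(lib2$calls$echo_1$samples, lib$calls$echo_1$samples,
               tolerance = 1e-4)
})
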