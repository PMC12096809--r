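#' Construct a call waveform object
#'
#' A `call_waveform` holds one synthesized vocalization: peak-normalized
#' samples, its sample rate and its behavioral category. The three category
#' generators ([synth_echolocation_call()], [synth_appeasement_call()],
#' [synth_aggression_call()]) all return this class.
#'
#' @param call_id Character id, unique within a library.
#' @param category One of `"echolocation"`, `"appeasement"`, `"aggression"`.
#' @param samples Numeric vector of amplitudes with `max(abs(samples)) <= 1`.
#' @param sample_rate_hz Sampling rate in Hz (default 192000).
#' @return An object of class `call_waveform` with fields `call_id`,
#'   `category`, `samples`, `sample_rate_hz`, `duration_ms`.
#' @export
call_waveform <- function(call_id, category, samples, sample_rate_hz = 192000) {
  category <- match.arg(category, c("echolocation", "appeasement", "aggression"))
  stopifnot(is.numeric(samples), length(samples) > 0L, sample_rate_hz > 0)
  if (max(abs(samples)) > 1 + 1e-9) stop("samples must be peak-normalized (<= 1)", call. = FALSE)
  structure(
    list(
      call_id = as.character(call_id),
      category = category,
      samples = as.numeric(samples),
      sample_rate_hz = sample_rate_hz,
      duration_ms = length(samples) / sample_rate_hz * 1000
    ),
    class = "call_waveform"
  )
}

#' @export
print.call_waveform <- function(x, ...) {
  cat(sprintf(
    "<call_waveform> %s [%s], %.2f ms @ %g kHz\n",
    x$call_id, x$category, x$duration_ms, x$sample_rate_hz / 1000
  ))
  invisible(x)
}

check_variant <- function(variant) {
  if (!is.numeric(variant) || length(variant) != 1L || is.na(variant) ||
      variant != as.integer(variant) || variant < 1L || variant > 5L) {
    stop("`variant` must be an integer in 1..5", call. = FALSE)
  }
  as.integer(variant)
}

# Additive harmonic synthesis along an instantaneous-frequency track.
# Harmonic components are muted sample-wise where they would exceed 94 kHz
# (just below Nyquist at 192 kHz).
harmonic_track <- function(f_inst, harmonic_amps, sample_rate_hz, phases = NULL) {
  phase0 <- 2 * pi * cumsum(f_inst) / sample_rate_hz
  x <- numeric(length(f_inst))
  for (k in seq_along(harmonic_amps)) {
    mask <- (k * f_inst) < 94000
    ph <- if (is.null(phases)) 0 else phases[k]
    x <- x + harmonic_amps[k] * mask * sin(k * phase0 + ph)
  }
  x
}

#' Synthesize an echolocation-type call
#'
#' Short (< 3 ms) multiharmonic downward frequency-modulated sweep whose
#' energy occupies roughly 90 to 40 kHz: the fundamental sweeps ~45 to 21 kHz
#' and the dominant second harmonic spans ~90 to 42 kHz. Variants differ
#' deterministically in duration and sweep endpoints.
#'
#' @param seed Integer seed; together with `variant` it fully determines the
#'   waveform.
#' @param variant Integer 1..5 selecting the within-category variant.
#' @param sample_rate_hz Sampling rate in Hz.
#' @return A [call_waveform()] of category `"echolocation"`.
#' @export
synth_echolocation_call <- function(seed = 1L, variant = 1L, sample_rate_hz = 192000) {
  variant <- check_variant(variant)
  with_seed(fan_seed(seed, "echolocation", variant), {
    dur_ms <- c(1.6, 1.9, 2.2, 2.5, 2.8)[variant] * stats::runif(1, 0.96, 1.0)
    hi <- 45000 * stats::runif(1, 0.96, 1.04)
    lo <- 22000 * stats::runif(1, 0.95, 1.05)
    n <- max(16L, round(dur_ms / 1000 * sample_rate_hz))
    u <- seq_len(n) / n
    f_inst <- hi * (lo / hi)^u # log-spaced downward sweep
    x <- harmonic_track(f_inst, c(0.4, 1, 0.65, 0.3), sample_rate_hz,
                        phases = stats::runif(4, 0, 2 * pi))
    x <- x * sin(pi * seq_len(n) / (n + 1)) # half-sine envelope
    out <- call_waveform(sprintf("echo_%d", variant), "echolocation",
                         0.98 * x / max(abs(x)), sample_rate_hz)
    out
  })
}

#' Synthesize an appeasement-type call
#'
#' 25-46 ms harmonic stack on a fundamental of about 17 kHz with shallow
#' sinusoidal frequency modulation, resembling mother-pup contact /
#' appeasement calls.
#'
#' @inheritParams synth_echolocation_call
#' @return A [call_waveform()] of category `"appeasement"`.
#' @export
synth_appeasement_call <- function(seed = 1L, variant = 1L, sample_rate_hz = 192000) {
  variant <- check_variant(variant)
  with_seed(fan_seed(seed, "appeasement", variant), {
    dur_ms <- c(27, 31, 36, 41, 45)[variant] * stats::runif(1, 0.98, 1.02)
    f0 <- 17000 * stats::runif(1, 0.95, 1.05)
    fm_depth <- stats::runif(1, 0.015, 0.03)
    fm_rate <- stats::runif(1, 18, 28)
    n <- round(dur_ms / 1000 * sample_rate_hz)
    t <- seq_len(n) / sample_rate_hz
    f_inst <- f0 * (1 + fm_depth * sin(2 * pi * fm_rate * t + stats::runif(1, 0, 2 * pi)))
    x <- harmonic_track(f_inst, c(1, 0.55, 0.3, 0.18, 0.1), sample_rate_hz,
                        phases = stats::runif(5, 0, 2 * pi))
    x <- x * tukey_window(n, 0.25)
    call_waveform(sprintf("app_%d", variant), "appeasement",
                  0.98 * x / max(abs(x)), sample_rate_hz)
  })
}

#' Synthesize an aggression-type call
#'
#' Long (134-271 ms) train of short broadband sound elements separated by
#' approximately 8 ms, on a low fundamental (7.5-13 kHz), giving rise to
#' strong amplitude modulation at ~125 Hz.
#'
#' @inheritParams synth_echolocation_call
#' @return A [call_waveform()] of category `"aggression"`.
#' @export
synth_aggression_call <- function(seed = 1L, variant = 1L, sample_rate_hz = 192000) {
  variant <- check_variant(variant)
  with_seed(fan_seed(seed, "aggression", variant), {
    dur_ms <- c(145, 175, 205, 235, 265)[variant] * stats::runif(1, 0.98, 1.02)
    period_ms <- 8
    pulse_ms <- 4
    f0 <- stats::runif(1, 8000, 12500)
    n_pulses <- ceiling((dur_ms - pulse_ms) / period_ms)
    np <- round(pulse_ms / 1000 * sample_rate_hz)
    t <- seq_len(np) / sample_rate_hz
    onsets_ms <- (seq_len(n_pulses) - 1L) * period_ms +
      c(0, stats::runif(n_pulses - 1L, -0.3, 0.3))
    onsets_ms <- pmax(0, onsets_ms)
    total_n <- round((max(onsets_ms) + pulse_ms) / 1000 * sample_rate_hz)
    x <- numeric(total_n)
    amps <- stats::runif(n_pulses, 0.7, 1)
    for (p in seq_len(n_pulses)) {
      f_jit <- f0 * stats::runif(1, 0.97, 1.03)
      f_inst <- rep(f_jit, np)
      pulse <- harmonic_track(f_inst, 0.9^(0:7), sample_rate_hz,
                              phases = stats::runif(8, 0, 2 * pi))
      pulse <- amps[p] * pulse * sin(pi * seq_len(np) / (np + 1))^2
      i0 <- round(onsets_ms[p] / 1000 * sample_rate_hz)
      idx <- (i0 + 1L):(i0 + np)
      x[idx] <- x[idx] + pulse
    }
    call_waveform(sprintf("aggr_%d", variant), "aggression",
                  0.98 * x / max(abs(x)), sample_rate_hz)
  })
}

#' Synthesize the full 15-call stimulus library
#'
#' Five variants of each of the three behavioral categories (echolocation,
#' appeasement, aggression), matching the composition of the stimulus set
#' used for acoustic stimulation: 3 categories x 5 calls.
#'
#' @param seed Integer seed controlling all within-category variability.
#' @param sample_rate_hz Sampling rate in Hz.
#' @return An object of class `call_library`: list with `calls` (named list
#'   of 15 [call_waveform()]s) and `categories` (named list mapping each
#'   category to its 5 call ids).
#' @export
synth_call_library <- function(seed = 1L, sample_rate_hz = 192000) {
  gens <- list(
    echolocation = synth_echolocation_call,
    appeasement = synth_appeasement_call,
    aggression = synth_aggression_call
  )
  calls <- list()
  categories <- list()
  for (cat in names(gens)) {
    ids <- character(5)
    for (v in 1:5) {
      w <- gens[[cat]](seed = seed, variant = v, sample_rate_hz = sample_rate_hz)
      calls[[w$call_id]] <- w
      ids[v] <- w$call_id
    }
    categories[[cat]] <- ids
  }
  structure(list(calls = calls, categories = categories, seed = seed),
            class = "call_library")
}

#' @export
print.call_library <- function(x, ...) {
  cat(sprintf("<call_library> %d calls in %d categories\n",
              length(x$calls), length(x$categories)))
  for (cat in names(x$categories)) {
    durs <- vapply(x$calls[x$categories[[cat]]], `[[`, numeric(1), "duration_ms")
    cat(sprintf("  %-12s %s (%.1f-%.1f ms)\n", cat,
                paste(x$categories[[cat]], collapse = " "), min(durs), max(durs)))
  }
  invisible(x)
}

#' Category membership table of a call library
#'
#' @param library A [synth_call_library()] object.
#' @return data.frame with columns `call_id`, `category`, `duration_ms`.
#' @export
call_manifest <- function(library) {
  ids <- names(library$calls)
  data.frame(
    call_id = ids,
    category = vapply(library$calls, `[[`, character(1), "category"),
    duration_ms = vapply(library$calls, `[[`, numeric(1), "duration_ms"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Temporal amplitude envelope of a call
#'
#' Magnitude of the analytic signal (Hilbert transform), smoothed by a
#' centered moving average of `smoothing_ms`. Invariant to a sign flip of the
#' waveform.
#'
#' @param w A [call_waveform()].
#' @param smoothing_ms Smoothing window in ms (>= 0; 0 disables smoothing).
#' @return Non-negative numeric vector, same length as `w$samples`.
#' @export
call_envelope <- function(w, smoothing_ms = 0.5) {
  stopifnot(inherits(w, "call_waveform"), smoothing_ms >= 0)
  if (length(w$samples) == 0L) stop("empty waveform", call. = FALSE)
  env <- analytic_magnitude(w$samples)
  n <- round(smoothing_ms / 1000 * w$sample_rate_hz)
  moving_average(env, n)
}

# Fundamental-frequency estimate by the autocorrelation-peak method,
# restricted to a plausible F0 search range.
estimate_f0 <- function(w, f0_range_hz = c(4000, 30000)) {
  x <- w$samples - mean(w$samples)
  sr <- w$sample_rate_hz
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  X <- stats::fft(c(x, numeric(nfft - n)))
  ac <- Re(stats::fft(X * Conj(X), inverse = TRUE))[1:n] / nfft
  lag_min <- max(2L, floor(sr / f0_range_hz[2]))
  lag_max <- min(n - 1L, ceiling(sr / f0_range_hz[1]))
  if (lag_max <= lag_min) stop("waveform too short for F0 estimation", call. = FALSE)
  lags <- lag_min:lag_max
  sr / lags[which.max(ac[lags + 1L])]
}

#' Acoustic features of a call
#'
#' The four features used to characterize the stimulus library: spectral
#' centroid (energy-weighted mean frequency of the power spectrum), temporal
#' centroid (energy-weighted mean time of the amplitude envelope), duration,
#' and harmonic ratio (fraction of spectral energy within narrow bands around
#' the estimated fundamental and its first 10 integer multiples).
#'
#' @param w A [call_waveform()].
#' @param f0_range_hz Search range for the autocorrelation F0 estimate used
#'   by the harmonic ratio.
#' @return List of class `acoustic_features` with `spectral_centroid_hz`,
#'   `temporal_centroid_ms`, `duration_ms`, `harmonic_ratio`.
#' @export
acoustic_features <- function(w, f0_range_hz = c(4000, 30000)) {
  stopifnot(inherits(w, "call_waveform"))
  x <- w$samples
  if (all(x == 0)) stop("all-zero waveform: features undefined", call. = FALSE)
  sr <- w$sample_rate_hz
  n <- length(x)
  X <- stats::fft(x)
  half <- 1:(floor(n / 2) + 1L)
  p <- Mod(X[half])^2
  f <- (half - 1L) / n * sr
  spectral_centroid <- sum(f * p) / sum(p)

  env <- call_envelope(w, smoothing_ms = 1)
  tms <- (seq_len(n) - 0.5) / sr * 1000
  temporal_centroid <- sum(tms * env^2) / sum(env^2)

  f0 <- estimate_f0(w, f0_range_hz)
  in_band <- rep(FALSE, length(f))
  for (k in 1:10) {
    fk <- k * f0
    if (fk > max(f)) break
    in_band <- in_band | (abs(f - fk) <= 0.03 * fk)
  }
  harmonic_ratio <- sum(p[in_band]) / sum(p)

  structure(
    list(
      spectral_centroid_hz = spectral_centroid,
      temporal_centroid_ms = temporal_centroid,
      duration_ms = w$duration_ms,
      harmonic_ratio = harmonic_ratio
    ),
    class = "acoustic_features"
  )
}
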