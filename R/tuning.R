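#' Frequency-response area from a simulated or recorded tone grid
#'
#' For every (frequency, level) cell, the per-trial spike count in the
#' counting window (stimulus onset to onset + `count_window_ms`) is reduced
#' to its median over repetitions; the expected spontaneous count (scaled
#' from the 50-ms pre-stimulus window) is subtracted. A cell is classified
#' responsive when its median raw count exceeds the pooled spontaneous mean
#' plus `crit_sd` spontaneous SDs (counts scaled to the window length).
#'
#' @param grid_sets List of [spike_train_set()]s from [simulate_tone_grid()]
#'   (or equivalent recordings), each carrying `freq_khz` / `level_db`
#'   attributes.
#' @param count_window_ms Response-counting window after onset (default
#'   100 ms; override for very long tonic responses).
#' @param crit_sd Responsiveness criterion in spontaneous SDs (default 2).
#' @return Object of class `fra`: list with `freqs_khz`, `levels_db`,
#'   `response` (freq x level matrix of spontaneous-corrected median
#'   counts), `raw_median`, `responsive_cells` (logical matrix),
#'   `spontaneous_rate` (mean spikes per trial in the pre-window),
#'   `spont_mean`, `spont_sd`, `threshold_count`, `count_window_ms`.
#' @export
compute_fra <- function(grid_sets, count_window_ms = 100, crit_sd = 2) {
  stopifnot(length(grid_sets) > 0)
  freqs <- attr(grid_sets, "freqs_khz") %||%
    sort(unique(vapply(grid_sets, attr, numeric(1), "freq_khz")))
  levels <- attr(grid_sets, "levels_db") %||%
    sort(unique(vapply(grid_sets, attr, numeric(1), "level_db")), decreasing = TRUE)
  if (length(grid_sets) != length(freqs) * length(levels)) {
    stop("incomplete tone grid: expected one spike_train_set per (freq, level)",
         call. = FALSE)
  }
  proto <- grid_sets[[1L]]$protocol
  pre <- proto$pre_stimulus_ms
  scale <- count_window_ms / pre

  pre_counts <- unlist(lapply(grid_sets, function(s) {
    vapply(s$trials, function(tr) sum(tr < pre), numeric(1))
  }))
  spont_mean <- mean(pre_counts)
  spont_sd <- stats::sd(pre_counts)
  threshold_count <- spont_mean * scale + crit_sd * spont_sd * sqrt(scale)

  raw_median <- matrix(NA_real_, length(freqs), length(levels),
                       dimnames = list(NULL, NULL))
  for (s in grid_sets) {
    i <- match(attr(s, "freq_khz"), freqs)
    j <- match(attr(s, "level_db"), levels)
    counts <- vapply(s$trials, function(tr) {
      sum(tr >= pre & tr < pre + count_window_ms)
    }, numeric(1))
    raw_median[i, j] <- stats::median(counts)
  }
  if (anyNA(raw_median)) stop("missing grid cells", call. = FALSE)

  response <- raw_median - spont_mean * scale
  response[response < 0] <- 0

  structure(
    list(
      freqs_khz = freqs, levels_db = levels,
      response = response,
      raw_median = raw_median,
      responsive_cells = raw_median > threshold_count,
      spontaneous_rate = spont_mean,
      spont_mean = spont_mean, spont_sd = spont_sd,
      threshold_count = threshold_count,
      count_window_ms = count_window_ms
    ),
    class = "fra"
  )
}

#' @export
print.fra <- function(x, ...) {
  cat(sprintf(
    "<fra> %d freqs x %d levels, %d responsive cells, spontaneous %.2f spikes/pre-window\n",
    length(x$freqs_khz), length(x$levels_db), sum(x$responsive_cells),
    x$spontaneous_rate
  ))
  invisible(x)
}

fra_is_responsive <- function(fra) any(fra$responsive_cells)

#' Best frequency: the (frequency, level) cell with the strongest response
#'
#' Ties are broken toward the lowest frequency, then the highest level.
#'
#' @param fra An [compute_fra()] object.
#' @return List with `bf_khz` and `bf_threshold_db` (the level of the
#'   maximal cell).
#' @export
best_frequency <- function(fra) {
  stopifnot(inherits(fra, "fra"))
  if (!fra_is_responsive(fra)) stop_nonresponsive("no responsive FRA cells")
  m <- fra$response
  best <- which(m == max(m), arr.ind = TRUE)
  # ties: lowest frequency first, then highest level (levels are stored
  # in grid order; pick explicitly by value)
  best <- best[order(fra$freqs_khz[best[, 1L]], -fra$levels_db[best[, 2L]]), ,
               drop = FALSE]
  list(
    bf_khz = fra$freqs_khz[best[1L, 1L]],
    bf_threshold_db = fra$levels_db[best[1L, 2L]]
  )
}

#' Characteristic frequency: responsive at the lowest sound level
#'
#' Among cells classified responsive, the one with the minimal level; ties
#' at the minimal level go to the frequency closest (in octaves) to the best
#' frequency.
#'
#' @param fra An [compute_fra()] object.
#' @return List with `cf_khz` and `cf_threshold_db`.
#' @export
characteristic_frequency <- function(fra) {
  stopifnot(inherits(fra, "fra"))
  if (!fra_is_responsive(fra)) stop_nonresponsive("no responsive FRA cells")
  resp <- which(fra$responsive_cells, arr.ind = TRUE)
  lev <- fra$levels_db[resp[, 2L]]
  lmin <- min(lev)
  cand <- resp[lev == lmin, , drop = FALSE]
  if (nrow(cand) > 1L) {
    bf <- best_frequency(fra)$bf_khz
    cand <- cand[order(abs(log2(fra$freqs_khz[cand[, 1L]] / bf))), , drop = FALSE]
  }
  list(cf_khz = fra$freqs_khz[cand[1L, 1L]], cf_threshold_db = lmin)
}

#' Q10dB: sharpness of tuning 10 dB above the CF threshold
#'
#' CF divided by the bandwidth of the contiguous responsive frequency run
#' (containing the CF) at the grid level nearest `cf_threshold_db + 10`.
#' Bandwidth edges sit at the outermost responsive grid frequencies. When
#' the responsive run touches the grid edge the bandwidth is censored and
#' the result carries `attr(, "censored") = TRUE`.
#'
#' @param fra An [compute_fra()] object.
#' @param cf_khz,cf_threshold_db CF and its threshold; computed from `fra`
#'   when omitted.
#' @return Q10dB (numeric scalar, possibly with a `censored` attribute), or
#'   `NA` when no responsive run exists at the probe level or the run has
#'   zero width.
#' @export
q10db <- function(fra, cf_khz = NULL, cf_threshold_db = NULL) {
  stopifnot(inherits(fra, "fra"))
  if (is.null(cf_khz) || is.null(cf_threshold_db)) {
    cf <- characteristic_frequency(fra)
    cf_khz <- cf$cf_khz
    cf_threshold_db <- cf$cf_threshold_db
  }
  target <- cf_threshold_db + 10
  j <- which.min(abs(fra$levels_db - target))
  if (abs(fra$levels_db[j] - target) > 1e-6 &&
      !any(abs(fra$levels_db - target) < 1e-6)) {
    # nearest level is used; grids with 5-dB steps always contain the target
    j <- which.min(abs(fra$levels_db - target))
  }
  resp_row <- fra$responsive_cells[, j]
  if (!any(resp_row)) return(NA_real_)
  i_cf <- which.min(abs(log2(fra$freqs_khz / cf_khz)))
  runs <- rle(resp_row)
  run_id <- rep(seq_along(runs$lengths), runs$lengths)
  if (!resp_row[i_cf]) {
    # take the responsive run nearest to CF
    resp_idx <- which(resp_row)
    i_cf <- resp_idx[which.min(abs(resp_idx - i_cf))]
  }
  members <- which(run_id == run_id[i_cf])
  f_lo <- fra$freqs_khz[min(members)]
  f_hi <- fra$freqs_khz[max(members)]
  if (f_hi <= f_lo) return(NA_real_)
  out <- cf_khz / (f_hi - f_lo)
  if (min(members) == 1L || max(members) == length(fra$freqs_khz)) {
    attr(out, "censored") <- TRUE
  }
  out
}

#' Response latency and duration from a PSTH
#'
#' Latency is the time from stimulus onset to the first bin of the evoked
#' epoch: the suprathreshold region (counts above the spontaneous mean +
#' `crit_sd` SD of the pre-stimulus bins, with at least two consecutive
#' suprathreshold bins) anchored at the response maximum and extended over
#' gaps of at most `max_gap_ms`. Duration is the span of that epoch.
#' Isolated threshold crossings away from the response do not bias the
#' estimates.
#'
#' @param psth A [compute_psth()] object covering the pre-stimulus window.
#' @param pre_ms Pre-stimulus window length; defaults to the PSTH's own.
#' @param crit_sd Criterion in spontaneous SDs (default 2).
#' @param max_gap_ms Largest within-epoch silent gap (default 10 ms).
#' @return List with `responsive` (logical), `latency_ms`, `duration_ms`.
#' @export
latency_and_duration <- function(psth, pre_ms = NULL, crit_sd = 2, max_gap_ms = 10) {
  stopifnot(inherits(psth, "psth"))
  epoch <- psth_evoked_epoch(psth, pre_ms = pre_ms, crit_sd = crit_sd,
                             max_gap_ms = max_gap_ms)
  pre_ms <- pre_ms %||% psth$pre_stimulus_ms
  if (is.null(epoch)) {
    return(list(responsive = FALSE, latency_ms = NA_real_, duration_ms = NA_real_))
  }
  # the increase occurs at an unknown time within the first epoch bin; the
  # bin midpoint is the unbiased estimate
  list(
    responsive = TRUE,
    latency_ms = epoch$onset_ms + psth$bin_width_ms / 2 - pre_ms,
    duration_ms = epoch$end_ms - epoch$onset_ms
  )
}

# Pool trial-summed 1-ms PSTHs over the responsive grid cells.
pooled_grid_psth <- function(grid_sets, fra, bin_width_ms = 1) {
  freqs <- fra$freqs_khz
  levels <- fra$levels_db
  counts <- NULL
  n_trials <- 0L
  proto <- grid_sets[[1L]]$protocol
  for (s in grid_sets) {
    i <- match(attr(s, "freq_khz"), freqs)
    j <- match(attr(s, "level_db"), levels)
    if (!fra$responsive_cells[i, j]) next
    p <- compute_psth(s, bin_width_ms = bin_width_ms)
    counts <- if (is.null(counts)) p$counts else counts + p$counts
    n_trials <- n_trials + p$n_trials
  }
  if (is.null(counts)) return(NULL)
  structure(
    list(bin_width_ms = bin_width_ms, t0_ms = 0, counts = counts,
         n_trials = n_trials, pre_stimulus_ms = proto$pre_stimulus_ms),
    class = "psth"
  )
}

#' Per-unit pure-tone tuning summary
#'
#' Computes the FRA, best and characteristic frequency, Q10dB, and response
#' latency/duration (from the 1-ms PSTH pooled over responsive grid cells).
#'
#' @param grid_sets List of [spike_train_set()]s from [simulate_tone_grid()].
#' @param count_window_ms Response-counting window for the FRA.
#' @param crit_sd Responsiveness criterion in spontaneous SDs.
#' @return One-row data.frame of class `tuning_summary` with columns
#'   `unit_id`, `responsive`, `bf_khz`, `bf_threshold_db`, `cf_khz`,
#'   `cf_threshold_db`, `q10`, `q10_censored`, `latency_ms`,
#'   `response_duration_ms`, `spontaneous_rate`.
#' @export
tuning_summary <- function(grid_sets, count_window_ms = 100, crit_sd = 2) {
  fra <- compute_fra(grid_sets, count_window_ms = count_window_ms, crit_sd = crit_sd)
  uid <- grid_sets[[1L]]$unit_id
  empty <- data.frame(
    unit_id = uid, responsive = FALSE, bf_khz = NA_real_,
    bf_threshold_db = NA_real_, cf_khz = NA_real_, cf_threshold_db = NA_real_,
    q10 = NA_real_, q10_censored = NA, latency_ms = NA_real_,
    response_duration_ms = NA_real_, spontaneous_rate = fra$spontaneous_rate,
    stringsAsFactors = FALSE
  )
  if (!fra_is_responsive(fra)) {
    class(empty) <- c("tuning_summary", "data.frame")
    return(empty)
  }
  bf <- best_frequency(fra)
  cf <- characteristic_frequency(fra)
  q <- q10db(fra, cf$cf_khz, cf$cf_threshold_db)
  pooled <- pooled_grid_psth(grid_sets, fra)
  ld <- if (is.null(pooled)) {
    list(responsive = FALSE, latency_ms = NA_real_, duration_ms = NA_real_)
  } else {
    latency_and_duration(pooled, crit_sd = crit_sd)
  }
  out <- data.frame(
    unit_id = uid, responsive = TRUE, bf_khz = bf$bf_khz,
    bf_threshold_db = bf$bf_threshold_db, cf_khz = cf$cf_khz,
    cf_threshold_db = cf$cf_threshold_db, q10 = as.numeric(q),
    q10_censored = isTRUE(attr(q, "censored")),
    latency_ms = ld$latency_ms, response_duration_ms = ld$duration_ms,
    spontaneous_rate = fra$spontaneous_rate,
    stringsAsFactors = FALSE
  )
  class(out) <- c("tuning_summary", "data.frame")
  out
}
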