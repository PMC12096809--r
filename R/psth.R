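#' Peri-stimulus time histogram
#'
#' Bins spike times over `[0, trial length)` and sums over trials (default)
#' or extracts a single trial.
#'
#' @param sts A [spike_train_set()].
#' @param bin_width_ms Bin width in ms.
#' @param trial `NULL` for the trial-summed PSTH, or a single trial index.
#' @return Object of class `psth`: list with `bin_width_ms`, `t0_ms` (0),
#'   `counts`, `n_trials`, `pre_stimulus_ms`.
#' @export
compute_psth <- function(sts, bin_width_ms = 1, trial = NULL) {
  stopifnot(inherits(sts, "spike_train_set"), bin_width_ms > 0)
  tlen <- trial_length_ms(sts$protocol)
  n_bins <- ceiling(tlen / bin_width_ms)
  if (is.null(trial)) {
    times <- unlist(sts$trials)
    n_trials <- length(sts$trials)
  } else {
    stopifnot(trial >= 1, trial <= length(sts$trials))
    times <- sts$trials[[trial]]
    n_trials <- 1L
  }
  counts <- if (length(times)) {
    tabulate(pmin(n_bins, floor(times / bin_width_ms) + 1L), nbins = n_bins)
  } else {
    integer(n_bins)
  }
  structure(
    list(
      bin_width_ms = bin_width_ms, t0_ms = 0, counts = counts,
      n_trials = n_trials, pre_stimulus_ms = sts$protocol$pre_stimulus_ms
    ),
    class = "psth"
  )
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> %d bins x %g ms, %d trial(s), %d spikes\n",
              length(x$counts), x$bin_width_ms, x$n_trials, sum(x$counts)))
  invisible(x)
}

#' Analysis response window
#'
#' @param start_ms,end_ms Window bounds in ms relative to trial start
#'   (`end_ms > start_ms`).
#' @return Object of class `response_window`.
#' @export
response_window <- function(start_ms, end_ms) {
  stopifnot(end_ms > start_ms)
  structure(list(start_ms = start_ms, end_ms = end_ms), class = "response_window")
}

#' @export
print.response_window <- function(x, ...) {
  cat(sprintf("<response_window> [%.1f, %.1f) ms (%.1f ms)\n",
              x$start_ms, x$end_ms, x$end_ms - x$start_ms))
  invisible(x)
}

# Evoked epoch of one PSTH: bins whose count exceeds mean + crit_sd * SD of
# the pre-stimulus bins, requiring >= 2 consecutive suprathreshold bins. The
# epoch is anchored at the suprathreshold run nearest the post-stimulus
# response maximum and extended in both directions across suprathreshold
# bins separated by gaps of at most max_gap_ms; isolated noise crossings
# away from the response are thereby excluded. Returns NULL if
# non-responsive.
psth_evoked_epoch <- function(psth, pre_ms = NULL, crit_sd = 2, max_gap_ms = 10) {
  pre_ms <- pre_ms %||% psth$pre_stimulus_ms
  bw <- psth$bin_width_ms
  starts <- (seq_along(psth$counts) - 1L) * bw
  base <- psth$counts[starts < pre_ms]
  if (length(base) < 2L) stop("PSTH must cover the pre-stimulus window", call. = FALSE)
  thr <- mean(base) + crit_sd * stats::sd(base)
  post <- starts >= pre_ms
  supra <- psth$counts > thr & post
  idx <- which(supra)
  if (length(idx) < 2L) return(NULL)
  # bins belonging to runs of >= 2 consecutive suprathreshold bins;
  # isolated single-bin crossings are treated as noise throughout
  in_run <- idx[c(diff(idx) == 1L, FALSE) | c(FALSE, diff(idx) == 1L)]
  if (!length(in_run)) return(NULL)
  peak_idx <- which(post)[which.max(psth$counts[post])]
  anchor <- in_run[which.min(abs(in_run - peak_idx))]
  lo <- anchor
  repeat {
    prev <- in_run[in_run < lo]
    if (!length(prev) || (lo - max(prev)) * bw > max_gap_ms) break
    lo <- max(prev)
  }
  hi <- anchor
  repeat {
    nxt <- in_run[in_run > hi]
    if (!length(nxt) || (min(nxt) - hi) * bw > max_gap_ms) break
    hi <- min(nxt)
  }
  list(
    onset_ms = starts[lo],
    end_ms = starts[hi] + bw,
    threshold = thr
  )
}
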