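#' Shared response window across the 15 calls
#'
#' Each call's evoked epoch is found on its trial-summed PSTH with the
#' spontaneous mean + 2 SD criterion (pre-stimulus bins in the first
#' `pre_ms`). The shared window starts at the earliest evoked onset across
#' calls and its length equals the longest per-call evoked duration, i.e. it
#' is "set to match the longest response duration evoked by one of the
#' calls".
#'
#' @param call_psths Named list of [compute_psth()] objects (same binning,
#'   aligned at trial start), one per call.
#' @param pre_ms Pre-stimulus window, ms (default 50).
#' @param crit_sd Criterion in spontaneous SDs.
#' @param max_gap_ms Largest within-epoch silent gap.
#' @return A [response_window()]. Signals a `vocsel_nonresponsive` error if
#'   no call evokes a response.
#' @export
shared_response_window <- function(call_psths, pre_ms = 50, crit_sd = 2,
                                   max_gap_ms = 10) {
  stopifnot(length(call_psths) > 0)
  bw <- call_psths[[1L]]$bin_width_ms
  onsets <- c()
  durations <- c()
  for (p in call_psths) {
    stopifnot(inherits(p, "psth"))
    if (p$bin_width_ms != bw) stop("all PSTHs must share the same binning", call. = FALSE)
    ep <- psth_evoked_epoch(p, pre_ms = pre_ms, crit_sd = crit_sd,
                            max_gap_ms = max_gap_ms)
    if (is.null(ep)) next
    onsets <- c(onsets, ep$onset_ms)
    durations <- c(durations, ep$end_ms - ep$onset_ms)
  }
  if (!length(onsets)) stop_nonresponsive("no call evokes a response")
  response_window(min(onsets), min(onsets) + max(durations))
}

#' Response strength of one call: maximum spikes per bin in the window
#'
#' @param psth A [compute_psth()] object (2-ms bins in the reference
#'   protocol; any binning accepted).
#' @param window A [response_window()].
#' @return Maximum bin count within the window (0 for an empty window).
#' @export
call_response_strength <- function(psth, window) {
  stopifnot(inherits(psth, "psth"), inherits(window, "response_window"))
  bw <- psth$bin_width_ms
  starts <- (seq_along(psth$counts) - 1L) * bw
  if (window$start_ms < 0 || window$end_ms > length(psth$counts) * bw + 1e-9) {
    stop("window outside PSTH range", call. = FALSE)
  }
  inside <- starts >= window$start_ms - 1e-9 & starts < window$end_ms - 1e-9
  if (!any(inside)) return(0)
  max(psth$counts[inside])
}

#' Category preference index PIcat
#'
#' The number of categories whose summed response reaches at least 50% of
#' the maximum summed category response: 1 = highest selectivity, 3 = no
#' selectivity. The 50% boundary is inclusive.
#'
#' @param per_category_response Numeric vector of 3 non-negative summed
#'   category responses (named or in category order).
#' @return Integer in 1..3.
#' @export
pi_cat <- function(per_category_response) {
  x <- as.numeric(per_category_response)
  stopifnot(length(x) == 3, all(x >= 0))
  if (all(x == 0)) stop_nonresponsive("all category responses are zero")
  sum(x >= 0.5 * max(x))
}

#' Call preference index PIcall (within one category)
#'
#' The number of calls within a category whose maximum per-bin response
#' reaches at least 50% of the strongest call of that category: 1 = highest
#' selectivity, 5 = no selectivity. The 50% boundary is inclusive.
#'
#' @param per_call_response Numeric vector of 5 non-negative per-call
#'   response strengths.
#' @return Integer in 1..5.
#' @export
pi_call <- function(per_call_response) {
  x <- as.numeric(per_call_response)
  stopifnot(length(x) == 5, all(x >= 0))
  if (all(x == 0)) stop_nonresponsive("all call responses are zero")
  sum(x >= 0.5 * max(x))
}

#' Response-strength selectivity of one unit
#'
#' Computes 2-ms trial-summed PSTHs for all calls, derives the shared
#' response window, measures each call's maximum bins-per-window strength,
#' sums strengths within categories, and reports PIcat plus per-category
#' PIcall.
#'
#' @param call_sets Named list of [spike_train_set()]s, one per call (names
#'   are call ids).
#' @param categories Named character vector mapping call id to category.
#' @param bin_width_ms PSTH bin width (default 2 ms).
#' @param pre_ms Pre-stimulus window (default 50 ms).
#' @param crit_sd Criterion in spontaneous SDs.
#' @return Object of class `preference_result`: list with `pi_cat`,
#'   `pi_call` (named by category), `per_call_response`,
#'   `per_category_response`, `window`.
#' @export
preference_result <- function(call_sets, categories, bin_width_ms = 2,
                              pre_ms = 50, crit_sd = 2) {
  stopifnot(length(call_sets) > 0, !is.null(names(call_sets)),
            all(names(call_sets) %in% names(categories)))
  psths <- lapply(call_sets, compute_psth, bin_width_ms = bin_width_ms)
  window <- shared_response_window(psths, pre_ms = pre_ms, crit_sd = crit_sd)
  strengths <- vapply(psths, call_response_strength, numeric(1), window = window)
  cats <- categories[names(call_sets)]
  per_category <- tapply(strengths, cats, sum)
  picat <- pi_cat(per_category[c("echolocation", "appeasement", "aggression")])
  picall <- sapply(unique(cats), function(cc) {
    v <- strengths[cats == cc]
    if (all(v == 0)) NA_integer_ else pi_call(v)
  })
  structure(
    list(
      pi_cat = picat,
      pi_call = picall,
      per_call_response = strengths,
      per_category_response = per_category,
      window = window
    ),
    class = "preference_result"
  )
}

#' @export
print.preference_result <- function(x, ...) {
  cat(sprintf("<preference_result> PIcat = %d; PIcall: %s\n", x$pi_cat,
              paste(sprintf("%s=%s", names(x$pi_call), x$pi_call), collapse = ", ")))
  invisible(x)
}
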