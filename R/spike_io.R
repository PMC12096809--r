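#' Serialize spike-train sets to a long-format data frame
#'
#' One row per spike plus one `NA`-spike row per empty trial, so that trial
#' counts and protocol timing survive the round trip.
#'
#' @param sets List of [spike_train_set()]s.
#' @return data.frame with columns `unit_id`, `stimulus_id`, `trial`,
#'   `spike_time_ms`, `pre_stimulus_ms`, `post_stimulus_ms`, `n_trials`.
#' @export
spikes_to_df <- function(sets) {
  if (inherits(sets, "spike_train_set")) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    n_sp <- lengths(s$trials)
    trial_idx <- rep(seq_along(s$trials), pmax(1L, n_sp))
    times <- unlist(lapply(s$trials, function(tr) if (length(tr)) tr else NA_real_))
    data.frame(
      unit_id = s$unit_id, stimulus_id = s$stimulus_id,
      trial = trial_idx, spike_time_ms = times,
      pre_stimulus_ms = s$protocol$pre_stimulus_ms,
      post_stimulus_ms = s$protocol$post_stimulus_ms,
      n_trials = s$protocol$n_trials,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rebuild spike-train sets from a long-format data frame
#'
#' Inverse of [spikes_to_df()].
#'
#' @param df data.frame in the [spikes_to_df()] schema.
#' @param seed Seed recorded in the reconstructed protocols (metadata only).
#' @return Named list of [spike_train_set()]s keyed `unit_id/stimulus_id`.
#' @export
df_to_spikes <- function(df, seed = 0L) {
  key <- paste(df$unit_id, df$stimulus_id, sep = "/")
  out <- list()
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    proto <- trial_protocol(
      pre_stimulus_ms = sub$pre_stimulus_ms[1],
      post_stimulus_ms = sub$post_stimulus_ms[1],
      n_trials = sub$n_trials[1], seed = seed
    )
    trials <- vector("list", proto$n_trials)
    for (i in seq_len(proto$n_trials)) {
      tt <- sub$spike_time_ms[sub$trial == i]
      trials[[i]] <- sort(tt[!is.na(tt)])
    }
    out[[k]] <- spike_train_set(sub$unit_id[1], sub$stimulus_id[1], trials, proto)
  }
  out
}

#' Write spike-train sets to CSV (long format)
#'
#' @param sets List of [spike_train_set()]s (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_csv <- function(sets, path) {
  utils::write.csv(spikes_to_df(sets), path, row.names = FALSE)
  invisible(path)
}

#' Read spike-train sets from CSV written by [write_spike_csv()]
#'
#' @param path CSV path.
#' @param seed Seed recorded in the reconstructed protocols (metadata only).
#' @return Named list of [spike_train_set()]s.
#' @export
read_spike_csv <- function(path, seed = 0L) {
  df_to_spikes(utils::read.csv(path, stringsAsFactors = FALSE), seed = seed)
}

#' Write spike-train sets to JSON
#'
#' @inheritParams write_spike_csv
#' @return `path`, invisibly.
#' @export
write_spike_json <- function(sets, path) {
  if (inherits(sets, "spike_train_set")) sets <- list(sets)
  payload <- lapply(sets, function(s) {
    list(
      unit_id = s$unit_id, stimulus_id = s$stimulus_id,
      protocol = s$protocol[c("pre_stimulus_ms", "post_stimulus_ms", "n_trials", "seed")],
      trials = lapply(s$trials, as.numeric)
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read spike-train sets from JSON written by [write_spike_json()]
#'
#' @param path JSON path.
#' @return Named list of [spike_train_set()]s keyed `unit_id/stimulus_id`.
#' @export
read_spike_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (p in payload) {
    proto <- trial_protocol(
      pre_stimulus_ms = p$protocol$pre_stimulus_ms,
      post_stimulus_ms = p$protocol$post_stimulus_ms,
      n_trials = p$protocol$n_trials, seed = p$protocol$seed
    )
    trials <- lapply(p$trials, function(tr) as.numeric(unlist(tr)))
    out[[paste(p$unit_id, p$stimulus_id, sep = "/")]] <-
      spike_train_set(p$unit_id, p$stimulus_id, trials, proto)
  }
  out
}
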