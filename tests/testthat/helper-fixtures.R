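# Shared fixtures built in code. The 15-call library and the template-unit
# responses are computed once per test run.

fixture_library <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- synth_call_library(seed = 1)
    lib
  }
})

fixture_categories <- function() {
  man <- call_manifest(fixture_library())
  stats::setNames(man$category, man$call_id)
}

fixture_call_sets <- local({
  cache <- list()
  function(profile, seed = 5, n_trials = 20) {
    key <- paste(profile$unit_id, seed, n_trials)
    if (is.null(cache[[key]])) {
      proto <- trial_protocol(post_stimulus_ms = 450, n_trials = n_trials,
                              seed = seed)
      cache[[key]] <<- lapply(fixture_library()$calls, simulate_call_response,
                              profile = profile, protocol = proto)
    }
    cache[[key]]
  }
})

# Deterministic spike-train set: every trial has identical spike times.
make_deterministic_set <- function(unit_id, stimulus_id, times, n_trials = 4,
                                   pre = 50, post = 150) {
  proto <- trial_protocol(pre_stimulus_ms = pre, post_stimulus_ms = post,
                          n_trials = n_trials, seed = 0)
  spike_train_set(unit_id, stimulus_id, rep(list(sort(times)), n_trials), proto)
}

# Baseline-only homogeneous-Poisson spike sets, one per id, rate-matched.
make_baseline_sets <- function(ids, rate_hz, n_trials = 20, pre = 50,
                               post = 250, seed = 1) {
  proto <- trial_protocol(pre_stimulus_ms = pre, post_stimulus_ms = post,
                          n_trials = n_trials, seed = seed)
  tlen <- pre + post
  out <- list()
  for (i in seq_along(ids)) {
    trials <- vocsel:::with_seed(fan_seed(seed, "baseline", ids[i]), {
      lapply(seq_len(n_trials), function(j) {
        n <- stats::rpois(1, rate_hz * tlen / 1000)
        sort(stats::runif(n, 0, tlen))
      })
    })
    out[[ids[i]]] <- spike_train_set("baseline_unit", ids[i], trials, proto)
  }
  out
}

# Exhaustive-enumeration oracle for the confusion matrix: averages the
# classification outcome over every (test trial, template combination),
# splitting ties equally among tied classes. Independent of the resampling
# engine (direct distance computation on smoothed patterns).
enumerate_confusion <- function(call_sets, categories, level = "category",
                                integration_window_ms = 2, window) {
  call_ids <- names(call_sets)
  class_of_call <- if (level == "category") {
    as.character(categories[call_ids])
  } else {
    call_ids
  }
  labels <- unique(class_of_call)
  K <- length(labels)
  pats <- lapply(call_sets, function(s) {
    lapply(seq_along(s$trials), function(tr) {
      smooth_pattern(compute_psth(s, 1, trial = tr), window,
                     integration_window_ms)$values
    })
  })
  probs <- matrix(0, K, K, dimnames = list(labels, labels))
  row_weight <- stats::setNames(numeric(K), labels)
  ntr <- vapply(call_sets, function(s) length(s$trials), integer(1))
  for (ci in seq_along(call_ids)) {
    for (tt in seq_len(ntr[ci])) {
      test <- pats[[ci]][[tt]]
      grids <- lapply(seq_along(call_ids), function(cj) {
        if (cj == ci) setdiff(seq_len(ntr[cj]), tt) else seq_len(ntr[cj])
      })
      combos <- expand.grid(grids)
      for (r in seq_len(nrow(combos))) {
        d2 <- vapply(seq_along(call_ids), function(cj) {
          sum((pats[[cj]][[combos[r, cj]]] - test)^2)
        }, numeric(1))
        dmin <- min(d2)
        tied <- unique(class_of_call[d2 <= dmin + 1e-9 * (1 + dmin)])
        for (cl in tied) {
          probs[class_of_call[ci], cl] <-
            probs[class_of_call[ci], cl] + 1 / length(tied) / nrow(combos)
        }
      }
      row_weight[class_of_call[ci]] <- row_weight[class_of_call[ci]] + 1
    }
  }
  sweep(probs, 1, row_weight, "/")
}
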